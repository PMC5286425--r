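#' Observed heterozygosity and homozygosity per population
#'
#' Per individual, heterozygosity is the fraction of non-missing calls that
#' are heterozygous; populations average over individuals and homozygosity
#' is its complement, `hom = 1 - het`.
#'
#' @param ds A `geno_ds`.
#' @return Tibble: `population`, `het`, `hom`, `n_individuals`.
#' @export
observed_heterozygosity <- function(ds) {
  stopifnot(inherits(ds, "geno_ds"))
  nobs <- rowSums(!is.na(ds$geno))
  if (any(nobs == 0)) {
    warn(sprintf("excluding %d individual(s) with no non-missing calls",
                 sum(nobs == 0)))
  }
  het_i <- rowSums(ds$geno == 1L, na.rm = TRUE) / nobs
  tibble(population = ds$meta$population, het_i = het_i) |>
    filter(is.finite(.data$het_i)) |>
    group_by(.data$population) |>
    summarise(het = mean(.data$het_i), n_individuals = dplyr::n(),
              .groups = "drop") |>
    mutate(hom = 1 - .data$het) |>
    select("population", "het", "hom", "n_individuals")
}

#' Inter-locus dispersion of heterozygosity
#'
#' Per population, computes the observed heterozygosity of every locus
#' across individuals and reports its dispersion over loci: the sample
#' standard deviation by default, or its square root with
#' `mode = "sqrt_sd"` (a literal reading of taking the square root of the
#' standard deviation).
#'
#' @param ds A `geno_ds`.
#' @param mode `"sd"` (default) or `"sqrt_sd"`.
#' @return Tibble: `population`, `interlocus_disp`.
#' @export
interlocus_dispersion <- function(ds, mode = c("sd", "sqrt_sd")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "geno_ds"))
  if (ncol(ds$geno) < 2) stop_isopop("need at least 2 loci for dispersion")
  pops <- unique(ds$meta$population)
  vals <- vapply(pops, function(p) {
    g <- ds$geno[ds$meta$population == p, , drop = FALSE]
    nobs <- colSums(!is.na(g))
    ph <- colSums(g == 1L, na.rm = TRUE) / nobs
    ph <- ph[is.finite(ph)]
    if (length(ph) < 2) stop_isopop(sprintf(
      "population %s has fewer than 2 informative loci", p))
    s <- sd(ph)
    if (mode == "sqrt_sd") sqrt(s) else s
  }, numeric(1))
  tibble(population = pops, interlocus_disp = unname(vals))
}

#' Pairwise identity-by-state matrix
#'
#' Per pair of individuals, the per-locus similarity `(2 - |g_i - g_j|) / 2`
#' averaged over loci where both are non-missing.
#'
#' @param ds A `geno_ds`.
#' @return Symmetric matrix of IBS fractions with unit diagonal; pairs with
#'   no jointly observed locus are `NA` (with a warning).
#' @export
pairwise_ibs <- function(ds) {
  stopifnot(inherits(ds, "geno_ds"))
  if (nrow(ds$geno) < 2) stop_isopop("need at least 2 samples")
  g <- ds$geno
  M <- (!is.na(g)) * 1
  gz <- g; gz[is.na(gz)] <- 0L
  a1 <- (gz >= 1L) * 1; a2 <- (gz >= 2L) * 1
  sum_ab <- tcrossprod(gz, M) + tcrossprod(M, gz)
  min_ab <- tcrossprod(a1) + tcrossprod(a2)
  abs_sum <- sum_ab - 2 * min_ab
  nobs <- tcrossprod(M)
  if (any(nobs[upper.tri(nobs)] == 0)) {
    warn("some sample pairs share no observed loci; IBS set to NA")
  }
  ibs <- 1 - abs_sum / (2 * nobs)
  ibs[nobs == 0] <- NA_real_
  dimnames(ibs) <- list(ds$meta$sample_id, ds$meta$sample_id)
  ibs
}

#' Mean intra-population identity by state
#'
#' @param ibs IBS matrix from [pairwise_ibs()].
#' @param meta Sample metadata.
#' @return Tibble: `population`, `mean_intra_ibs`, `n_pairs`.
#' @export
intra_population_ibs <- function(ibs, meta) {
  meta <- as_tibble(meta)
  pops <- unique(meta$population)
  purrr::map_dfr(pops, function(p) {
    ids <- meta$sample_id[meta$population == p]
    if (length(ids) < 2) {
      return(tibble(population = p, mean_intra_ibs = NA_real_, n_pairs = 0L))
    }
    sub <- ibs[ids, ids, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    tibble(population = p, mean_intra_ibs = mean(vals, na.rm = TRUE),
           n_pairs = length(vals))
  })
}

#' Intra-population sharing of identity-by-descent segments (W_int)
#'
#' The total length of IBD segments shared within a population divided by
#' the number of possible pairs of its individuals. Centimorgan lengths are
#' used when every relevant segment carries one, base pairs otherwise.
#'
#' @param segments IBD segment tibble (columns `sample_a`, `sample_b`,
#'   `length_bp`, optional `length_cm`).
#' @param sample_ids Members of the population.
#' @param unit `"auto"` (default), `"cm"` or `"bp"`.
#' @return One-row tibble: `w_int`, `unit`, `n_pairs`, `n_segments`.
#' @export
w_int <- function(segments, sample_ids, unit = c("auto", "cm", "bp")) {
  unit <- match.arg(unit)
  n <- length(sample_ids)
  if (n < 2) stop_isopop("W_int needs at least 2 individuals")
  inpop <- segments$sample_a %in% sample_ids &
    segments$sample_b %in% sample_ids
  seg <- segments[inpop, , drop = FALSE]
  have_cm <- "length_cm" %in% names(seg) && nrow(seg) > 0 &&
    !anyNA(seg$length_cm)
  use <- switch(unit,
                auto = if (have_cm) "cm" else "bp",
                cm = { if (!have_cm && nrow(seg) > 0)
                  stop_isopop("cM lengths unavailable"); "cm" },
                bp = "bp")
  tot <- if (nrow(seg) == 0) 0
         else if (use == "cm") sum(seg$length_cm) else sum(seg$length_bp)
  n_pairs <- n * (n - 1) / 2
  tibble(w_int = tot / n_pairs, unit = use, n_pairs = n_pairs,
         n_segments = nrow(seg))
}

#' Assemble per-population isolation profiles
#'
#' Joins the intra-population measures into one complete profile per
#' population; any population missing from a component table is an error,
#' because the downstream principal-component analysis needs complete rows.
#'
#' @param het Output of [observed_heterozygosity()].
#' @param dispersion Output of [interlocus_dispersion()].
#' @param roh_summary Output of [roh_population_summary()].
#' @param ibs Output of [intra_population_ibs()].
#' @param wint Tibble `population`, `w_int`, `unit` (one [w_int()] row per
#'   population).
#' @param ld Tibble `population`, `mean_ld_block_bp`.
#' @param froh_pop Tibble `population`, `mean_froh`.
#' @return Tibble with one row per population and one column per measure.
#' @export
build_profiles <- function(het, dispersion, roh_summary, ibs, wint, ld,
                           froh_pop) {
  parts <- list(het = het, dispersion = dispersion,
                roh_summary = roh_summary, ibs = ibs, wint = wint,
                ld = ld, froh = froh_pop)
  pops <- sort(unique(het$population))
  for (nm in names(parts)) {
    missing_pop <- setdiff(pops, parts[[nm]]$population)
    extra <- setdiff(parts[[nm]]$population, pops)
    if (length(missing_pop) || length(extra)) {
      stop_isopop(sprintf(
        "component '%s' population set mismatch (missing: %s; extra: %s)",
        nm, paste(missing_pop, collapse = ",") %|e|% "-",
        paste(extra, collapse = ",") %|e|% "-"))
    }
  }
  out <- het |> select("population", "hom") |>
    left_join(select(dispersion, "population", "interlocus_disp"),
              by = "population") |>
    left_join(roh_summary, by = "population") |>
    left_join(select(ibs, "population", "mean_intra_ibs"),
              by = "population") |>
    left_join(select(wint, "population", "w_int", dplyr::any_of("unit")),
              by = "population") |>
    left_join(select(ld, "population", "mean_ld_block_bp"),
              by = "population") |>
    left_join(select(froh_pop, "population", "mean_froh"),
              by = "population")
  num <- vapply(out, is.numeric, logical(1))
  if (any(vapply(out[num], anyNA, logical(1)))) {
    bad <- names(out[num])[vapply(out[num], anyNA, logical(1))]
    stop_isopop(paste0("incomplete profile measures: ",
                       paste(bad, collapse = ", ")))
  }
  out
}

`%|e|%` <- function(x, y) if (nzchar(x)) x else y
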