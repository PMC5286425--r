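#' Mean Burrows composite-disequilibrium r-squared
#'
#' Applies a minor-allele-frequency floor, then for SNP pairs under the
#' chosen pairing policy computes the Burrows composite disequilibrium from
#' unphased genotype counts with the `S/(S-1)` sample correction and
#' standardizes it to a squared correlation using the per-locus variance
#' components `p(1-p) + (P_hom - p^2)` that absorb departures from
#' Hardy-Weinberg proportions. Missing genotypes are excluded pairwise.
#'
#' @param ds A `geno_ds`.
#' @param population Optional population name; default uses all samples.
#' @param maf_min Minor-allele-frequency floor; loci below it are excluded
#'   (default 0.05).
#' @param pair_policy `"inter_chromosome"` (default; only pairs on different
#'   chromosomes, free of physical linkage) or `"all"`.
#' @param max_pairs Upper bound on the number of SNP pairs; a random subset
#'   is drawn under `seed` when exceeded.
#' @param seed Integer seed for pair subsampling.
#' @return One-row tibble: `mean_r2`, `n_pairs`, `harmonic_s`, `n_snps`.
#' @export
burrows_r2 <- function(ds, population = NULL, maf_min = 0.05,
                       pair_policy = c("inter_chromosome", "all"),
                       max_pairs = 50000L, seed = 1L) {
  pair_policy <- match.arg(pair_policy)
  stopifnot(inherits(ds, "geno_ds"))
  if (!is.null(population)) {
    ds <- subset_geno(ds, samples = ds$meta$sample_id[
      ds$meta$population == population])
  }
  g <- ds$geno
  if (nrow(g) < 2) stop_isopop("need at least 2 individuals")
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min
  if (sum(keep) < 2) stop_isopop("no retained loci after the MAF floor")
  g <- g[, keep, drop = FALSE]
  chrom <- ds$map$chrom[keep]
  m <- ncol(g)
  if (pair_policy == "inter_chromosome" && length(unique(chrom)) < 2) {
    stop_isopop("inter-chromosome pairing needs SNPs on >= 2 chromosomes")
  }
  pairs <- if (m <= 2000L) {
    idx <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
    if (pair_policy == "inter_chromosome") {
      idx <- idx[chrom[idx[, 1]] != chrom[idx[, 2]], , drop = FALSE]
    }
    if (nrow(idx) > max_pairs) {
      sel <- with_seed(child_seed(seed, 17L),
                       sample.int(nrow(idx), max_pairs))
      idx <- idx[sel, , drop = FALSE]
    }
    idx
  } else {
    # too many pairs to enumerate: rejection-sample distinct random pairs
    with_seed(child_seed(seed, 17L), {
      acc <- matrix(integer(0), 0, 2)
      tries <- 0L
      while (nrow(acc) < max_pairs && tries < 50L) {
        a <- sample.int(m, max_pairs, replace = TRUE)
        b <- sample.int(m, max_pairs, replace = TRUE)
        sw <- a > b; tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
        ok <- a < b
        if (pair_policy == "inter_chromosome") ok <- ok & chrom[a] != chrom[b]
        acc <- unique(rbind(acc, cbind(a[ok], b[ok])))
        tries <- tries + 1L
      }
      acc[seq_len(min(max_pairs, nrow(acc))), , drop = FALSE]
    })
  }
  if (nrow(pairs) < 1) stop_isopop("no SNP pairs under this pairing policy")
  M <- (!is.na(g)) * 1
  gz <- g; gz[is.na(gz)] <- 0L
  hz <- (gz == 2L) * 1
  r2 <- numeric(nrow(pairs)); nc_all <- numeric(nrow(pairs))
  batch <- 20000L
  for (b0 in seq(1, nrow(pairs), by = batch)) {
    b1 <- min(b0 + batch - 1, nrow(pairs))
    a <- pairs[b0:b1, 1]; b <- pairs[b0:b1, 2]
    Ca <- M[, a, drop = FALSE]; Cb <- M[, b, drop = FALSE]
    C <- Ca * Cb
    nc <- colSums(C)
    Xa <- gz[, a, drop = FALSE] * C; Xb <- gz[, b, drop = FALSE] * C
    pa <- colSums(Xa) / (2 * nc); pb <- colSums(Xb) / (2 * nc)
    homa <- colSums(hz[, a, drop = FALSE] * C) / nc
    homb <- colSums(hz[, b, drop = FALSE] * C) / nc
    sxy <- colSums(Xa * Xb) / nc
    delta <- (nc / (nc - 1)) * (sxy / 2 - 2 * pa * pb)
    ta <- pa * (1 - pa) + (homa - pa^2)
    tb <- pb * (1 - pb) + (homb - pb^2)
    r2[b0:b1] <- delta^2 / (ta * tb)
    nc_all[b0:b1] <- nc
  }
  ok <- is.finite(r2) & nc_all >= 2
  tibble(mean_r2 = mean(r2[ok]), n_pairs = sum(ok),
         harmonic_s = 1 / mean(1 / nc_all[ok]), n_snps = m)
}

#' Effective population size from linkage disequilibrium
#'
#' Subtracts the finite-sample expectation of the squared correlation from
#' the observed mean, then converts the residual drift signal to an
#' effective size using the random-mating bias-corrected coefficients
#' (Waples 2006, Conserv Genet 7; Waples & Do 2008, Mol Ecol Resour 8): for
#' harmonic sample size S >= 30, `E(r2_sample) = 1/S + 3.19/S^2` and
#' `Ne = (1/3 + sqrt(1/9 + 2.76 r2'))/(2 r2')`; for S < 30,
#' `E(r2_sample) = 0.0018 + 0.907/S + 4.44/S^2` and
#' `Ne = (0.308 + sqrt(0.308^2 + 2.08 r2'))/(2 r2')`. Parametric 95%
#' confidence bounds put `n_pairs * mean_r2 / chi-square` quantiles through
#' the same transformation.
#'
#' @param mean_r2 Mean squared correlation (or a [burrows_r2()] row, in
#'   which case the other arguments are taken from it).
#' @param n_pairs Number of SNP pairs behind the mean.
#' @param harmonic_s Harmonic mean sample size per pairwise comparison.
#' @param population Optional label carried into the output.
#' @return A one-row tibble of class `ne_estimate`: `population`,
#'   `ne_point`, `ci_low`, `ci_high`, `mean_r2`, `r2_drift`, `n_pairs`,
#'   `harmonic_s`. `ne_point` is `Inf` when no drift signal remains.
#' @export
ldne_estimate <- function(mean_r2, n_pairs = NULL, harmonic_s = NULL,
                          population = NA_character_) {
  if (is.data.frame(mean_r2)) {
    n_pairs <- mean_r2$n_pairs
    harmonic_s <- mean_r2$harmonic_s
    mean_r2 <- mean_r2$mean_r2
  }
  if (n_pairs < 2) stop_isopop("need at least 2 SNP pairs")
  S <- harmonic_s
  sample_term <- function(S) {
    if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
  }
  ne_of <- function(r2p) {
    if (!is.finite(r2p) || r2p <= 0) return(Inf)
    if (S >= 30) (1 / 3 + sqrt(1 / 9 + 2.76 * r2p)) / (2 * r2p)
    else (0.308 + sqrt(0.308^2 + 2.08 * r2p)) / (2 * r2p)
  }
  r2d <- mean_r2 - sample_term(S)
  ne <- ne_of(r2d)
  r2_lo <- n_pairs * mean_r2 / qchisq(0.975, df = n_pairs)
  r2_hi <- n_pairs * mean_r2 / qchisq(0.025, df = n_pairs)
  ci <- sort(c(ne_of(r2_lo - sample_term(S)), ne_of(r2_hi - sample_term(S))))
  out <- tibble(population = population, ne_point = ne,
                ci_low = ci[1], ci_high = ci[2], mean_r2 = mean_r2,
                r2_drift = r2d, n_pairs = n_pairs, harmonic_s = S)
  class(out) <- c("ne_estimate", class(out))
  out
}

#' Per-population LD effective-size estimates
#'
#' Convenience wrapper: [burrows_r2()] then [ldne_estimate()] for every
#' population with at least `min_s` individuals.
#'
#' @param ds A `geno_ds`.
#' @param min_s Minimum population sample size (default 10).
#' @param ... Passed to [burrows_r2()].
#' @return Tibble with one `ne_estimate` row per population.
#' @export
estimate_ne <- function(ds, min_s = 10L, ...) {
  pops <- unique(ds$meta$population)
  purrr::map_dfr(pops, function(p) {
    s <- sum(ds$meta$population == p)
    if (s < min_s) {
      inform(sprintf("population %s has %d < %d samples; skipped", p, s, min_s))
      return(NULL)
    }
    ldne_estimate(burrows_r2(ds, population = p, ...), population = p)
  })
}
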