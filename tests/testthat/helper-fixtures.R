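# Shared fixtures and independent brute-force oracles for the suite.

.fixture_env <- new.env(parent = emptyenv())

# The bundled study-design fixture is expensive; build it once per run.
study_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    .fixture_env$fx <- make_study_fixture(seed = 101L)
  }
  .fixture_env$fx
}

# Intra-population measures of the study fixture, computed once.
fixture_measures <- function() {
  if (!is.null(.fixture_env$meas)) return(.fixture_env$meas)
  fx <- study_fixture()
  ds <- fx$ds
  seg <- scan_roh(ds)
  mix <- classify_roh_lengths(seg, max_k = 6L, seed = 11L)
  genome_bp <- 4e8
  fr <- froh(mix$segments, genome_bp = genome_bp,
             sample_ids = ds$meta$sample_id)
  froh_pop <- dplyr::left_join(fr, ds$meta[, c("sample_id", "population")],
                               by = "sample_id") |>
    dplyr::group_by(population) |>
    dplyr::summarise(mean_froh = mean(froh), .groups = "drop")
  het <- observed_heterozygosity(ds)
  disp <- interlocus_dispersion(ds)
  ibs <- pairwise_ibs(ds)
  intra <- intra_population_ibs(ibs, ds$meta)
  ld <- ld_block_summary(ds)
  wint <- purrr::map_dfr(unique(ds$meta$population), function(p) {
    ids <- ds$meta$sample_id[ds$meta$population == p]
    dplyr::mutate(w_int(fx$ibd, ids), population = p, .before = 1)
  })
  profiles <- build_profiles(het, disp, roh_population_summary(mix$segments,
                                                              ds$meta),
                             intra, wint, ld, froh_pop)
  profiles <- dplyr::left_join(
    profiles, dplyr::distinct(ds$meta, population, group), by = "population")
  .fixture_env$meas <- list(
    fx = fx, segments = mix$segments, mixture = mix, froh = fr,
    froh_pop = froh_pop, het = het, disp = disp, ibs = ibs, intra = intra,
    ld = ld, wint = wint, profiles = profiles, genome_bp = genome_bp)
  .fixture_env$meas
}

# quick geno_ds builder
toy_ds <- function(geno, chrom = NULL, pos = NULL, population = "P",
                   group = "open", lat = NULL, lon = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  chrom <- chrom %||% rep("1", m)
  if (is.null(pos)) {
    pos <- integer(m)
    for (cc in unique(chrom)) {
      pos[chrom == cc] <- seq_len(sum(chrom == cc)) * 1000L
    }
  }
  map <- data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
                    pos_bp = as.integer(pos), a1 = "A", a2 = "B")
  meta <- data.frame(sample_id = rownames(geno) %||% paste0("i", seq_len(n)),
                     population = rep_len(population, n),
                     group = rep_len(group, n))
  if (!is.null(lat)) { meta$lat <- rep_len(lat, n); meta$lon <- rep_len(lon, n) }
  geno_dataset(geno, map, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force RoH reference, written directly from the windowing rule with
# explicit loops; deliberately independent of the package implementation.
roh_brute <- function(g, pos, p = roh_params()) {
  m <- length(g); W <- p$window_snps
  out <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                    n_snps = integer(0))
  if (m < W) return(out)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  nw <- m - W + 1L
  pass <- logical(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + W - 1L)
    pass[i] <- sum(het[idx]) <= p$window_het_max &&
      sum(mis[idx]) <= p$window_missing_max
  }
  elig <- logical(m)
  for (j in seq_len(m)) {
    starts <- max(1L, j - W + 1L):min(j, nw)
    elig[j] <- mean(pass[starts]) > p$hit_threshold
  }
  j <- 1L
  while (j <= m) {
    if (!elig[j]) { j <- j + 1L; next }
    k <- j
    while (k < m && elig[k + 1L]) k <- k + 1L
    a <- j; b <- k
    while (a <= b && !hom[a]) a <- a + 1L
    while (b >= a && !hom[b]) b <- b - 1L
    if (a <= b) {
      ns <- b - a + 1L
      len <- pos[b] - pos[a]
      if (ns >= p$min_segment_snps && len >= p$min_segment_bp) {
        out <- rbind(out, data.frame(start_bp = pos[a], end_bp = pos[b],
                                     n_snps = ns))
      }
    }
    j <- k + 1L
  }
  out
}

# Brute-force W_int: explicit double loop over individual pairs.
wint_brute <- function(segments, ids, use_cm = FALSE) {
  n <- length(ids)
  tot <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    sel <- (segments$sample_a == ids[a] & segments$sample_b == ids[b]) |
      (segments$sample_a == ids[b] & segments$sample_b == ids[a])
    if (any(sel)) {
      tot <- tot + if (use_cm) sum(segments$length_cm[sel])
                   else sum(segments$length_bp[sel])
    }
  }
  tot / (n * (n - 1) / 2)
}

# Least-squares rigid Procrustes residual (rotation + translation only).
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sum((Xc - Yc %*% R)^2)
}
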