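test_that("scanner matches the brute-force reference on constructed vectors", {
  p <- roh_params()
  # long homozygous stretch flanked by heterozygous runs
  n <- 200
  g <- rep(1L, n)
  g[71:130] <- 0L
  pos <- as.integer(seq(1, by = 21000, length.out = n))
  ds <- toy_ds(matrix(g, 1))
  ds$map$pos_bp <- pos
  got <- scan_roh(ds, p)
  ref <- roh_brute(g, pos, p)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start_bp, ref$start_bp)
  expect_equal(got$end_bp, ref$end_bp)
  expect_equal(got$n_snps, ref$n_snps)
  # all-heterozygous individual: nothing
  expect_equal(nrow(scan_roh(toy_ds(matrix(1L, 1, 100)), p)), 0L)
})

test_that("sub-threshold runs are rejected on SNP count and on length", {
  p <- roh_params()
  mk <- function(n_hom, span_bp, n_flank = 80) {
    g <- c(rep(1L, n_flank), rep(0L, n_hom), rep(1L, n_flank))
    m <- length(g)
    pos <- integer(m)
    pos[1:n_flank] <- seq(1, by = 1000, length.out = n_flank)
    pos[n_flank + (1:n_hom)] <- as.integer(
      seq(pos[n_flank] + 1000, by = span_bp / (n_hom - 1),
          length.out = n_hom))
    pos[(n_flank + n_hom + 1):m] <- seq(pos[n_flank + n_hom] + 1000,
                                        by = 1000, length.out = n_flank)
    list(g = g, pos = as.integer(pos))
  }
  # 24 homozygous SNPs over 0.6 Mb: fails the SNP-count threshold
  a <- mk(24, 6e5)
  # 30 homozygous SNPs over 0.4 Mb: fails the length threshold
  b <- mk(30, 4e5)
  for (case in list(a, b)) {
    ds <- toy_ds(matrix(case$g, 1))
    ds$map$pos_bp <- case$pos
    got <- scan_roh(ds, p)
    ref <- roh_brute(case$g, case$pos, p)
    expect_equal(nrow(got), 0L)
    expect_equal(nrow(ref), 0L)
  }
  # 60 homozygous SNPs over 1.2 Mb passes both
  c3 <- mk(60, 1.2e6)
  ds <- toy_ds(matrix(c3$g, 1))
  ds$map$pos_bp <- c3$pos
  expect_equal(nrow(scan_roh(ds, p)), 1L)
})

test_that("scanner equals brute force on random genotype vectors", {
  set.seed(31)
  p <- roh_params(window_snps = 10L, window_het_max = 1L,
                  window_missing_max = 2L, min_segment_bp = 5e4,
                  min_segment_snps = 8L)
  for (rep in 1:25) {
    m <- 120
    # blocks of homozygosity embedded in noisy heterozygous background
    g <- rbinom(m, 1L, 0.35)
    start <- sample(1:(m - 30), 1)
    g[start:(start + sample(10:30, 1))] <- 0L
    g[sample(m, 3)] <- NA
    pos <- sort(sample.int(1e6, m))
    ds <- toy_ds(matrix(as.integer(g), 1))
    ds$map$pos_bp <- pos
    got <- scan_roh(ds, p)
    ref <- roh_brute(as.integer(g), pos, p)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start_bp, ref$start_bp)
      expect_equal(got$end_bp, ref$end_bp)
      expect_equal(got$n_snps, ref$n_snps)
    }
  }
})

test_that("segments never overlap, respect thresholds, and ignore allele labels", {
  meas <- fixture_measures()
  seg <- meas$segments
  p <- roh_params()
  expect_true(all(seg$n_snps >= p$min_segment_snps))
  expect_true(all(seg$length_bp >= p$min_segment_bp))
  by_ind <- split(seg, paste(seg$sample_id, seg$chrom))
  for (s in by_ind) {
    if (nrow(s) < 2) next
    s <- s[order(s$start_bp), ]
    expect_true(all(s$start_bp[-1] >= s$end_bp[-nrow(s)]))
  }
  # allele relabelling (dosage flip) leaves hom/het status unchanged
  ds <- study_fixture()$ds
  sub <- subset_geno(ds, samples = ds$meta$sample_id[1:3])
  flipped <- sub
  flipped$geno <- 2L - flipped$geno
  expect_equal(scan_roh(sub), scan_roh(flipped))
})

test_that("relaxing the SNP-count threshold never loses segments", {
  ds <- study_fixture()$ds
  sub <- subset_geno(ds, samples = ds$meta$sample_id[
    ds$meta$population == "isol1"])
  strict <- scan_roh(sub, roh_params(min_segment_snps = 25L))
  relaxed <- scan_roh(sub, roh_params(min_segment_snps = 12L))
  expect_gte(nrow(relaxed), nrow(strict))
})

test_that("short chromosomes are skipped with a warning", {
  ds <- toy_ds(matrix(0L, 1, 10))
  expect_warning(out <- scan_roh(ds), "too few SNPs")
  expect_equal(nrow(out), 0L)
})

test_that("mixture picks one component for a single tight cluster", {
  set.seed(41)
  seg <- tibble::tibble(length_bp = rnorm(300, 1e6, 1e4))
  fit <- classify_roh_lengths(seg, max_k = 4L, seed = 1L)
  expect_equal(fit$k, 1L)
  expect_equal(fit$means, 1e6, tolerance = 0.01)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("mixture recovers two well-separated components", {
  set.seed(42)
  seg <- tibble::tibble(length_bp = c(rnorm(200, 6e5, 5e4),
                                      rnorm(200, 5e6, 5e4)))
  fit <- classify_roh_lengths(seg, max_k = 6L, seed = 2L)
  expect_equal(fit$k, 2L)
  se1 <- 5e4 / sqrt(200)
  expect_lt(abs(fit$means[1] - 6e5), 3 * se1)
  expect_lt(abs(fit$means[2] - 5e6), 3 * se1)
  expect_true(all(diff(fit$means) > 0))   # classes ordered by mean
  # class assignment follows maximum responsibility
  expect_equal(as.vector(table(fit$segments$class)), c(200, 200),
               tolerance = 0.02)
  # independent cross-check: model-based clustering agrees on k
  if (requireNamespace("mclust", quietly = TRUE)) {
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
    mc <- mclust::Mclust(seg$length_bp / 1e6, G = 1:6, verbose = FALSE)
    expect_equal(mc$G, 2L)
  }
})

test_that("selected class count never exceeds max_k", {
  meas <- fixture_measures()
  expect_lte(meas$mixture$k, 6L)
  expect_equal(sum(meas$mixture$weights), 1, tolerance = 1e-9)
  expect_error(classify_roh_lengths(tibble::tibble(length_bp = c(1, 2, 3)),
                                    max_k = 6L), "segments")
})

test_that("F_ROH arithmetic handles masks by interval subtraction", {
  seg <- tibble::tibble(sample_id = "x", chrom = c("1", "1"),
                        start_bp = c(1e6, 5e7), end_bp = c(11e6, 7e7))
  # 10 Mb + 20 Mb on a 1000 Mb genome with a non-intersecting 100 Mb mask
  mask <- tibble::tibble(chrom = "2", start_bp = 1, end_bp = 1e8 + 1)
  out <- froh(seg, genome_bp = 1e9, mask = mask)
  expect_equal(out$froh, 30 / 900, tolerance = 1e-12)
  # mask overlapping a segment removes the overlap from the numerator
  mask2 <- tibble::tibble(chrom = "1", start_bp = 6e6, end_bp = 8e6)
  out2 <- froh(seg, genome_bp = 1e9, mask = mask2)
  expect_equal(out2$froh, (30e6 - 2e6) / (1e9 - 2e6))
  expect_equal(froh(seg[0, ], 1e9, sample_ids = "x")$froh, 0)
  expect_error(froh(seg, genome_bp = 1e6,
                    mask = tibble::tibble(chrom = "1", start_bp = 1,
                                          end_bp = 2e6)), "mask")
})

test_that("population summary averages counts and normalizes class shares", {
  seg <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 2), chrom = "1",
    start_bp = 1e6 * c(1, 3, 5, 7), end_bp = 1e6 * c(2, 4, 6, 8),
    length_bp = rep(1e6, 4), n_snps = 30L, class = c(1L, 2L, 1L, 1L))
  meta <- data.frame(sample_id = c("a", "b"), population = "P",
                     group = "open")
  s <- roh_population_summary(seg, meta)
  expect_equal(s$mean_roh_count, 2)
  expect_equal(s$mean_roh_total_bp, 2e6)
  expect_equal(s$class_prop_1 + s$class_prop_2, 1, tolerance = 1e-12)
  meas <- fixture_measures()
  sums <- rowSums(as.matrix(meas$profiles[
    , grep("^class_prop_", names(meas$profiles))]))
  pops_with_segments <- unique(meas$segments$sample_id)
  expect_true(all(abs(sums[meas$profiles$mean_roh_count > 0] - 1) < 1e-12))
})

test_that("isolated fixture demes carry the heavier RoH burden", {
  meas <- fixture_measures()
  pr <- meas$profiles
  expect_gt(min(pr$mean_roh_total_bp[pr$group == "isolated"]),
            max(pr$mean_roh_total_bp[pr$group == "open"]))
})
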