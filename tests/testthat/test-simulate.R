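small_demes <- function(ne = 20L, n = 1) {
  data.frame(name = paste0("d", seq_len(n)), group = "isolated", ne = ne)
}

test_that("zero generations leaves founder pairs with zero autozygosity", {
  cfg <- demography_config(small_demes(10L), n_generations = 0L,
                           n_chrom = 2L, chrom_bp = 1e6,
                           snps_per_chrom = 20L, seed = 2L)
  co <- simulate_cohort(cfg)
  az <- autozygosity(co)
  expect_equal(nrow(az), 10L)
  expect_true(all(az$autozygosity == 0))
})

test_that("mosaic tiles partition every chromosome", {
  cfg <- demography_config(small_demes(15L), n_generations = 12L,
                           n_chrom = 3L, chrom_bp = 5e7,
                           snps_per_chrom = 10L, seed = 8L)
  co <- simulate_cohort(cfg)
  for (ind in co$demes[[1]]) for (hap in ind) for (mo in hap) {
    expect_equal(mo$bp[1], 1)
    expect_true(all(diff(mo$bp) > 0))
    expect_true(all(mo$bp < cfg$chrom_bp + 1))
    expect_equal(length(mo$bp), length(mo$fid))
    # adjacent tiles never repeat a founder id (they would be merged)
    if (length(mo$fid) > 1) expect_true(all(diff(mo$fid) != 0))
  }
})

test_that("expected inbreeding matches the per-generation recursion oracle", {
  # oracle: iterate F' = F + (1 - F) / (2 Ne)
  rec <- function(ne, t) {
    f <- 0
    for (i in seq_len(t)) f <- f + (1 - f) / (2 * ne)
    f
  }
  expect_equal(expected_inbreeding(100, 0), 0)
  expect_equal(expected_inbreeding(100, 50), rec(100, 50), tolerance = 1e-10)
  expect_equal(expected_inbreeding(100, 50), 0.221687, tolerance = 1e-5)
  for (ne in c(1, 10, 500)) {
    t <- 0:20
    f <- expected_inbreeding(ne, t)
    expect_true(all(diff(f) > 0))  # strictly increasing in t
  }
})

test_that("mean autozygosity calibrates to the closed form at N = 200, t = 10", {
  set.seed(21)
  az <- replicate(12, {
    cfg <- demography_config(small_demes(200L), n_generations = 10L,
                             n_chrom = 4L, chrom_bp = 1e8,
                             snps_per_chrom = 5L,
                             seed = sample.int(1e6, 1))
    mean(autozygosity(simulate_cohort(cfg))$autozygosity)
  })
  target <- expected_inbreeding(200, 10)
  se <- sd(az) / sqrt(length(az))
  expect_lt(abs(mean(az) - target), 3 * se + 1e-4)
})

test_that("genotypes equal the sum of the founder alleles addressed by tiles", {
  cfg <- demography_config(small_demes(8L), n_generations = 3L,
                           n_chrom = 2L, chrom_bp = 1e7,
                           snps_per_chrom = 25L, seed = 5L)
  co <- simulate_cohort(cfg)
  ds <- emit_dataset(co, 8L)
  pos <- isopop:::snp_positions(cfg)
  sampled <- attr(ds, "sampled")
  for (k in c(1L, 5L)) {
    ind <- co$demes[[1]][[sampled$idx[k]]]
    for (cc in 1:2) {
      cols <- (cc - 1) * 25 + 1:25
      f1 <- isopop:::fid_at(ind[[1]][[cc]], pos)
      f2 <- isopop:::fid_at(ind[[2]][[cc]], pos)
      raw <- vapply(seq_along(pos), function(s)
        isopop:::founder_alleles(co, f1[s], cc)[s] +
          isopop:::founder_alleles(co, f2[s], cc)[s], numeric(1))
      got <- ds$geno[k, cols]
      flipped <- ds$map$a1[cols] == "B"
      expect_equal(unname(got), as.integer(ifelse(flipped, 2 - raw, raw)))
    }
  }
  expect_error(emit_dataset(co, 30L), "has 8")
})

test_that("monomorphic founders yield monomorphic columns", {
  cfg <- demography_config(small_demes(6L), n_generations = 2L,
                           n_chrom = 1L, chrom_bp = 1e6,
                           snps_per_chrom = 10L,
                           founder_maf = c(1e-9, 1e-9), seed = 3L)
  ds <- emit_dataset(simulate_cohort(cfg), 6L)
  expect_true(all(apply(ds$geno, 2, function(x) length(unique(x))) == 1))
})

test_that("ground-truth IBD matches a hand-constructed mosaic intersection", {
  cfg <- demography_config(small_demes(4L), n_generations = 0L,
                           n_chrom = 1L, chrom_bp = 1e7,
                           snps_per_chrom = 5L, seed = 1L)
  co <- simulate_cohort(cfg)
  L <- cfg$chrom_bp
  # overwrite mosaics with known breakpoints
  # ind1 hap1: founder 1 on [1, 4e6), founder 2 on [4e6, L+1)
  co$demes[[1]][[1]][[1]][[1]] <- list(bp = c(1, 4e6), fid = c(1L, 2L))
  co$demes[[1]][[1]][[2]][[1]] <- list(bp = 1, fid = 3L)
  # ind2 hap1: founder 2 on [2e6, 7e6) -> overlap with ind1 on [4e6, 7e6)
  co$demes[[1]][[2]][[1]][[1]] <- list(bp = c(1, 2e6, 7e6),
                                       fid = c(9L, 2L, 10L))
  co$demes[[1]][[2]][[2]][[1]] <- list(bp = 1, fid = 11L)
  # ind3 shares founder 3 everywhere with ind1 hap2
  co$demes[[1]][[3]][[1]][[1]] <- list(bp = 1, fid = 3L)
  co$demes[[1]][[3]][[2]][[1]] <- list(bp = 1, fid = 12L)
  # ind4 disjoint founders
  co$demes[[1]][[4]][[1]][[1]] <- list(bp = 1, fid = 13L)
  co$demes[[1]][[4]][[2]][[1]] <- list(bp = 1, fid = 14L)
  seg <- true_ibd_segments(co, min_bp = 1e6)
  d1 <- function(i) paste0("d1_", i)
  s12 <- seg[seg$sample_a == d1(1) & seg$sample_b == d1(2), ]
  expect_equal(nrow(s12), 1L)
  expect_equal(s12$start_bp, 4e6)
  expect_equal(s12$end_bp, 7e6)
  expect_equal(s12$length_cm, 3)   # 3 Mb at 1 cM/Mb
  s13 <- seg[seg$sample_a == d1(1) & seg$sample_b == d1(3), ]
  expect_equal(s13$length_bp, 1e7) # whole chromosome
  expect_false(any(seg$sample_b == d1(4) | seg$sample_a == d1(4)))
})

test_that("strong migration erases the within/between deme IBS contrast", {
  demes <- data.frame(name = c("a", "b"), group = "open", ne = 40L)
  mig <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  cfg <- demography_config(demes, n_generations = 12L, n_chrom = 4L,
                           chrom_bp = 2e7, snps_per_chrom = 250L,
                           migration = mig, seed = 6L)
  ds <- emit_dataset(simulate_cohort(cfg), 30L)
  ibs <- pairwise_ibs(ds)
  pop <- ds$meta$population
  within <- c(ibs[pop == "a", pop == "a"][upper.tri(diag(30))],
              ibs[pop == "b", pop == "b"][upper.tri(diag(30))])
  between <- ibs[pop == "a", pop == "b"]
  expect_lt(abs(mean(within) - mean(between)), 0.005)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- demography_config(small_demes(10L), n_generations = 5L,
                           n_chrom = 2L, chrom_bp = 1e7,
                           snps_per_chrom = 50L, seed = 77L)
  ds1 <- emit_dataset(simulate_cohort(cfg), 10L)
  ds2 <- emit_dataset(simulate_cohort(cfg), 10L)
  expect_identical(ds1$geno, ds2$geno)
  cfg2 <- demography_config(small_demes(10L), n_generations = 5L,
                            n_chrom = 2L, chrom_bp = 1e7,
                            snps_per_chrom = 50L, seed = 78L)
  ds3 <- emit_dataset(simulate_cohort(cfg2), 10L)
  expect_false(identical(ds1$geno, ds3$geno))
})

test_that("selfing can be excluded, which then forbids demes of size 1", {
  expect_error(demography_config(small_demes(1L), n_generations = 1L,
                                 allow_selfing = FALSE), "size 1")
  cfg <- demography_config(small_demes(5L), n_generations = 3L,
                           n_chrom = 1L, chrom_bp = 1e6,
                           snps_per_chrom = 5L, allow_selfing = FALSE,
                           seed = 4L)
  expect_s3_class(simulate_cohort(cfg), "sim_cohort")
})

test_that("study fixture separates isolated from open demes on drift signals", {
  meas <- fixture_measures()
  truth <- meas$fx$truth
  fp <- dplyr::left_join(meas$froh_pop, truth, by = "population")
  expect_gt(min(fp$mean_froh[fp$group == "isolated"]),
            max(fp$mean_froh[fp$group == "open"]))
  # F_ROH tracks the closed-form expectation reasonably (detector misses
  # sub-threshold segments, so it may undershoot but not overshoot wildly)
  iso <- fp[fp$group == "isolated", ]
  expect_true(all(iso$mean_froh > 0.4 * iso$expected_f))
  expect_true(all(iso$mean_froh < 1.5 * iso$expected_f))
})
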