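profile_like <- function(n = 8, seed = 71) {
  set.seed(seed)
  tibble::tibble(
    population = paste0("P", seq_len(n)),
    group = rep(c("open", "isolated"), length.out = n),
    hom = runif(n, 0.6, 0.8),
    mean_roh_total_bp = runif(n, 1e6, 5e7),
    mean_intra_ibs = runif(n, 0.6, 0.8),
    w_int = runif(n, 0, 5))
}

test_that("PCA matches an SVD oracle up to sign and normalizes variance", {
  pr <- profile_like(10)
  pca <- isolation_pca(pr)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)
  X <- scale(as.matrix(pr[, c("hom", "mean_roh_total_bp",
                              "mean_intra_ibs", "w_int")]))
  sv <- svd(X)
  oracle_scores <- sv$u %*% diag(sv$d)
  for (j in 1:4) {
    expect_equal(abs(unname(pca$scores[, j])), abs(oracle_scores[, j]),
                 tolerance = 1e-9)
  }
  # orthogonal components
  G <- crossprod(pca$loadings)
  expect_equal(unname(G), diag(4), tolerance = 1e-9)
  # variance fractions equal normalized squared singular values
  expect_equal(unname(pca$variance_fraction),
               sv$d^2 / sum(sv$d^2), tolerance = 1e-9)
  # sign convention: anchor loading positive on PC1
  expect_gt(pca$loadings["mean_roh_total_bp", 1], 0)
})

test_that("rank-1 structure loads everything on one component", {
  pr <- tibble::tibble(
    population = paste0("P", 1:6),
    mean_roh_total_bp = c(1, 2, 3, 4, 5, 6) * 1e6)
  pr$hom <- pr$mean_roh_total_bp / 1e7   # perfectly correlated
  pr$flat <- 1                            # constant -> dropped
  expect_warning(pca <- isolation_pca(pr), "constant")
  expect_equal(pca$variance_fraction[1], 1, tolerance = 1e-12)
  expect_error(isolation_pca(pr[1:2, ]), "3 populations")
})

test_that("group comparisons reproduce exact Mann-Whitney enumeration", {
  # fully separated groups, n1 = n2 = 10: two-sided exact p = 2 / C(20,10)
  d <- tibble::tibble(group = rep(c("open", "isolated"), each = 10),
                      x = c(1:10, 101:110) + 0)
  out <- group_compare(d, measures = "x", n_measures = 7)
  expect_equal(out$mw_p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(out$alpha_bonferroni, 0.007)
  expect_true(out$significant_bonferroni)
  # identical multisets -> p = 1 under the approximation
  d2 <- tibble::tibble(group = rep(c("open", "isolated"), each = 12),
                       x = rep(c(1, 2, 3, 4), 6))
  out2 <- group_compare(d2, measures = "x")
  expect_equal(out2$mw_p, 1, tolerance = 1e-9)
  # invariant to row order
  d3 <- d[sample(nrow(d)), ]
  expect_equal(group_compare(d3, measures = "x")$mw_p, out$mw_p)
  expect_error(group_compare(tibble::tibble(group = "open", x = 1),
                             measures = "x"), "two non-empty")
})

test_that("distance matrices and population averages are consistent", {
  ibs <- rbind(c(1, 0.9, 0.8), c(0.9, 1, 0.6), c(0.8, 0.6, 1))
  dimnames(ibs) <- list(c("a", "b", "c"), c("a", "b", "c"))
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         population = c("P1", "P1", "P2"),
                         group = c("open", "open", "isolated"))
  dm <- distance_matrix(ibs, meta)
  expect_equal(dm$dist["a", "b"], 0.1)
  avg <- dm$population_avg
  # P1 inter-population pairs: (a,c) and (b,c) -> mean(0.2, 0.4) = 0.3
  expect_equal(avg$avg_distance[avg$population == "P1"], 0.3)
  expect_equal(avg$avg_distance[avg$population == "P2"], 0.3)
})

test_that("great-circle distances use the 6371 km haversine", {
  coords <- tibble::tibble(population = c("rome", "paris"),
                           lat = c(41.9, 48.85), lon = c(12.5, 2.35))
  m <- geographic_distances(coords)
  expect_equal(m["rome", "paris"], 1106, tolerance = 2 / 1106)
  expect_equal(m["rome", "paris"], m["paris", "rome"])
  expect_equal(m["rome", "rome"], 0)
  coords$lat[2] <- NA
  expect_error(geographic_distances(coords), "paris")
})

test_that("isolation-by-distance residuals recover a constructed offset", {
  pops <- paste0("P", 1:6)
  geo <- as.matrix(dist(1:6)) * 100
  dimnames(geo) <- list(pops, pops)
  gen <- 0.001 + 0.0002 * geo           # exact line
  gen["P1", "P2"] <- gen["P2", "P1"] <- gen["P1", "P2"] + 0.02
  reg <- ibd_distance_regression(gen, geo, open_populations = pops[3:6])
  expect_equal(reg$slope, 2e-4, tolerance = 1e-10)
  expect_equal(reg$r_squared_open, 1, tolerance = 1e-9)
  off <- reg$pairs[reg$pairs$pop_a == "P1" & reg$pairs$pop_b == "P2", ]
  expect_equal(off$residual, 0.02, tolerance = 1e-12)
  others <- reg$pairs$residual[!(reg$pairs$pop_a == "P1" &
                                   reg$pairs$pop_b == "P2")]
  expect_true(all(abs(others) < 1e-12))
  expect_error(ibd_distance_regression(gen, geo * 0, pops[3:6]),
               "geographic variance")
})

test_that("a stepping-stone arrangement shows isolation by distance", {
  # 4 demes in a line with nearest-neighbour migration
  demes <- data.frame(name = paste0("d", 1:4), group = "open", ne = 30L,
                      lat = 40 + 0:3 * 2, lon = rep(10, 4))
  mig <- matrix(0, 4, 4)
  for (i in 1:3) { mig[i, i + 1] <- 0.05; mig[i + 1, i] <- 0.05 }
  cfg <- demography_config(demes, n_generations = 25L, n_chrom = 4L,
                           chrom_bp = 2e7, snps_per_chrom = 300L,
                           migration = mig, seed = 72L)
  ds <- emit_dataset(simulate_cohort(cfg), 20L)
  ibs <- pairwise_ibs(ds)
  pop_d <- isopop:::population_distance(ibs, ds$meta)
  geo <- geographic_distances(
    tibble::tibble(population = demes$name, lat = demes$lat,
                   lon = demes$lon))
  reg <- ibd_distance_regression(pop_d, geo[rownames(pop_d),
                                            rownames(pop_d)],
                                 open_populations = demes$name)
  expect_gt(reg$slope, 0)
})

test_that("classical MDS reconstructs a planar configuration", {
  set.seed(73)
  X <- cbind(runif(12, -5, 5), runif(12, -5, 5))
  d <- as.matrix(dist(X))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  mds <- classical_mds(d, k = 2)
  Y <- as.matrix(mds$coordinates[, c("dim1", "dim2")])
  expect_lt(procrustes_error(X, Y), 1e-8)
  # independent cross-check of the embedding via a second implementation
  if (requireNamespace("vegan", quietly = TRUE)) {
    pv <- vegan::procrustes(X, Y, scale = FALSE)
    expect_lt(pv$ss, 1e-8)
  }
  # dimensions ordered by eigenvalue ratio
  expect_gte(mds$eigenvalue_ratio[1], mds$eigenvalue_ratio[2])
  # duplicated individual lands on identical coordinates
  d2 <- rbind(cbind(d, d[, 1]), c(d[1, ], 0))
  dimnames(d2) <- list(c(rownames(d), "dup"), c(rownames(d), "dup"))
  mds2 <- classical_mds(d2, k = 2)
  co <- as.matrix(mds2$coordinates[, c("dim1", "dim2")])
  expect_equal(co[1, ], co[13, ], tolerance = 1e-9)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(classical_mds(d, k = 12), "n - 1")
})

test_that("complete-linkage clustering merges the closest pair first", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- hierarchical_cluster(d)
  expect_equal(sort(cl$hclust$labels[-cl$hclust$merge[1, ]]), c("A", "B"))
  expect_equal(cl$hclust$height[1], 1)
  expect_match(cl$newick, "A")
  d2 <- d[1:2, 1:2]
  cl2 <- hierarchical_cluster(d2)
  expect_equal(cl2$hclust$height, 1)
})

test_that("score regression recovers constructed coefficients", {
  set.seed(74)
  pr <- tibble::tibble(population = paste0("P", 1:12),
                       f_roh = runif(12, 0, 0.2))
  sc <- tibble::tibble(population = pr$population,
                       PC1 = 2 * pr$f_roh + rnorm(12, 0, 1e-8))
  reg <- regress_scores(sc, pr)
  expect_equal(unname(reg$coefficients$estimate[2]), 2, tolerance = 1e-4)
  expect_equal(reg$r_squared, 1, tolerance = 1e-6)
  # noise-free construction with two predictors
  pr$ne <- runif(12, 100, 1000)
  sc2 <- tibble::tibble(population = pr$population,
                        PC1 = 1 + 3 * pr$f_roh - 0.001 * pr$ne)
  reg2 <- regress_scores(sc2, pr)
  expect_equal(reg2$r_squared, 1, tolerance = 1e-9)
  # collinear predictors are rejected
  pr$f2 <- pr$f_roh * 2
  expect_error(regress_scores(sc2, pr), "collinear")
  # single predictor equals the simple regression slope
  reg3 <- regress_scores(sc, pr[, c("population", "f_roh")])
  expect_equal(unname(reg3$coefficients$estimate[2]),
               unname(coef(lm(sc$PC1 ~ pr$f_roh))[2]))
})

test_that("fixture MDS scatters isolated individuals more widely", {
  meas <- fixture_measures()
  md <- classical_mds(1 - meas$ibs, k = 2, meta = meas$fx$ds$meta)
  ct <- md$coordinates
  spread <- function(grp) {
    sub <- ct[ct$group == grp, ]
    mean(tapply(seq_len(nrow(sub)), sub$population, function(i)
      sd(sub$dim1[i]) + sd(sub$dim2[i])))
  }
  expect_gt(spread("isolated"), spread("open"))
})
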