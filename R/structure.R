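#' Principal-component ranking of population isolation profiles
#'
#' Standardizes the intra-population measures to zero mean and unit
#' variance, eigen-decomposes their correlation matrix, and returns scores,
#' loadings and variance fractions. Constant variables are dropped with a
#' warning. The sign of each component is fixed so that the loading of
#' `sign_variable` (default `mean_roh_total_bp`) on component 1 is positive,
#' making isolated populations score consistently on the same side.
#'
#' @param profiles Profile tibble from [build_profiles()] (or any data frame
#'   with a `population` column, optional `group`, and numeric measures).
#' @param sign_variable Variable anchoring the sign convention.
#' @return An `isolation_pca` object with `scores`, `loadings`,
#'   `variance_fraction`; methods [tidy()], [glance()], [autoplot()].
#' @export
isolation_pca <- function(profiles, sign_variable = "mean_roh_total_bp") {
  profiles <- as_tibble(profiles)
  if (nrow(profiles) < 3) stop_isopop("need at least 3 populations")
  num <- vapply(profiles, is.numeric, logical(1))
  vars <- names(profiles)[num]
  X <- as.matrix(profiles[, vars, drop = FALSE])
  rownames(X) <- profiles$population
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping constant variable(s): ",
                paste(vars[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    vars <- vars[sds > 0]
  }
  if (ncol(X) < 2) stop_isopop("fewer than 2 informative variables")
  Z <- scale(X)
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  k <- ncol(Z)
  load <- eig$vectors
  scores <- Z %*% load
  # sign convention
  anchor <- match(sign_variable, vars)
  if (!is.na(anchor)) {
    for (j in seq_len(k)) {
      ref <- if (j == 1) load[anchor, 1] else load[which.max(abs(load[, j])), j]
      if (j == 1 && ref < 0 || j > 1 && ref < 0) {
        load[, j] <- -load[, j]; scores[, j] <- -scores[, j]
      }
    }
  }
  dimnames(load) <- list(vars, paste0("PC", seq_len(k)))
  dimnames(scores) <- list(profiles$population, paste0("PC", seq_len(k)))
  structure(list(
    scores = scores, loadings = load,
    variance_fraction = vals / sum(vals),
    sdev = sqrt(vals),
    populations = profiles$population,
    group = if ("group" %in% names(profiles)) profiles$group else NULL),
    class = "isolation_pca")
}

#' @export
print.isolation_pca <- function(x, ...) {
  cat(sprintf("<isolation_pca> %d populations, %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  vf <- x$variance_fraction
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of total variance\n",
              100 * vf[1], 100 * vf[2]))
  invisible(x)
}

#' @rdname isolation_pca
#' @param x An `isolation_pca`.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.isolation_pca <- function(x, matrix = "scores", ...) {
  switch(matrix,
    scores = {
      out <- as_tibble(x$scores, rownames = "population")
      if (!is.null(x$group)) out <- mutate(out, group = x$group,
                                           .after = "population")
      out
    },
    loadings = as_tibble(x$loadings, rownames = "variable"),
    eigenvalues = tibble(component = seq_along(x$variance_fraction),
                         eigenvalue = x$sdev^2,
                         variance_fraction = x$variance_fraction),
    stop_isopop("matrix must be scores, loadings or eigenvalues"))
}

#' @rdname isolation_pca
#' @export
glance.isolation_pca <- function(x, ...) {
  tibble(n_populations = nrow(x$scores), n_variables = nrow(x$loadings),
         pc1_variance_fraction = x$variance_fraction[1],
         pc2_variance_fraction = x$variance_fraction[2])
}

#' @rdname isolation_pca
#' @param object An `isolation_pca`.
#' @export
autoplot.isolation_pca <- function(object, ...) {
  sc <- tidy(object, "scores")
  vf <- object$variance_fraction
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(object$group)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::geom_text(ggplot2::aes(label = .data$population),
                         vjust = -0.7, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * vf[2])) +
    ggplot2::theme_minimal()
}

#' Open-vs-isolated group comparison of population measures
#'
#' Per measure: a two-sided Mann-Whitney U test of location (exact when the
#' combined sample size is at most 20 and ties are absent, otherwise the
#' normal approximation with tie correction), a Brown-Forsythe/Levene test
#' of variance equality (median-centred), and a Bonferroni-corrected alpha
#' `0.05 / n_measures` rounded to 3 decimals.
#'
#' @param data Data frame with a `group` column and the measure columns.
#' @param measures Character vector of measure columns (default: all numeric
#'   columns).
#' @param n_measures Number of simultaneous comparisons for the Bonferroni
#'   correction (default `length(measures)`).
#' @return Tibble per measure: `mw_p`, `levene_p`, `alpha_bonferroni`,
#'   `significant`, `significant_bonferroni`.
#' @export
group_compare <- function(data, measures = NULL, n_measures = NULL) {
  data <- as_tibble(data)
  if (!"group" %in% names(data)) stop_isopop("data needs a 'group' column")
  g <- factor(data$group)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop_isopop("group must have two non-empty levels")
  }
  measures <- measures %||%
    names(data)[vapply(data, is.numeric, logical(1))]
  n_measures <- n_measures %||% length(measures)
  alpha <- round(0.05 / n_measures, 3)
  purrr::map_dfr(measures, function(mv) {
    x <- data[[mv]]
    n_tot <- length(x)
    exact <- n_tot <= 20 && !any(duplicated(x))
    mw <- suppressWarnings(
      wilcox.test(x ~ g, exact = exact, correct = FALSE))
    lev <- car::leveneTest(x ~ g, center = median)
    tibble(measure = mv, mw_p = mw$p.value,
           levene_p = lev[1, "Pr(>F)"],
           alpha_bonferroni = alpha,
           significant = mw$p.value < 0.05,
           significant_bonferroni = mw$p.value < alpha)
  })
}

#' Genetic distance matrix from identity by state
#'
#' @param ibs IBS matrix from [pairwise_ibs()].
#' @param meta Optional sample metadata; adds per-population average
#'   distances over all inter-population individual pairs.
#' @return List: `dist` (matrix `1 - IBS`) and, with `meta`,
#'   `population_avg` tibble.
#' @export
distance_matrix <- function(ibs, meta = NULL) {
  d <- 1 - ibs
  out <- list(dist = d)
  if (!is.null(meta)) {
    meta <- as_tibble(meta)
    pop <- meta$population[match(rownames(d), meta$sample_id)]
    pops <- unique(pop)
    avg <- vapply(pops, function(p) {
      inside <- pop == p
      mean(d[inside, !inside], na.rm = TRUE)
    }, numeric(1))
    out$population_avg <- tibble(population = pops,
                                 avg_distance = unname(avg)) |>
      arrange(.data$avg_distance)
  }
  out
}

#' Great-circle distances between population sampling sites
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Data frame: `population`, `lat`, `lon` (degrees).
#' @return Symmetric matrix of distances in km.
#' @export
geographic_distances <- function(coords) {
  coords <- as_tibble(coords)
  bad <- !complete.cases(coords[, c("lat", "lon")])
  if (any(bad)) {
    stop_isopop(paste0("missing coordinates for: ",
                       paste(coords$population[bad], collapse = ", ")))
  }
  stopifnot(all(abs(coords$lat) <= 90), all(abs(coords$lon) <= 180))
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(coords$population, coords$population))
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(
      cbind(coords$lon[i], coords$lat[i]),
      cbind(coords$lon, coords$lat), r = 6371000) / 1000
  }
  (m + t(m)) / 2
}

#' Isolation-by-distance regression and residual deviations
#'
#' Fits genetic distance on geographic distance by ordinary least squares
#' over open-population pairs only, then measures every pair's deviation
#' from that line (observed minus predicted) and each population's mean
#' deviation over its pairs.
#'
#' @param gen_dist,geo_dist Symmetric population-level matrices with
#'   matching dimnames.
#' @param open_populations Character vector of open population names.
#' @return List: `slope`, `intercept`, `r_squared_open`, `r_squared_all`,
#'   `pairs` tibble (with `residual`), `population_deviation` tibble.
#' @export
ibd_distance_regression <- function(gen_dist, geo_dist, open_populations) {
  pops <- rownames(gen_dist)
  stopifnot(identical(pops, rownames(geo_dist)))
  ut <- upper.tri(gen_dist)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- tibble(pop_a = pops[idx[, 1]], pop_b = pops[idx[, 2]],
                  gen = gen_dist[ut], geo = geo_dist[ut],
                  open_pair = pops[idx[, 1]] %in% open_populations &
                    pops[idx[, 2]] %in% open_populations)
  open <- filter(pairs, .data$open_pair)
  if (nrow(open) < 3) stop_isopop("need at least 3 open-population pairs")
  if (var(open$geo) == 0) stop_isopop("zero geographic variance among open pairs")
  fit <- lm(gen ~ geo, data = open)
  pairs$predicted <- coef(fit)[1] + coef(fit)[2] * pairs$geo
  pairs$residual <- pairs$gen - pairs$predicted
  fit_all <- lm(gen ~ geo, data = pairs)
  pop_dev <- purrr::map_dfr(pops, function(p) {
    sel <- pairs$pop_a == p | pairs$pop_b == p
    tibble(population = p, mean_deviation = mean(pairs$residual[sel]))
  })
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared_open = summary(fit)$r.squared,
       r_squared_all = summary(fit_all)$r.squared,
       pairs = pairs, population_deviation = pop_dev)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix and eigen-decomposes it;
#' coordinates are eigenvectors scaled by root eigenvalues. Negative
#' eigenvalues are truncated with a warning; the information carried by each
#' dimension is its eigenvalue over the sum of positive eigenvalues.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Number of dimensions (default 2; at most n - 1).
#' @param meta Optional sample metadata joined onto the coordinates.
#' @return An `iso_mds` object: `coordinates` tibble, `eigenvalues`,
#'   `eigenvalue_ratio`; methods [tidy()], [autoplot()].
#' @export
classical_mds <- function(d, k = 2, meta = NULL) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop_isopop("distance matrix must be symmetric")
  }
  n <- nrow(dm)
  if (k > n - 1) stop_isopop("k must be at most n - 1")
  fit <- cmdscale(as.dist(dm), k = k, eig = TRUE)
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warn(sprintf("%d negative eigenvalue(s) truncated", sum(eig < 0)))
  }
  pos <- pmax(eig, 0)
  coords <- fit$points
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  ct <- as_tibble(coords, rownames = "sample_id")
  if (!is.null(meta)) {
    ct <- left_join(ct, as_tibble(meta)[, c("sample_id", "population",
                                            "group")], by = "sample_id")
  }
  structure(list(coordinates = ct, eigenvalues = eig,
                 eigenvalue_ratio = pos[seq_len(k)] / sum(pos)),
            class = "iso_mds")
}

#' @rdname classical_mds
#' @param x An `iso_mds`.
#' @param ... Unused.
#' @export
tidy.iso_mds <- function(x, ...) x$coordinates

#' @rdname classical_mds
#' @param object An `iso_mds`.
#' @export
autoplot.iso_mds <- function(object, ...) {
  ct <- object$coordinates
  p <- ggplot2::ggplot(ct, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if ("population" %in% names(ct)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$population),
                                 size = 1.5)
  } else p <- p + ggplot2::geom_point(size = 1.5)
  p + ggplot2::labs(
    x = sprintf("dim 1 (%.1f%%)", 100 * object$eigenvalue_ratio[1]),
    y = sprintf("dim 2 (%.1f%%)", 100 * object$eigenvalue_ratio[2])) +
    ggplot2::theme_minimal()
}

#' Complete-linkage clustering of populations
#'
#' Agglomerative complete-linkage on a population distance matrix, with
#' deterministic tie-breaking by lexicographic population order.
#'
#' @param pop_dist Symmetric population distance matrix.
#' @return List: `hclust` (the merge tree), `leaf_order`, `newick` string.
#' @export
hierarchical_cluster <- function(pop_dist) {
  dm <- as.matrix(pop_dist)
  if (nrow(dm) < 2) stop_isopop("need at least 2 populations")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- hclust(as.dist(dm), method = "complete")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}

#' Regress principal-component scores on isolation predictors
#'
#' Ordinary least squares of a component's population scores on any subset
#' of predictors (for example the inbreeding coefficient, effective size or
#' time since isolation), with t-based p-values.
#'
#' @param scores Tibble with `population` and score columns (from
#'   [tidy()] on an [isolation_pca()]).
#' @param predictors Tibble with `population` and predictor columns.
#' @param response Score column to model (default `"PC1"`).
#' @return List: `coefficients` tibble (`term`, `estimate`, `std_error`,
#'   `p_value`), `r_squared`, `fit` (the `lm`).
#' @export
regress_scores <- function(scores, predictors, response = "PC1") {
  df <- left_join(as_tibble(scores), as_tibble(predictors),
                  by = "population")
  pred_vars <- setdiff(names(predictors), "population")
  if (nrow(df) < length(pred_vars) + 2) {
    stop_isopop("need at least 2 more populations than predictors")
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(pred_vars, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) stop_isopop("collinear predictors")
  sm <- summary(fit)
  list(coefficients = tibble(term = rownames(sm$coefficients),
                             estimate = sm$coefficients[, 1],
                             std_error = sm$coefficients[, 2],
                             p_value = sm$coefficients[, 4]),
       r_squared = sm$r.squared, fit = fit)
}
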