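#' Parameters of the run-of-homozygosity scanner
#'
#' Defaults mirror the conventional SNP-count sliding-window scheme: 50-SNP
#' windows tolerating one heterozygous and five missing calls, a SNP joining
#' a run when more than 5% of the windows covering it pass, and segments
#' kept only when at least 0.5 Mb long with at least 25 SNPs.
#'
#' @param window_snps SNPs per sliding window.
#' @param window_het_max Heterozygous calls tolerated per window.
#' @param window_missing_max Missing calls tolerated per window.
#' @param hit_threshold A SNP is segment-eligible when its fraction of
#'   passing windows is strictly above this value.
#' @param min_segment_bp Minimum segment length (`end - start` bp).
#' @param min_segment_snps Minimum SNPs per segment.
#' @param window_mode `"snp"` (default): windows are `window_snps`
#'   consecutive SNPs. `"bp"`: windows span `window_bp` base pairs and are
#'   evaluated only when they contain at least `window_snps` SNPs.
#' @param window_bp Physical window span for `window_mode = "bp"`.
#' @return A `roh_params` list.
#' @export
roh_params <- function(window_snps = 50L, window_het_max = 1L,
                       window_missing_max = 5L, hit_threshold = 0.05,
                       min_segment_bp = 5e5, min_segment_snps = 25L,
                       window_mode = c("snp", "bp"), window_bp = 5e6) {
  window_mode <- match.arg(window_mode)
  stopifnot(window_snps >= 1, window_het_max >= 0, window_missing_max >= 0,
            hit_threshold > 0, hit_threshold <= 1,
            min_segment_bp >= 0, min_segment_snps >= 0)
  structure(list(window_snps = as.integer(window_snps),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 hit_threshold = hit_threshold,
                 min_segment_bp = min_segment_bp,
                 min_segment_snps = as.integer(min_segment_snps),
                 window_mode = window_mode, window_bp = window_bp),
            class = "roh_params")
}

# windows: integer matrix with columns (start_snp, end_snp), or NULL when
# the chromosome cannot host a window
roh_windows <- function(pos, params) {
  m <- length(pos)
  if (params$window_mode == "snp") {
    if (m < params$window_snps) return(NULL)
    nw <- m - params$window_snps + 1L
    cbind(seq_len(nw), seq_len(nw) + params$window_snps - 1L)
  } else {
    ends <- findInterval(pos + params$window_bp - 1e-9, pos)
    w <- cbind(seq_len(m), ends)
    w <- w[w[, 2] - w[, 1] + 1L >= params$window_snps, , drop = FALSE]
    if (nrow(w) == 0) NULL else w
  }
}

scan_roh_one <- function(g, pos, params) {
  w <- roh_windows(pos, params)
  if (is.null(w)) return(NULL)
  m <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  H <- c(0, cumsum(het)); M <- c(0, cumsum(mis))
  hs <- H[w[, 2] + 1L] - H[w[, 1]]
  ms <- M[w[, 2] + 1L] - M[w[, 1]]
  pass <- hs <= params$window_het_max & ms <= params$window_missing_max
  # per SNP: passing / containing windows among evaluated windows
  contain <- numeric(m); hits <- numeric(m)
  # windows are intervals [start, end] over SNP index; accumulate by
  # difference arrays
  d_c <- numeric(m + 1L); d_h <- numeric(m + 1L)
  d_c[w[, 1]] <- d_c[w[, 1]] + 1
  d_c[w[, 2] + 1L] <- d_c[w[, 2] + 1L] - 1
  pw <- w[pass, , drop = FALSE]
  if (nrow(pw)) {
    d_h[pw[, 1]] <- d_h[pw[, 1]] + 1
    d_h[pw[, 2] + 1L] <- d_h[pw[, 2] + 1L] - 1
  }
  contain <- cumsum(d_c[seq_len(m)])
  hits <- cumsum(d_h[seq_len(m)])
  eligible <- contain > 0 & hits / pmax(contain, 1) > params$hit_threshold
  if (!any(eligible)) return(NULL)
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hom <- !het & !mis
  segs <- list()
  for (k in which(r$values)) {
    j1 <- starts[k]; j2 <- ends[k]
    while (j1 <= j2 && !hom[j1]) j1 <- j1 + 1L
    while (j2 >= j1 && !hom[j2]) j2 <- j2 - 1L
    if (j2 < j1) next
    n_snps <- j2 - j1 + 1L
    len <- pos[j2] - pos[j1]
    if (n_snps >= params$min_segment_snps && len >= params$min_segment_bp) {
      segs[[length(segs) + 1]] <- c(j1, j2)
    }
  }
  segs
}

#' Detect runs of homozygosity
#'
#' Slides windows along each chromosome of each individual, marks SNPs whose
#' fraction of homozygous-passing windows exceeds the hit threshold, joins
#' consecutive eligible SNPs into candidate runs trimmed to homozygous end
#' SNPs, and keeps runs meeting both minimum-length and minimum-SNP-count
#' thresholds. Segments within an individual never overlap.
#'
#' @param ds A `geno_ds` with the SNP map sorted per chromosome.
#' @param params A [roh_params()].
#' @return Tibble of segments: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
scan_roh <- function(ds, params = roh_params()) {
  stopifnot(inherits(ds, "geno_ds"), inherits(params, "roh_params"))
  chroms <- unique(ds$map$chrom)
  out <- list()
  for (ch in chroms) {
    j <- which(ds$map$chrom == ch)
    pos <- ds$map$pos_bp[j]
    if (is.null(roh_windows(pos, params))) {
      warn(sprintf("chromosome %s has too few SNPs for a window; skipped", ch))
      next
    }
    for (i in seq_len(nrow(ds$geno))) {
      segs <- scan_roh_one(ds$geno[i, j], pos, params)
      if (length(segs)) {
        sm <- do.call(rbind, segs)
        out[[length(out) + 1]] <- tibble(
          sample_id = ds$meta$sample_id[i], chrom = ch,
          start_bp = pos[sm[, 1]], end_bp = pos[sm[, 2]],
          n_snps = sm[, 2] - sm[, 1] + 1L)
      }
    }
  }
  if (!length(out)) {
    return(tibble(sample_id = character(), chrom = character(),
                  start_bp = numeric(), end_bp = numeric(),
                  n_snps = integer(), length_bp = numeric()))
  }
  res <- bind_rows(out)
  res$length_bp <- res$end_bp - res$start_bp
  res
}

# ---- univariate Gaussian mixture by EM ------------------------------------

kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(v) min((v - centers[seq_len(j - 1)])^2),
                 numeric(1))
    if (sum(d2) <= 0) centers[j] <- x[sample.int(length(x), 1)]
    else centers[j] <- x[sample.int(length(x), 1, prob = d2)]
  }
  centers
}

fit_gmm1d <- function(x, k, tol = 1e-8, max_iter = 500, sd_floor = 1e-6) {
  n <- length(x)
  mu <- kmeanspp_centers(x, k)
  assign0 <- apply(abs(outer(x, mu, "-")), 1, which.min)
  sig <- vapply(seq_len(k), function(j) {
    xs <- x[assign0 == j]
    s <- if (length(xs) > 1) sd(xs) else sd(x) / k
    max(s, sd_floor, sd(x) / (5 * k))
  }, numeric(1))
  w <- tabulate(assign0, k) / n
  w[w == 0] <- 1 / n
  w <- w / sum(w)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sig[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    if (any(rs <= 0) || any(!is.finite(rs))) return(NULL)
    ll <- sum(log(rs))
    r <- dens / rs
    nk <- colSums(r)
    if (any(nk < 1e-10)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sig <- sqrt(colSums(r * (outer(x, mu, "-")^2)) / nk)
    if (any(sig < sd_floor)) return(NULL)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sig, loglik = ll,
       responsibilities = r)
}

#' Classify run-of-homozygosity lengths by Gaussian mixture
#'
#' Fits univariate Gaussian mixtures to the segment length distribution by
#' EM (k-means++ initialization, 10 restarts per k, tolerance 1e-8 on the
#' log-likelihood) for `k = 1..max_k`, selects `k` by lowest BIC, orders
#' classes by increasing mean length, and assigns each segment to its
#' maximum-responsibility class.
#'
#' @param segments Segment tibble from [scan_roh()] (needs `length_bp`).
#' @param max_k Maximum number of classes (default 6).
#' @param seed Integer seed for the stochastic initializations.
#' @param restarts EM restarts per candidate `k`.
#' @return A `roh_mixture` object; `$segments` carries the input with a
#'   `class` column. Methods: [tidy()], [glance()], [autoplot()].
#' @export
classify_roh_lengths <- function(segments, max_k = 6L, seed = 1L,
                                 restarts = 10L) {
  x_bp <- segments$length_bp
  if (length(x_bp) < max_k + 1) {
    stop_isopop(sprintf("need more than max_k = %d segments, got %d",
                        max_k, length(x_bp)))
  }
  x <- x_bp / 1e6  # fit on the Mb scale
  n <- length(x)
  fits <- vector("list", max_k)
  with_seed(child_seed(seed, 11L), {
    for (k in seq_len(max_k)) {
      best <- NULL
      for (r in seq_len(restarts)) {
        f <- fit_gmm1d(x, k)
        if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
      }
      if (is.null(best)) {
        if (k == 1) stop_isopop("all EM restarts degenerate")
        next
      }
      best$k <- k
      best$bic <- -2 * best$loglik + (3 * k - 1) * log(n)
      fits[[k]] <- best
    }
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  sel <- fits[[which.min(bics)]]
  ord <- order(sel$means)
  rank <- match(seq_along(ord), ord)
  assign <- rank[apply(sel$responsibilities, 1, which.max)]
  segments$class <- assign
  structure(list(k = sel$k, weights = sel$weights[ord],
                 means = sel$means[ord] * 1e6, sds = sel$sds[ord] * 1e6,
                 loglik = sel$loglik, bic = sel$bic,
                 bic_by_k = setNames(bics, vapply(fits, `[[`, numeric(1), "k")),
                 n = n, segments = segments),
            class = "roh_mixture")
}

#' @export
print.roh_mixture <- function(x, ...) {
  cat(sprintf("<roh_mixture> %d classes over %d segments (BIC %.1f)\n",
              x$k, x$n, x$bic))
  print(tidy(x))
  invisible(x)
}

#' @rdname classify_roh_lengths
#' @param x A `roh_mixture`.
#' @param ... Unused.
#' @export
tidy.roh_mixture <- function(x, ...) {
  tibble(class = seq_len(x$k), weight = x$weights,
         mean_bp = x$means, sd_bp = x$sds,
         n_segments = tabulate(x$segments$class, x$k))
}

#' @rdname classify_roh_lengths
#' @export
glance.roh_mixture <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, bic = x$bic, n = x$n)
}

#' @rdname classify_roh_lengths
#' @param object A `roh_mixture`.
#' @export
autoplot.roh_mixture <- function(object, ...) {
  seg <- object$segments
  grid <- seq(min(seg$length_bp), max(seg$length_bp), length.out = 400)
  dens <- purrr::map_dfr(seq_len(object$k), function(j)
    tibble(class = factor(j), length_bp = grid,
           density = object$weights[j] *
             dnorm(grid, object$means[j], object$sds[j])))
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$length_bp)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, colour = .data$class)) +
    ggplot2::labs(x = "RoH length (bp)", y = "density",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Inbreeding coefficient from runs of homozygosity
#'
#' `F_ROH` is the fraction of the (optionally centromere-masked) genome
#' covered by runs of homozygosity: masked stretches are subtracted from
#' both the segments and the genome length.
#'
#' @param segments Segment tibble ([scan_roh()] output).
#' @param genome_bp Total genome length in bp before masking.
#' @param mask Optional mask tibble (`chrom`, `start_bp`, `end_bp`,
#'   half-open as from [read_bed_mask()]).
#' @param sample_ids Samples to report; defaults to those present in
#'   `segments`. Samples without segments get `froh = 0`.
#' @return Tibble: `sample_id`, `froh`.
#' @export
froh <- function(segments, genome_bp, mask = NULL, sample_ids = NULL) {
  stopifnot(genome_bp > 0)
  mask_bp <- 0
  if (!is.null(mask) && nrow(mask) > 0) {
    mask_bp <- sum(vapply(split(mask, mask$chrom), function(mm)
      masked_length(mm$start_bp, mm$end_bp, numeric(0), numeric(0)),
      numeric(1)))
  }
  denom <- genome_bp - mask_bp
  if (denom <= 0) stop_isopop("mask covers the whole genome")
  sample_ids <- sample_ids %||% unique(segments$sample_id)
  vals <- vapply(sample_ids, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    if (nrow(seg) == 0) return(0)
    tot <- sum(vapply(split(seg, seg$chrom), function(sc) {
      mm <- if (is.null(mask)) NULL else mask[mask$chrom == sc$chrom[1], ]
      masked_length(sc$start_bp, sc$end_bp,
                    mm$start_bp %||% numeric(0), mm$end_bp %||% numeric(0))
    }, numeric(1)))
    tot / denom
  }, numeric(1))
  tibble(sample_id = sample_ids, froh = unname(vals))
}

#' Per-population summary of runs of homozygosity
#'
#' Averages per-individual segment counts and total lengths within
#' populations and, when class assignments are present, tallies the class
#' proportions of each population's segments.
#'
#' @param segments Segment tibble, optionally with a `class` column.
#' @param meta Sample metadata (defines the population of every sample,
#'   including individuals without segments).
#' @return Tibble per population: `mean_roh_count`, `mean_roh_total_bp`,
#'   and `class_prop_<j>` columns when classes are available.
#' @export
roh_population_summary <- function(segments, meta) {
  meta <- as_tibble(meta)
  per_ind <- meta |>
    select("sample_id", "population") |>
    left_join(
      segments |> group_by(.data$sample_id) |>
        summarise(count = dplyr::n(), total_bp = sum(.data$length_bp),
                  .groups = "drop"),
      by = "sample_id")
  per_ind$count[is.na(per_ind$count)] <- 0
  per_ind$total_bp[is.na(per_ind$total_bp)] <- 0
  out <- per_ind |> group_by(.data$population) |>
    summarise(mean_roh_count = mean(.data$count),
              mean_roh_total_bp = mean(.data$total_bp), .groups = "drop")
  if ("class" %in% names(segments) && nrow(segments) > 0) {
    kmax <- max(segments$class)
    seg <- left_join(segments, select(meta, "sample_id", "population"),
                     by = "sample_id")
    props <- seg |> group_by(.data$population) |>
      summarise(props = list(tabulate(.data$class, kmax) /
                               length(.data$class)), .groups = "drop")
    pm <- do.call(rbind, props$props)
    colnames(pm) <- paste0("class_prop_", seq_len(kmax))
    props <- bind_cols(props["population"], as_tibble(pm))
    out <- left_join(out, props, by = "population")
    for (cn in grep("^class_prop_", names(out), value = TRUE)) {
      out[[cn]][is.na(out[[cn]])] <- 0
    }
  }
  out
}
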