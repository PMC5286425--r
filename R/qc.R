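#' Genotyping-success-rate quality control
#'
#' Removes SNPs whose call rate is not strictly above `snp_call_min`, then
#' individuals whose call rate is not strictly above `ind_call_min` (SNPs
#' first, then individuals). Minor-allele orientation is recomputed on the
#' filtered sample.
#'
#' @param ds A `geno_ds`.
#' @param snp_call_min Minimum SNP call rate, strict `>` (default 0.90).
#' @param ind_call_min Minimum individual call rate, strict `>`
#'   (default 0.92).
#' @return A filtered `geno_ds` with a `qc_log` attribute describing the
#'   two passes.
#' @export
qc_filter <- function(ds, snp_call_min = 0.90, ind_call_min = 0.92) {
  stopifnot(inherits(ds, "geno_ds"),
            snp_call_min > 0, snp_call_min <= 1,
            ind_call_min > 0, ind_call_min <= 1)
  obs <- !is.na(ds$geno)
  snp_rate <- colMeans(obs)
  keep_snp <- snp_rate > snp_call_min
  g <- ds$geno[, keep_snp, drop = FALSE]
  ind_rate <- rowMeans(!is.na(g))
  keep_ind <- ind_rate > ind_call_min
  if (!any(keep_snp) || !any(keep_ind)) {
    stop_isopop("no data left after call-rate filtering")
  }
  out <- geno_dataset(g[keep_ind, , drop = FALSE],
                      ds$map[keep_snp, , drop = FALSE],
                      ds$meta[keep_ind, , drop = FALSE])
  or <- orient_minor(out$geno, out$map$a1, out$map$a2)
  out$geno <- or$geno
  if (any(or$flipped)) {
    tmp <- out$map$a1[or$flipped]
    out$map$a1[or$flipped] <- out$map$a2[or$flipped]
    out$map$a2[or$flipped] <- tmp
  }
  attr(out, "qc_log") <- sprintf(
    "pass 1: SNP call rate > %g removed %d/%d SNPs; pass 2: individual call rate > %g removed %d/%d individuals",
    snp_call_min, sum(!keep_snp), length(keep_snp),
    ind_call_min, sum(!keep_ind), length(keep_ind))
  out
}

#' Pairwise relatedness (PI_HAT) by method of moments
#'
#' Estimates the proportion of the genome shared identical by descent for
#' every sample pair from identity-by-state counts and sample allele
#' frequencies: `PI_HAT = P(IBD = 1)/2 + P(IBD = 2)`, with the IBD-state
#' probabilities obtained by moment matching of the observed IBS-state
#' counts against their expectations under each IBD state.
#'
#' @param ds A `geno_ds`.
#' @return A symmetric matrix of PI_HAT values with `NA` on the diagonal.
#' @export
estimate_pihat <- function(ds) {
  stopifnot(inherits(ds, "geno_ds"))
  g <- ds$geno
  if (nrow(g) < 2) stop_isopop("need at least 2 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  if (ncol(g) < 1) stop_isopop("no polymorphic loci for relatedness")
  M <- (!is.na(g)) * 1
  gz <- g; gz[is.na(gz)] <- 0L
  i0 <- (gz == 0L) * M; i1 <- (gz == 1L) * M; i2 <- (gz == 2L) * M
  # IBS-state counts over jointly observed loci
  n2 <- tcrossprod(i0) + tcrossprod(i1) + tcrossprod(i2)
  n0 <- tcrossprod(i0, i2) + tcrossprod(i2, i0)
  nobs <- tcrossprod(M)
  n1 <- nobs - n2 - n0
  # per-locus IBS-state expectations given IBD state, using count-based
  # unbiased estimators of the allele-frequency products (finite-sample
  # correction for frequencies estimated from the same panel)
  Tn <- 2 * colSums(M)
  X <- colSums(gz)          # minor-allele count
  Y <- Tn - X
  den4 <- Tn * (Tn - 1) * (Tn - 2) * (Tn - 3)
  den3 <- Tn * (Tn - 1) * (Tn - 2)
  den2 <- Tn * (Tn - 1)
  e0_0 <- 2 * X * (X - 1) * Y * (Y - 1) / den4
  e1_0 <- 4 * (X * (X - 1) * (X - 2) * Y + X * Y * (Y - 1) * (Y - 2)) / den4
  e2_0 <- 1 - e0_0 - e1_0
  e1_1 <- 2 * X * Y / den2
  e2_1 <- 1 - e1_1
  E0 <- tcrossprod(sweep(M, 2, e0_0, `*`), M)
  E10 <- tcrossprod(sweep(M, 2, e1_0, `*`), M)
  E20 <- tcrossprod(sweep(M, 2, e2_0, `*`), M)
  E11 <- tcrossprod(sweep(M, 2, e1_1, `*`), M)
  E21 <- tcrossprod(sweep(M, 2, e2_1, `*`), M)
  P0 <- n0 / E0
  P1 <- (n1 - P0 * E10) / E11
  P2 <- (n2 - P0 * E20 - P1 * E21) / nobs
  P0 <- pmin(pmax(P0, 0), 1)
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  tot <- P0 + P1 + P2
  pihat <- (P1 / 2 + P2) / tot
  diag(pihat) <- NA_real_
  dimnames(pihat) <- list(ds$meta$sample_id, ds$meta$sample_id)
  pihat
}

#' Prune related individuals
#'
#' Computes pairwise PI_HAT relatedness and, while any pair exceeds
#' `pihat_max`, removes one member of the offending pair chosen at random
#' under `seed`. Pairs are visited in a fixed order so the result is
#' deterministic for a given seed.
#'
#' @param ds A `geno_ds`.
#' @param pihat_max Maximum tolerated PI_HAT, strict `>` triggers removal
#'   (default 0.185, third-degree relatedness).
#' @param seed Integer seed for the random choice of which member to drop.
#' @return A `geno_ds` restricted to the retained samples, with a
#'   `pruned_samples` attribute.
#' @export
relatedness_prune <- function(ds, pihat_max = 0.185, seed = 1L) {
  stopifnot(inherits(ds, "geno_ds"))
  pihat <- estimate_pihat(ds)
  ids <- ds$meta$sample_id
  keep <- rep(TRUE, length(ids))
  with_seed(child_seed(seed, 7L), {
    repeat {
      sub <- pihat[keep, keep, drop = FALSE]
      over <- which(!is.na(sub) & sub > pihat_max & upper.tri(sub),
                    arr.ind = TRUE)
      if (nrow(over) == 0) break
      over <- over[order(over[, 1], over[, 2]), , drop = FALSE]
      pair <- c(rownames(sub)[over[1, 1]], colnames(sub)[over[1, 2]])
      drop_id <- sample(pair, 1)
      keep[match(drop_id, ids)] <- FALSE
    }
  })
  out <- subset_geno(ds, samples = ids[keep])
  attr(out, "pruned_samples") <- ids[!keep]
  out
}
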