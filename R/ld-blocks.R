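#' Linkage-disequilibrium blocks by the D' confidence-interval method
#'
#' For every SNP pair within `max_span_bp`, two-locus haplotype frequencies
#' are estimated from unphased genotypes by EM and a 90% confidence interval
#' for |D'| is read off the profile of the multinomial log-likelihood on a
#' 0.001 grid. A pair is "strong LD" when the interval lies in
#' `[strong_low, 1]` with upper bound at least `strong_high`, and "strong
#' recombination" when the upper bound is below `recomb_high`. Maximal spans
#' in which at least `informative_min_frac` of the informative pairs are
#' strong LD become blocks, selected greedily longest-first without overlap.
#'
#' @param ds A `geno_ds` (typically one population's samples).
#' @param strong_low,strong_high Strong-LD interval thresholds.
#' @param recomb_high Strong-recombination upper-bound threshold.
#' @param informative_min_frac Minimum fraction of informative pairs in
#'   strong LD within a block.
#' @param max_span_bp Maximum block span in bp (default 200 kb, the
#'   conventional pairwise search window of the block definition).
#' @param grid_step D' grid resolution.
#' @param return_pairs Also return the per-pair classification.
#' @return Tibble of blocks: `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp`; with `return_pairs = TRUE`, a list with `blocks` and
#'   `pairs`.
#' @export
ld_blocks <- function(ds, strong_low = 0.70, strong_high = 0.98,
                      recomb_high = 0.90, informative_min_frac = 0.95,
                      max_span_bp = 2e5, grid_step = 0.001,
                      return_pairs = FALSE) {
  stopifnot(inherits(ds, "geno_ds"))
  chroms <- unique(ds$map$chrom)
  blocks <- list(); pairs <- list()
  for (ch in chroms) {
    j <- which(ds$map$chrom == ch)
    if (length(j) < 2) next
    res <- ld_block_scan_cpp(ds$geno[, j, drop = FALSE],
                             as.numeric(ds$map$pos_bp[j]),
                             strong_low, strong_high, recomb_high,
                             informative_min_frac, max_span_bp, grid_step,
                             return_pairs)
    if (length(res$block_start)) {
      s <- j[res$block_start]; e <- j[res$block_end]
      blocks[[length(blocks) + 1]] <- tibble(
        chrom = ch, start_bp = ds$map$pos_bp[s], end_bp = ds$map$pos_bp[e],
        n_snps = res$block_end - res$block_start + 1L)
    }
    if (return_pairs && !is.null(res$pairs)) {
      pairs[[length(pairs) + 1]] <- tibble(
        chrom = ch,
        snp_i = ds$map$snp_id[j[res$pairs$i]],
        snp_j = ds$map$snp_id[j[res$pairs$j]],
        dprime = res$pairs$dprime, ci_low = res$pairs$ci_low,
        ci_high = res$pairs$ci_high, class = res$pairs$class)
    }
  }
  blocks <- if (length(blocks)) {
    b <- bind_rows(blocks)
    b$length_bp <- b$end_bp - b$start_bp
    b
  } else {
    tibble(chrom = character(), start_bp = numeric(), end_bp = numeric(),
           n_snps = integer(), length_bp = numeric())
  }
  if (return_pairs) {
    list(blocks = blocks,
         pairs = if (length(pairs)) bind_rows(pairs) else NULL)
  } else blocks
}

#' Per-population mean LD-block length
#'
#' Runs [ld_blocks()] on each population's samples and averages the block
#' lengths; populations without blocks report 0.
#'
#' @param ds A `geno_ds`.
#' @param ... Passed to [ld_blocks()].
#' @return Tibble: `population`, `mean_ld_block_bp`, `n_blocks`.
#' @export
ld_block_summary <- function(ds, ...) {
  pops <- unique(ds$meta$population)
  purrr::map_dfr(pops, function(p) {
    sub <- subset_geno(ds, samples = ds$meta$sample_id[ds$meta$population == p])
    b <- ld_blocks(sub, ...)
    tibble(population = p,
           mean_ld_block_bp = if (nrow(b)) mean(b$length_bp) else 0,
           n_blocks = nrow(b))
  })
}
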