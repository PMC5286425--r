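#' Demography configuration for the cohort simulator
#'
#' Describes a multi-deme Wright-Fisher demography: per-deme census (equal to
#' effective) size, founder count, split generation, optional migration, and
#' a genome layout. A deme holds its founders unchanged until its split
#' generation, then advances by random mating for the remaining generations,
#' so `t = n_generations - split_gen` is its time under drift.
#'
#' @param demes Data frame with columns `name`, `group` (`"open"`/
#'   `"isolated"`), `ne` (census/effective size), `founders` (founder
#'   individuals; defaults to `ne`), `split_gen` (generation at which drift
#'   starts; default 0), and optional `lat`, `lon`.
#' @param n_generations Total generations simulated.
#' @param n_chrom Number of chromosomes.
#' @param chrom_bp Chromosome length in base pairs (all chromosomes equal).
#' @param snps_per_chrom SNPs per chromosome, evenly spaced.
#' @param cm_per_mb Uniform recombination rate (default 1 cM/Mb).
#' @param founder_maf Length-2 range of the founder minor-allele-frequency
#'   spectrum (default `c(0.05, 0.5)`).
#' @param migration Optional square matrix; `migration[d, s]` is the
#'   probability that an offspring born in deme `d` draws both parents from
#'   deme `s` (backward migration). Off-diagonal row sums must be < 1.
#' @param allow_selfing Logical; under the idealized Wright-Fisher model the
#'   two parents are drawn independently with replacement (selfing
#'   possible), which is what makes the closed-form inbreeding recursion
#'   exact. Set `FALSE` to force distinct parents.
#' @param seed Integer seed controlling the whole simulation.
#' @return A `demography_config` list.
#' @export
demography_config <- function(demes, n_generations, n_chrom = 4,
                              chrom_bp = 1e8, snps_per_chrom = 2500,
                              cm_per_mb = 1, founder_maf = c(0.05, 0.5),
                              migration = NULL, allow_selfing = TRUE,
                              seed = 1L) {
  demes <- as_tibble(demes)
  if (!"founders" %in% names(demes)) demes$founders <- demes$ne
  if (!"split_gen" %in% names(demes)) demes$split_gen <- 0L
  stopifnot(all(c("name", "group", "ne") %in% names(demes)),
            all(demes$ne >= 1), all(demes$founders >= 1),
            all(demes$split_gen <= n_generations),
            n_generations >= 0, n_chrom >= 1, chrom_bp >= 1,
            snps_per_chrom >= 1, cm_per_mb > 0,
            length(founder_maf) == 2)
  nd <- nrow(demes)
  if (is.null(migration)) migration <- matrix(0, nd, nd)
  migration <- as.matrix(migration)
  stopifnot(nrow(migration) == nd, ncol(migration) == nd)
  diag(migration) <- 0
  if (any(migration < 0) || any(migration >= 1) ||
      any(rowSums(migration) >= 1)) {
    stop_isopop("migration fractions must be in [0,1) with row sums < 1")
  }
  if (!allow_selfing && any(demes$ne == 1)) {
    stop_isopop("deme of size 1 is impossible with selfing excluded")
  }
  structure(list(demes = demes, n_generations = as.integer(n_generations),
                 n_chrom = as.integer(n_chrom), chrom_bp = chrom_bp,
                 snps_per_chrom = as.integer(snps_per_chrom),
                 cm_per_mb = cm_per_mb, founder_maf = founder_maf,
                 migration = migration, allow_selfing = allow_selfing,
                 seed = as.integer(seed)),
            class = "demography_config")
}

# A haplotype mosaic on one chromosome: list(bp = tile start positions
# (bp[1] == 1, half-open tiles ending at the next start or chrom_bp + 1),
# fid = founder haplotype id per tile).

new_tile <- function(fid, L) list(bp = 1, fid = fid)

# Extract the sub-mosaic of `hap` covering [a, b).
slice_mosaic <- function(hap, a, b) {
  ia <- sum(hap$bp <= a)
  ib <- sum(hap$bp < b)
  bp <- hap$bp[ia:ib]
  bp[1] <- a
  list(bp = bp, fid = hap$fid[ia:ib])
}

# One meiosis on one chromosome: recombinant mosaic of the parent's two
# haplotypes with Poisson(cM/100) crossovers at uniform positions.
gamete <- function(h1, h2, L, cm_len) {
  k <- rpois(1, cm_len / 100)
  first <- runif(1) < 0.5
  if (k == 0) return(if (first) h1 else h2)
  cuts <- sort(runif(k, min = 1, max = L + 1))
  bounds <- c(1, cuts, L + 1)
  use1 <- rep(c(first, !first), length.out = length(bounds) - 1)
  bp <- numeric(0); fid <- integer(0)
  for (s in seq_len(length(bounds) - 1)) {
    piece <- slice_mosaic(if (use1[s]) h1 else h2, bounds[s], bounds[s + 1])
    bp <- c(bp, piece$bp); fid <- c(fid, piece$fid)
  }
  keep <- c(TRUE, fid[-1] != fid[-length(fid)])
  list(bp = bp[keep], fid = fid[keep])
}

#' Simulate a multi-deme cohort by founder-mosaic Wright-Fisher
#'
#' Forward-time simulation in which every haplotype is a mosaic of founder
#' haplotypes, so identity by descent and autozygosity are exact by
#' construction. Each generation, offspring in deme `d` draw a source deme
#' from the migration matrix, then two parents from it (independently with
#' replacement under the default selfing-allowed model), each contributing a
#' recombinant gamete per chromosome.
#'
#' @param cfg A [demography_config()].
#' @return A `sim_cohort` list: final-generation individuals per deme
#'   (haplotype mosaics), the genome layout, per-SNP founder allele
#'   frequencies and the configuration.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "demography_config"))
  nd <- nrow(cfg$demes)
  L <- cfg$chrom_bp
  cm_len <- L / 1e6 * cfg$cm_per_mb
  with_seed(child_seed(cfg$seed, 1L), {
    # founder frequencies per chromosome (minor allele)
    freqs <- lapply(seq_len(cfg$n_chrom), function(cc)
      runif(cfg$snps_per_chrom, cfg$founder_maf[1], cfg$founder_maf[2]))
    # founders: unique haplotype ids, single tile per chromosome
    fid_next <- 1L
    founder_pools <- vector("list", nd)
    for (d in seq_len(nd)) {
      nf <- cfg$demes$founders[d]
      inds <- vector("list", nf)
      for (i in seq_len(nf)) {
        h1 <- lapply(seq_len(cfg$n_chrom), function(cc) list(bp = 1, fid = fid_next))
        h2 <- lapply(seq_len(cfg$n_chrom), function(cc) list(bp = 1, fid = fid_next + 1L))
        fid_next <- fid_next + 2L
        inds[[i]] <- list(h1, h2)
      }
      founder_pools[[d]] <- inds
    }
    state <- founder_pools
    for (g in seq_len(cfg$n_generations)) {
      active <- g > cfg$demes$split_gen
      newstate <- state
      prev <- state
      for (d in which(active)) {
        N <- cfg$demes$ne[d]
        kids <- vector("list", N)
        mig <- cfg$migration[d, ]
        for (i in seq_len(N)) {
          s <- d
          if (any(mig > 0)) {
            u <- runif(1)
            cum <- cumsum(mig)
            hit <- which(u < cum)
            if (length(hit)) s <- hit[1]
          }
          pool <- prev[[s]]
          np <- length(pool)
          if (cfg$allow_selfing) {
            pi1 <- sample.int(np, 1); pi2 <- sample.int(np, 1)
          } else {
            if (np < 2) stop_isopop("cannot exclude selfing in a deme of size 1")
            pick <- sample.int(np, 2)
            pi1 <- pick[1]; pi2 <- pick[2]
          }
          p1 <- pool[[pi1]]; p2 <- pool[[pi2]]
          h1 <- lapply(seq_len(cfg$n_chrom), function(cc)
            gamete(p1[[1]][[cc]], p1[[2]][[cc]], L, cm_len))
          h2 <- lapply(seq_len(cfg$n_chrom), function(cc)
            gamete(p2[[1]][[cc]], p2[[2]][[cc]], L, cm_len))
          kids[[i]] <- list(h1, h2)
        }
        newstate[[d]] <- kids
      }
      state <- newstate
    }
    structure(list(demes = state, cfg = cfg, freqs = freqs,
                   n_founder_haps = fid_next - 1L),
              class = "sim_cohort")
  })
}

# Deterministic founder allele vector for one founder haplotype on one
# chromosome (1 = minor allele), derived from the cohort seed.
founder_alleles <- function(cohort, fid, chrom) {
  with_seed(child_seed(cohort$cfg$seed, 100L + fid * cohort$cfg$n_chrom + chrom),
            rbinom(cohort$cfg$snps_per_chrom, 1, cohort$freqs[[chrom]]))
}

snp_positions <- function(cfg) {
  round(seq_len(cfg$snps_per_chrom) * cfg$chrom_bp / (cfg$snps_per_chrom + 1))
}

# founder id per SNP for a haplotype mosaic
fid_at <- function(hap, pos) hap$fid[findInterval(pos, hap$bp)]

#' Read genotypes off a simulated cohort
#'
#' Samples individuals from each deme's final generation and converts their
#' mosaic haplotypes plus founder allele states into a [geno_dataset()].
#' Dosages are oriented to the minor allele of the emitted sample.
#'
#' @param cohort A `sim_cohort`.
#' @param sample_sizes Named integer vector (deme name -> count) or a single
#'   count recycled over demes.
#' @return A `geno_ds`; the attribute `"sampled"` records which deme
#'   individuals were drawn (used by [true_ibd_segments()] and
#'   [autozygosity()]).
#' @export
emit_dataset <- function(cohort, sample_sizes) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$cfg
  nd <- nrow(cfg$demes)
  if (length(sample_sizes) == 1 && is.null(names(sample_sizes))) {
    sample_sizes <- setNames(rep(sample_sizes, nd), cfg$demes$name)
  }
  sample_sizes <- sample_sizes[cfg$demes$name]
  if (anyNA(sample_sizes)) stop_isopop("sample_sizes must cover every deme")
  avail <- vapply(cohort$demes, length, integer(1))
  if (any(sample_sizes > avail)) {
    bad <- which(sample_sizes > avail)
    stop_isopop(sprintf("requested %d from deme %s which has %d individuals",
                        sample_sizes[bad[1]], cfg$demes$name[bad[1]],
                        avail[bad[1]]))
  }
  pos <- snp_positions(cfg)
  sampled <- with_seed(child_seed(cfg$seed, 2L), {
    purrr::map2(seq_len(nd), sample_sizes,
                function(d, k) sort(sample.int(avail[d], k)))
  })
  n_tot <- sum(sample_sizes)
  m <- cfg$n_chrom * cfg$snps_per_chrom
  geno <- matrix(0L, n_tot, m)
  # per chromosome: build a founder-allele matrix for the fids in use
  for (cc in seq_len(cfg$n_chrom)) {
    cols <- (cc - 1) * cfg$snps_per_chrom + seq_len(cfg$snps_per_chrom)
    haps <- list(); row <- 1L
    fidsets <- list()
    for (d in seq_len(nd)) for (i in sampled[[d]]) {
      ind <- cohort$demes[[d]][[i]]
      fidsets[[length(fidsets) + 1]] <- c(ind[[1]][[cc]]$fid, ind[[2]][[cc]]$fid)
    }
    uf <- sort(unique(unlist(fidsets)))
    FA <- matrix(0L, length(uf), cfg$snps_per_chrom)
    for (k in seq_along(uf)) FA[k, ] <- founder_alleles(cohort, uf[k], cc)
    row <- 1L
    for (d in seq_len(nd)) for (i in sampled[[d]]) {
      ind <- cohort$demes[[d]][[i]]
      f1 <- match(fid_at(ind[[1]][[cc]], pos), uf)
      f2 <- match(fid_at(ind[[2]][[cc]], pos), uf)
      idx <- seq_len(cfg$snps_per_chrom)
      geno[row, cols] <- FA[cbind(f1, idx)] + FA[cbind(f2, idx)]
      row <- row + 1L
    }
  }
  deme_of <- rep(seq_len(nd), sample_sizes)
  meta <- tibble(
    sample_id = paste0(cfg$demes$name[deme_of], "_",
                       unlist(lapply(sample_sizes, seq_len))),
    population = cfg$demes$name[deme_of],
    group = cfg$demes$group[deme_of])
  if (all(c("lat", "lon") %in% names(cfg$demes))) {
    meta$lat <- cfg$demes$lat[deme_of]
    meta$lon <- cfg$demes$lon[deme_of]
  }
  map <- tibble(
    snp_id = paste0("snp", rep(seq_len(cfg$n_chrom), each = cfg$snps_per_chrom),
                    "_", rep(seq_len(cfg$snps_per_chrom), cfg$n_chrom)),
    chrom = as.character(rep(seq_len(cfg$n_chrom), each = cfg$snps_per_chrom)),
    pos_bp = rep(pos, cfg$n_chrom), a1 = "A", a2 = "B")
  or <- orient_minor(geno, rep("A", m), rep("B", m))
  map$a1[or$flipped] <- "B"; map$a2[or$flipped] <- "A"
  ds <- geno_dataset(or$geno, map, meta)
  attr(ds, "sampled") <- tibble(
    sample_id = meta$sample_id, deme = meta$population,
    idx = unlist(sampled))
  ds
}

# merge possibly-overlapping real intervals, return matrix [start, end)
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) return(cbind(numeric(0), numeric(0)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me) me <- max(me, ends[k]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

# intervals (matrix [start, end)) where two mosaics carry the same founder id
shared_intervals <- function(hA, hB, L) {
  u <- sort(unique(c(hA$bp, hB$bp)))
  fA <- hA$fid[findInterval(u, hA$bp)]
  fB <- hB$fid[findInterval(u, hB$bp)]
  eq <- fA == fB
  if (!any(eq)) return(cbind(numeric(0), numeric(0)))
  ends <- c(u[-1], L + 1)
  merge_intervals(u[eq], ends[eq])
}

#' Ground-truth identity-by-descent segments of a simulated cohort
#'
#' For each individual pair, reports the maximal intervals where any
#' haplotype of one shares a founder haplotype id with any haplotype of the
#' other. Centimorgan lengths follow the configured uniform map.
#'
#' @param cohort A `sim_cohort`.
#' @param min_bp Minimum segment length in bp; shorter intervals dropped.
#' @param samples Tibble with columns `sample_id`, `deme`, `idx` selecting
#'   individuals (the `"sampled"` attribute of [emit_dataset()]); default:
#'   every final-generation individual of every deme.
#' @param within_population_only If `TRUE` (default) only pairs within the
#'   same deme are scanned, the pairs entering the intra-population sharing
#'   statistic [w_int()].
#' @return A tibble of segments: `sample_a`, `sample_b`, `chrom`,
#'   `start_bp`, `end_bp`, `length_bp`, `length_cm`.
#' @export
true_ibd_segments <- function(cohort, min_bp = 1e6, samples = NULL,
                              within_population_only = TRUE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$cfg
  if (is.null(samples)) {
    samples <- purrr::map_dfr(seq_len(nrow(cfg$demes)), function(d)
      tibble(sample_id = paste0(cfg$demes$name[d], "_",
                                seq_along(cohort$demes[[d]])),
             deme = cfg$demes$name[d],
             idx = seq_along(cohort$demes[[d]])))
  }
  n <- nrow(samples)
  L <- cfg$chrom_bp
  res <- list()
  for (a in seq_len(max(n - 1, 0))) for (b in seq(a + 1, n)) {
    if (within_population_only && samples$deme[a] != samples$deme[b]) next
    ia <- cohort$demes[[match(samples$deme[a], cfg$demes$name)]][[samples$idx[a]]]
    ib <- cohort$demes[[match(samples$deme[b], cfg$demes$name)]][[samples$idx[b]]]
    for (cc in seq_len(cfg$n_chrom)) {
      ivs <- rbind(shared_intervals(ia[[1]][[cc]], ib[[1]][[cc]], L),
                   shared_intervals(ia[[1]][[cc]], ib[[2]][[cc]], L),
                   shared_intervals(ia[[2]][[cc]], ib[[1]][[cc]], L),
                   shared_intervals(ia[[2]][[cc]], ib[[2]][[cc]], L))
      if (nrow(ivs) == 0) next
      ivs <- merge_intervals(ivs[, 1], ivs[, 2])
      len <- ivs[, 2] - ivs[, 1]
      keep <- len >= min_bp
      if (!any(keep)) next
      res[[length(res) + 1]] <- tibble(
        sample_a = samples$sample_id[a], sample_b = samples$sample_id[b],
        chrom = as.character(cc),
        start_bp = round(ivs[keep, 1]), end_bp = round(ivs[keep, 2]))
    }
  }
  if (!length(res)) {
    return(tibble(sample_a = character(), sample_b = character(),
                  chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), length_bp = numeric(),
                  length_cm = numeric()))
  }
  out <- bind_rows(res)
  out$length_bp <- out$end_bp - out$start_bp
  out$length_cm <- out$length_bp / 1e6 * cfg$cm_per_mb
  out
}

#' Autozygous genome fraction of simulated individuals
#'
#' Exact fraction of the genome where an individual's two haplotypes carry
#' the same founder haplotype id.
#'
#' @param cohort A `sim_cohort`.
#' @param samples As in [true_ibd_segments()]; default all individuals.
#' @return A tibble: `sample_id`, `deme`, `autozygosity`.
#' @export
autozygosity <- function(cohort, samples = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$cfg
  if (is.null(samples)) {
    samples <- purrr::map_dfr(seq_len(nrow(cfg$demes)), function(d)
      tibble(sample_id = paste0(cfg$demes$name[d], "_",
                                seq_along(cohort$demes[[d]])),
             deme = cfg$demes$name[d],
             idx = seq_along(cohort$demes[[d]])))
  }
  L <- cfg$chrom_bp
  tot <- L * cfg$n_chrom
  fr <- vapply(seq_len(nrow(samples)), function(k) {
    ind <- cohort$demes[[match(samples$deme[k], cfg$demes$name)]][[samples$idx[k]]]
    s <- 0
    for (cc in seq_len(cfg$n_chrom)) {
      iv <- shared_intervals(ind[[1]][[cc]], ind[[2]][[cc]], L)
      if (nrow(iv)) s <- s + sum(iv[, 2] - iv[, 1])
    }
    s / tot
  }, numeric(1))
  tibble(sample_id = samples$sample_id, deme = samples$deme,
         autozygosity = fr)
}

#' Expected inbreeding under stationary drift
#'
#' Closed form of the Wright-Fisher inbreeding recursion:
#' `F(t) = 1 - (1 - 1/(2 Ne))^t`.
#'
#' @param ne Effective population size (>= 1).
#' @param t Generations of drift (>= 0).
#' @return Expected inbreeding coefficient in `[0, 1)`.
#' @export
#' @examples
#' expected_inbreeding(100, 50)
expected_inbreeding <- function(ne, t) {
  stopifnot(all(ne >= 1), all(t >= 0))
  1 - (1 - 1 / (2 * ne))^t
}

#' Bundled study-design fixture
#'
#' A desk-scale analogue of a multi-population isolation survey: 6 open
#' demes (Ne = 2000, 4 generations of drift) and 4 isolated demes
#' (Ne = 100, 200, 400, 800, 30 generations of drift), 25 samples each,
#' 10,000 SNPs over 4 chromosomes of 100 Mb at 1 cM/Mb. Ground-truth
#' within-deme IBD segments (>= 1 Mb) and the closed-form expected
#' inbreeding per deme are returned alongside the genotypes.
#'
#' @param seed Integer seed.
#' @return A list: `ds` (a `geno_ds`), `ibd` (segment tibble), `truth`
#'   (per-deme `ne`, `t`, `expected_f`), and the `cohort`.
#' @export
make_study_fixture <- function(seed = 1L) {
  demes <- tibble(
    name = c(paste0("open", 1:6), paste0("isol", 1:4)),
    group = rep(c("open", "isolated"), c(6, 4)),
    ne = c(rep(2000L, 6), 100L, 200L, 400L, 800L),
    founders = c(rep(2000L, 6), 100L, 200L, 400L, 800L),
    split_gen = c(rep(26L, 6), rep(0L, 4)),
    lat = c(45.1, 47.3, 41.9, 52.2, 40.6, 48.8, 46.5, 46.4, 39.2, 42.5),
    lon = c(7.6, 19.0, 12.5, 21.0, 22.9, 2.3, 12.7, 13.6, 9.1, 1.9))
  cfg <- demography_config(demes, n_generations = 30L, n_chrom = 4L,
                           chrom_bp = 1e8, snps_per_chrom = 2500L,
                           cm_per_mb = 1, seed = seed)
  cohort <- simulate_cohort(cfg)
  ds <- emit_dataset(cohort, 25L)
  ibd <- true_ibd_segments(cohort, min_bp = 1e6,
                           samples = attr(ds, "sampled"))
  truth <- tibble(population = demes$name, group = demes$group,
                  ne = demes$ne, t = cfg$n_generations - demes$split_gen,
                  expected_f = expected_inbreeding(demes$ne,
                    cfg$n_generations - demes$split_gen))
  list(ds = ds, ibd = ibd, truth = truth, cohort = cohort)
}
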