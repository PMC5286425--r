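#' Configuration of a full profiling run
#'
#' @param dataset Optional `geno_ds` (takes precedence over file inputs).
#' @param ped,map Paths to PLINK text genotypes.
#' @param vcf Path to a VCF (alternative to `ped`/`map`).
#' @param meta Metadata tibble or path to a metadata TSV.
#' @param ibd IBD segment tibble or path to a segment TSV (required for the
#'   W_int profile component).
#' @param mask Optional centromere mask tibble or BED path.
#' @param genome_bp Total genome length in bp for F_ROH; default: sum over
#'   chromosomes of the largest mapped position.
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; every stochastic stage derives a child seed
#'   from it.
#' @param roh A [roh_params()].
#' @param max_k Maximum RoH length classes.
#' @param maf_min MAF floor of the Ne estimation.
#' @param pair_policy SNP pairing policy of the Ne estimation.
#' @param max_pairs SNP-pair budget per population for the Ne estimation.
#' @param t_grid Generations grid of the timing envelopes.
#' @param snp_call_min,ind_call_min Call-rate thresholds of the QC stage.
#' @param pihat_max Relatedness pruning threshold.
#' @param ld_max_span_bp Maximum LD-block span.
#' @return A `run_config` list.
#' @export
run_config <- function(dataset = NULL, ped = NULL, map = NULL, vcf = NULL,
                       meta = NULL, ibd = NULL, mask = NULL,
                       genome_bp = NULL, out_dir = tempfile("isopop_run_"),
                       seed = 1L, roh = roh_params(), max_k = 6L,
                       maf_min = 0.05,
                       pair_policy = c("inter_chromosome", "all"),
                       max_pairs = 20000L,
                       t_grid = seq(5, 100, by = 5),
                       snp_call_min = 0.90, ind_call_min = 0.92,
                       pihat_max = 0.185, ld_max_span_bp = 2e5) {
  pair_policy <- match.arg(pair_policy)
  for (p in c(ped, map, vcf)) {
    if (is.character(p) && !file.exists(p)) {
      stop_isopop(paste0("input file does not exist: ", p))
    }
  }
  if (is.character(meta) && !file.exists(meta)) {
    stop_isopop(paste0("metadata file does not exist: ", meta))
  }
  if (is.character(ibd) && !file.exists(ibd)) {
    stop_isopop(paste0("IBD table does not exist: ", ibd))
  }
  structure(list(dataset = dataset, ped = ped, map = map, vcf = vcf,
                 meta = meta, ibd = ibd, mask = mask, genome_bp = genome_bp,
                 out_dir = out_dir, seed = as.integer(seed), roh = roh,
                 max_k = max_k, maf_min = maf_min,
                 pair_policy = pair_policy, max_pairs = max_pairs,
                 t_grid = t_grid, snp_call_min = snp_call_min,
                 ind_call_min = ind_call_min, pihat_max = pihat_max,
                 ld_max_span_bp = ld_max_span_bp),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_isopop(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)))
  })
}

#' Run the full isolation-profiling pipeline
#'
#' Quality control and relatedness pruning, runs of homozygosity (scan,
#' length classes, F_ROH), the remaining intra-population measures, the
#' profile PCA with open-vs-isolated group tests, LD-based effective sizes,
#' time-since-isolation envelopes for isolated populations, and the
#' inter-population structure analyses (distances, geography, MDS,
#' clustering). All tables are written to `cfg$out_dir` as tab-separated
#' files plus a JSON summary.
#'
#' @param cfg A [run_config()].
#' @return An `iso_report` list of every stage result (invisibly); side
#'   effect: the report bundle in `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("isopop pipeline; seed = %d", cfg$seed),
                 sprintf("report schema version 1"))
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  ds <- stage("load", {
    meta <- if (is.character(cfg$meta)) read_sample_meta(cfg$meta) else cfg$meta
    if (!is.null(cfg$dataset)) cfg$dataset
    else if (!is.null(cfg$vcf)) read_vcf(cfg$vcf, meta)
    else if (!is.null(cfg$ped)) read_plink_text(cfg$ped, cfg$map, meta)
    else stop_isopop("no genotype input configured")
  })
  ibd <- stage("load", {
    if (is.null(cfg$ibd)) NULL
    else if (is.character(cfg$ibd)) read_ibd_table(cfg$ibd) else cfg$ibd
  })
  mask <- stage("load", {
    if (is.null(cfg$mask)) NULL
    else if (is.character(cfg$mask)) read_bed_mask(cfg$mask) else cfg$mask
  })
  note("loaded %d samples x %d SNPs", nrow(ds$geno), ncol(ds$geno))

  ds <- stage("qc", {
    out <- qc_filter(ds, cfg$snp_call_min, cfg$ind_call_min)
    note("%s", attr(out, "qc_log"))
    out <- relatedness_prune(out, cfg$pihat_max, seed = cfg$seed)
    note("relatedness pruning (PI_HAT > %g) removed %d sample(s)",
         cfg$pihat_max, length(attr(out, "pruned_samples")))
    out
  })
  genome_bp <- cfg$genome_bp %||%
    sum(tapply(ds$map$pos_bp, ds$map$chrom, max))

  rohres <- stage("roh", {
    seg <- scan_roh(ds, cfg$roh)
    mix <- if (nrow(seg) > cfg$max_k) {
      classify_roh_lengths(seg, max_k = cfg$max_k,
                           seed = child_seed(cfg$seed, 3L))
    } else NULL
    seg_cl <- if (is.null(mix)) seg else mix$segments
    fr <- froh(seg_cl, genome_bp = genome_bp, mask = mask,
               sample_ids = ds$meta$sample_id)
    froh_pop <- fr |>
      left_join(select(ds$meta, "sample_id", "population"),
                by = "sample_id") |>
      group_by(.data$population) |>
      summarise(mean_froh = mean(.data$froh), .groups = "drop")
    note("RoH: %d segments, %s length classes", nrow(seg_cl),
         if (is.null(mix)) "no" else as.character(mix$k))
    list(segments = seg_cl, mixture = mix,
         summary = roh_population_summary(seg_cl, ds$meta),
         froh = fr, froh_pop = froh_pop)
  })

  divres <- stage("diversity", {
    het <- observed_heterozygosity(ds)
    disp <- interlocus_dispersion(ds)
    ibs <- pairwise_ibs(ds)
    intra <- intra_population_ibs(ibs, ds$meta)
    ld <- ld_block_summary(ds, max_span_bp = cfg$ld_max_span_bp)
    if (is.null(ibd)) {
      stop_isopop("no IBD segment table configured; w_int cannot be computed")
    }
    wint <- purrr::map_dfr(unique(ds$meta$population), function(p) {
      ids <- ds$meta$sample_id[ds$meta$population == p]
      mutate(w_int(ibd, ids), population = p, .before = 1)
    })
    list(het = het, dispersion = disp, ibs = ibs, intra_ibs = intra,
         ld = ld, wint = wint)
  })

  profiles <- stage("profiles", {
    build_profiles(divres$het, divres$dispersion, rohres$summary,
                   divres$intra_ibs, divres$wint, divres$ld,
                   rohres$froh_pop)
  })
  prof_groups <- distinct(ds$meta, .data$population, .data$group)
  profiles <- left_join(profiles, prof_groups, by = "population")

  structure_res <- stage("structure", {
    pca <- isolation_pca(profiles)
    core <- c("hom", "interlocus_disp", "mean_roh_count",
              "mean_roh_total_bp", "mean_intra_ibs", "w_int",
              "mean_ld_block_bp")
    tests <- group_compare(profiles, measures = intersect(core,
                                                          names(profiles)))
    dm <- distance_matrix(divres$ibs, ds$meta)
    pop_gen <- population_distance(divres$ibs, ds$meta)
    mds <- classical_mds(dm$dist, k = 2, meta = ds$meta)
    clus <- hierarchical_cluster(pop_gen)
    geo <- NULL; ibd_reg <- NULL
    if (all(c("lat", "lon") %in% names(ds$meta))) {
      coords <- distinct(ds$meta, .data$population, .data$lat, .data$lon)
      geo <- geographic_distances(coords)
      open_pops <- unique(ds$meta$population[ds$meta$group == "open"])
      pops <- rownames(pop_gen)
      ibd_reg <- ibd_distance_regression(pop_gen, geo[pops, pops], open_pops)
    }
    list(pca = pca, group_tests = tests, dist = dm, pop_dist = pop_gen,
         mds = mds, cluster = clus, geo = geo, ibd_regression = ibd_reg)
  })

  ne <- stage("ne", {
    estimate_ne(ds, maf_min = cfg$maf_min, pair_policy = cfg$pair_policy,
                max_pairs = cfg$max_pairs, seed = child_seed(cfg$seed, 5L))
  })

  envelopes <- stage("timing", {
    open_f <- rohres$froh_pop$mean_froh[
      rohres$froh_pop$population %in%
        ds$meta$population[ds$meta$group == "open"]]
    iso_pops <- unique(ds$meta$population[ds$meta$group == "isolated"])
    purrr::map(setNames(iso_pops, iso_pops), function(p) {
      fo <- rohres$froh_pop$mean_froh[rohres$froh_pop$population == p]
      tryCatch(isolation_envelope(fo, open_f, cfg$t_grid, population = p),
               isopop_error = function(e) NULL)
    })
  })

  report <- structure(list(
    schema_version = 1L, seed = cfg$seed, dataset = ds,
    genome_bp = genome_bp, roh = rohres, diversity = divres,
    profiles = profiles, structure = structure_res, ne = ne,
    envelopes = envelopes, log = log_lines, out_dir = cfg$out_dir),
    class = "iso_report")
  stage("write", write_report(report))
  invisible(report)
}

# population-level genetic distance: mean inter-individual 1 - IBS
population_distance <- function(ibs, meta) {
  meta <- as_tibble(meta)
  pop <- meta$population[match(rownames(ibs), meta$sample_id)]
  pops <- sort(unique(pop))
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)) for (b in seq_along(pops)) {
    if (a >= b) next
    block <- 1 - ibs[pop == pops[a], pop == pops[b], drop = FALSE]
    d[a, b] <- d[b, a] <- mean(block, na.rm = TRUE)
  }
  d
}

write_tsv_file <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name), progress = FALSE)
}

write_report <- function(report) {
  dir <- report$out_dir
  write_tsv_file(report$profiles, dir, "profiles.tsv")
  write_tsv_file(report$roh$segments, dir, "roh_segments.tsv")
  write_tsv_file(report$roh$froh, dir, "froh.tsv")
  write_tsv_file(report$structure$group_tests, dir, "group_tests.tsv")
  write_tsv_file(tidy(report$structure$pca, "scores"), dir, "pca_scores.tsv")
  write_tsv_file(tidy(report$structure$pca, "loadings"), dir,
                 "pca_loadings.tsv")
  write_tsv_file(report$ne, dir, "ne_estimates.tsv")
  write_tsv_file(tidy(report$structure$mds), dir, "mds_coordinates.tsv")
  env_files <- character(0)
  for (p in names(report$envelopes)) {
    if (is.null(report$envelopes[[p]])) next
    fn <- paste0("envelope_", p, ".tsv")
    write_tsv_file(report$envelopes[[p]], dir, fn)
    env_files <- c(env_files, fn)
  }
  writeLines(report$structure$cluster$newick,
             file.path(dir, "population_tree.nwk"))
  writeLines(report$log, file.path(dir, "run_log.txt"))
  summary <- list(
    schema_version = report$schema_version,
    seed = report$seed,
    n_samples = nrow(report$dataset$geno),
    n_snps = ncol(report$dataset$geno),
    genome_bp = report$genome_bp,
    pc1_variance_fraction = report$structure$pca$variance_fraction[1],
    pc2_variance_fraction = report$structure$pca$variance_fraction[2],
    populations = report$profiles$population,
    envelope_files = env_files)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.iso_report <- function(x, ...) {
  cat("<iso_report>\n")
  cat(sprintf("  %d samples, %d SNPs, %d populations\n",
              nrow(x$dataset$geno), ncol(x$dataset$geno),
              nrow(x$profiles)))
  cat(sprintf("  PC1 variance fraction: %.3f\n",
              x$structure$pca$variance_fraction[1]))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}

#' Simulate a cohort and write it as a dataset bundle
#'
#' Writes PLINK text genotypes, a metadata TSV, the ground-truth IBD table
#' and a truth table of per-deme expectations (`ne`, `t`, expected
#' inbreeding) ready for [run_pipeline()] and recovery tests.
#'
#' @param cfg A [demography_config()].
#' @param sample_sizes Per-deme sample counts for [emit_dataset()].
#' @param out_dir Output directory.
#' @param ibd_min_bp Minimum ground-truth IBD segment length.
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_to_files <- function(cfg, sample_sizes, out_dir,
                              ibd_min_bp = 1e6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(cfg)
  ds <- emit_dataset(cohort, sample_sizes)
  ibd <- true_ibd_segments(cohort, min_bp = ibd_min_bp,
                           samples = attr(ds, "sampled"))
  prefix <- file.path(out_dir, "cohort")
  write_plink_text(ds, prefix)
  readr::write_tsv(ds$meta, file.path(out_dir, "meta.tsv"), progress = FALSE)
  write_ibd_table(ibd, file.path(out_dir, "ibd.tsv"))
  truth <- mutate(cfg$demes,
                  t = cfg$n_generations - .data$split_gen,
                  expected_f = expected_inbreeding(.data$ne, .data$t))
  readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  invisible(list(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map"),
                 meta = file.path(out_dir, "meta.tsv"),
                 ibd = file.path(out_dir, "ibd.tsv"),
                 truth = file.path(out_dir, "truth.tsv")))
}

#' Read a demography configuration from a flat key-value file
#'
#' Debian-control-style `key: value` text with whitespace-separated vectors
#' for the per-deme fields. Keys: `deme_name`, `deme_group`, `deme_ne`,
#' optional `deme_founders`, `deme_split_gen`, `deme_lat`, `deme_lon`, and
#' scalars `n_generations`, `n_chrom`, `chrom_bp`, `snps_per_chrom`,
#' `cm_per_mb`, `maf_low`, `maf_high`, `seed`.
#'
#' @param path File path.
#' @return A [demography_config()].
#' @export
read_demography_config <- function(path) {
  kv <- as.list(read.dcf(path)[1, ])
  splitv <- function(x) strsplit(trimws(x), "[ \t,]+")[[1]]
  need <- c("deme_name", "deme_group", "deme_ne", "n_generations")
  if (!all(need %in% names(kv))) {
    stop_isopop(paste0("demography config needs keys: ",
                       paste(setdiff(need, names(kv)), collapse = ", ")))
  }
  demes <- tibble(name = splitv(kv$deme_name),
                  group = splitv(kv$deme_group),
                  ne = as.integer(splitv(kv$deme_ne)))
  if (!is.null(kv$deme_founders)) {
    demes$founders <- as.integer(splitv(kv$deme_founders))
  }
  if (!is.null(kv$deme_split_gen)) {
    demes$split_gen <- as.integer(splitv(kv$deme_split_gen))
  }
  if (!is.null(kv$deme_lat)) demes$lat <- as.numeric(splitv(kv$deme_lat))
  if (!is.null(kv$deme_lon)) demes$lon <- as.numeric(splitv(kv$deme_lon))
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  demography_config(
    demes, n_generations = as.integer(num("n_generations", 0)),
    n_chrom = as.integer(num("n_chrom", 4)),
    chrom_bp = num("chrom_bp", 1e8),
    snps_per_chrom = as.integer(num("snps_per_chrom", 2500)),
    cm_per_mb = num("cm_per_mb", 1),
    founder_maf = c(num("maf_low", 0.05), num("maf_high", 0.5)),
    seed = as.integer(num("seed", 1)))
}
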