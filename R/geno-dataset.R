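#' Assemble a genotype dataset
#'
#' Bundles a minor-allele dosage matrix, a SNP map and per-sample metadata
#' into a validated `geno_ds` object, the substrate of every statistic in
#' the package.
#'
#' @param geno Integer matrix, samples in rows and SNPs in columns. Entries
#'   are minor-allele dosages 0/1/2, `NA` for missing calls.
#' @param map Data frame with one row per SNP: `snp_id`, `chrom`, `pos_bp`
#'   (1-based), and allele labels `a1` (minor) and `a2` (major). Positions
#'   must be strictly increasing within each chromosome.
#' @param meta Data frame with one row per sample: `sample_id`, `population`,
#'   `group` (one of `"open"` or `"isolated"`), and optional `lat`/`lon`
#'   sampling coordinates in degrees.
#' @return An object of class `geno_ds`: a list with elements `geno`, `map`
#'   (tibble) and `meta` (tibble).
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, NA, 1L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("rs1", "rs2", "rs3")))
#' map <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
#'                   pos_bp = c(100L, 200L, 300L), a1 = "A", a2 = "B")
#' meta <- data.frame(sample_id = c("s1", "s2"), population = "P1",
#'                    group = "open")
#' geno_dataset(g, map, meta)
geno_dataset <- function(geno, map, meta) {
  map <- as_tibble(map)
  meta <- as_tibble(meta)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(map))) {
    stop_isopop("`map` needs columns snp_id, chrom, pos_bp")
  }
  if (!"a1" %in% names(map)) map$a1 <- NA_character_
  if (!"a2" %in% names(map)) map$a2 <- NA_character_
  if (!all(c("sample_id", "population", "group") %in% names(meta))) {
    stop_isopop("`meta` needs columns sample_id, population, group")
  }
  if (nrow(geno) != nrow(meta) || ncol(geno) != nrow(map)) {
    stop_isopop(sprintf(
      "genotype matrix is %d x %d but meta has %d samples and map %d SNPs",
      nrow(geno), ncol(geno), nrow(meta), nrow(map)))
  }
  if (anyDuplicated(meta$sample_id)) stop_isopop("duplicate sample_id in meta")
  if (!all(meta$group %in% c("open", "isolated"))) {
    stop_isopop("meta$group must be 'open' or 'isolated'")
  }
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop_isopop("genotype codes must be 0, 1, 2 or NA")
  if (any(is.na(map$pos_bp)) || any(map$pos_bp < 1)) {
    stop_isopop("map positions must be >= 1")
  }
  if (any(is.na(map$chrom)) || any(!nzchar(map$chrom))) {
    stop_isopop("chromosome labels must be non-empty")
  }
  incr <- tapply(map$pos_bp, map$chrom, function(p) all(diff(p) > 0))
  if (!all(incr)) {
    stop_isopop("map positions must be strictly increasing within chromosomes")
  }
  rownames(geno) <- meta$sample_id
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map, meta = meta), class = "geno_ds")
}

#' @export
print.geno_ds <- function(x, ...) {
  cat(sprintf("<geno_ds> %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  cat(sprintf("  populations: %s\n",
              paste(sort(unique(x$meta$population)), collapse = ", ")))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.geno_ds <- function(x) dim(x$geno)

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param ds A `geno_ds`.
#' @param samples Character vector of sample ids (default all).
#' @param snps Logical or integer index over SNP columns (default all).
#' @return A `geno_ds`.
#' @export
subset_geno <- function(ds, samples = NULL, snps = NULL) {
  stopifnot(inherits(ds, "geno_ds"))
  i <- if (is.null(samples)) seq_len(nrow(ds$geno)) else {
    idx <- match(samples, ds$meta$sample_id)
    if (anyNA(idx)) stop_isopop(paste0("unknown sample ids: ",
      paste(samples[is.na(idx)], collapse = ", ")))
    idx
  }
  j <- if (is.null(snps)) seq_len(ncol(ds$geno)) else snps
  geno_dataset(ds$geno[i, j, drop = FALSE], ds$map[j, , drop = FALSE],
               ds$meta[i, , drop = FALSE])
}

# Re-express dosages so that code 2 counts the minor allele of the current
# sample; ties at frequency 0.5 keep the current orientation when allele
# labels are unknown, else put the lexicographically smaller label first.
orient_minor <- function(geno, a1 = NULL, a2 = NULL) {
  freq <- colMeans(geno, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  flip <- freq > 0.5
  tie <- abs(freq - 0.5) < 1e-12
  if (!is.null(a1) && !is.null(a2)) {
    flip[tie] <- (a1 > a2)[tie]
  }
  if (any(flip)) geno[, flip] <- 2L - geno[, flip, drop = FALSE]
  list(geno = geno, flipped = flip)
}

#' Read a sample metadata table
#'
#' Tab-separated with header columns `sample_id`, `population`, `group`
#' and optional `lat`, `lon`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "population", "group")
  if (!all(need %in% names(meta))) {
    stop_isopop(paste0("metadata must have columns: ",
                       paste(need, collapse = ", ")))
  }
  meta
}

#' Read genotypes from PLINK text files
#'
#' Parses whitespace-separated `.ped`/`.map` files into a [geno_dataset()].
#' Dosages are oriented to the minor allele of the loaded sample; `0 0`
#' allele pairs become missing.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @param meta Sample metadata table (see [read_sample_meta()]); matched to
#'   the `.ped` individual ids.
#' @return A `geno_ds`.
#' @export
read_plink_text <- function(ped_path, map_path, meta) {
  map_raw <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map_raw) != 4) {
    stop_isopop(sprintf(".map must have 4 columns, found %d", ncol(map_raw)))
  }
  map <- tibble(chrom = map_raw[[1]], snp_id = map_raw[[2]],
                pos_bp = as.integer(map_raw[[4]]))
  n_snps <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (any(len != 6 + 2 * n_snps)) {
    stop_isopop(sprintf(
      ".ped rows must have %d columns; rows %s differ",
      6 + 2 * n_snps,
      paste(head(which(len != 6 + 2 * n_snps), 5), collapse = ", ")))
  }
  ped <- do.call(rbind, toks)
  ids <- ped[, 2]
  al1 <- ped[, 6 + 2 * seq_len(n_snps) - 1, drop = FALSE]
  al2 <- ped[, 6 + 2 * seq_len(n_snps), drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_snps)
  a1_lab <- a2_lab <- character(n_snps)
  for (j in seq_len(n_snps)) {
    x1 <- al1[, j]; x2 <- al2[, j]
    miss <- x1 == "0" | x2 == "0"
    seen <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(seen) > 2) {
      stop_isopop(sprintf("SNP %s has %d allele symbols: %s",
                          map$snp_id[j], length(seen),
                          paste(seen, collapse = "/")))
    }
    if (length(seen) == 0) { a1_lab[j] <- "0"; a2_lab[j] <- "0"; next }
    if (length(seen) == 1) seen <- c(seen, "0")
    d <- (x1 == seen[1]) + (x2 == seen[1])
    d[miss] <- NA_integer_
    geno[, j] <- d
    a1_lab[j] <- seen[1]; a2_lab[j] <- seen[2]
  }
  or <- orient_minor(geno, a1_lab, a2_lab)
  a1 <- ifelse(or$flipped, a2_lab, a1_lab)
  a2 <- ifelse(or$flipped, a1_lab, a2_lab)
  map$a1 <- a1; map$a2 <- a2
  meta <- as_tibble(meta)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) {
    stop_isopop(paste0(".ped samples missing from metadata: ",
                       paste(ids[is.na(idx)], collapse = ", ")))
  }
  geno_dataset(or$geno, map[, c("snp_id", "chrom", "pos_bp", "a1", "a2")],
               meta[idx, , drop = FALSE])
}

#' Write a genotype dataset as PLINK text files
#'
#' @param ds A `geno_ds`.
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(ds, prefix) {
  stopifnot(inherits(ds, "geno_ds"))
  map <- ds$map
  a1 <- ifelse(is.na(map$a1), "A", map$a1)
  a2 <- ifelse(is.na(map$a2), "B", map$a2)
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  write.table(data.frame(map$chrom, map$snp_id, 0, map$pos_bp),
              map_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(ds$geno); m <- ncol(ds$geno)
  out <- matrix("", nrow = n, ncol = 6 + 2 * m)
  out[, 1] <- ds$meta$population
  out[, 2] <- ds$meta$sample_id
  out[, 3] <- "0"; out[, 4] <- "0"; out[, 5] <- "0"; out[, 6] <- "-9"
  for (j in seq_len(m)) {
    d <- ds$geno[, j]
    c1 <- ifelse(is.na(d), "0", ifelse(d >= 1, a1[j], a2[j]))
    c2 <- ifelse(is.na(d), "0", ifelse(d == 2, a1[j], a2[j]))
    out[, 6 + 2 * j - 1] <- c1
    out[, 6 + 2 * j] <- c2
  }
  writeLines(apply(out, 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read genotypes from a VCF file
#'
#' Biallelic records only; multiallelic rows are skipped with a warning
#' giving the count. `./.` genotypes become missing; dosages are ALT counts
#' re-oriented to the minor allele per locus.
#'
#' @param vcf_path Path to a VCF 4.x file with GT fields.
#' @param meta Sample metadata table; its sample set must equal the VCF's.
#' @return A `geno_ds`.
#' @export
read_vcf <- function(vcf_path, meta) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop_isopop("VCF contains no records")
  keyed <- grepl("(^|:)GT(:|$)", fix$FORMAT)
  if (!all(keyed)) stop_isopop("VCF records lack a GT format key")
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("skipping %d multiallelic VCF record(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- colnames(gt)
  meta <- as_tibble(meta)
  if (!setequal(ids, meta$sample_id)) {
    only_vcf <- setdiff(ids, meta$sample_id)
    only_meta <- setdiff(meta$sample_id, ids)
    stop_isopop(paste0(
      "VCF and metadata sample sets disagree",
      if (length(only_vcf)) paste0("; only in VCF: ",
                                   paste(only_vcf, collapse = ", ")) else "",
      if (length(only_meta)) paste0("; only in metadata: ",
                                    paste(only_meta, collapse = ", ")) else ""))
  }
  clean <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  geno <- t(dos)
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, ":", fix$POS), fix$ID)
  or <- orient_minor(geno, fix$ALT, fix$REF)
  map <- tibble(snp_id = snp_id, chrom = fix$CHROM,
                pos_bp = as.integer(fix$POS),
                a1 = ifelse(or$flipped, fix$REF, fix$ALT),
                a2 = ifelse(or$flipped, fix$ALT, fix$REF))
  idx <- match(ids, meta$sample_id)
  geno_dataset(or$geno, map, meta[idx, , drop = FALSE])
}

#' Read an identity-by-descent segment table
#'
#' Tab-separated with header `sample_a`, `sample_b`, `chrom`, `start_bp`,
#' `end_bp` and optional `length_cm`. Rows violating `end_bp > start_bp` are
#' rejected with a warning naming the row numbers.
#'
#' @param path File path.
#' @return A tibble of segments with a `length_bp` column
#'   (`end_bp - start_bp`).
#' @export
read_ibd_table <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_a", "sample_b", "chrom", "start_bp", "end_bp")
  if (!all(need %in% names(seg))) {
    stop_isopop(paste0("IBD table must have columns: ",
                       paste(need, collapse = ", ")))
  }
  bad <- seg$end_bp <= seg$start_bp | seg$sample_a == seg$sample_b
  if (any(bad)) {
    warn(sprintf("rejecting %d invalid IBD row(s): %s", sum(bad),
                 paste(head(which(bad), 10), collapse = ", ")))
    seg <- seg[!bad, , drop = FALSE]
  }
  seg$length_bp <- seg$end_bp - seg$start_bp
  if (!"length_cm" %in% names(seg)) seg$length_cm <- NA_real_
  as_tibble(seg)
}

#' Write an identity-by-descent segment table
#'
#' @param segments Tibble as returned by [read_ibd_table()] or
#'   [true_ibd_segments()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ibd_table <- function(segments, path) {
  cols <- intersect(c("sample_a", "sample_b", "chrom", "start_bp", "end_bp",
                      "length_cm"), names(segments))
  readr::write_tsv(segments[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a BED interval mask
#'
#' Three-column BED (0-based, half-open); converted on load to the package's
#' 1-based half-open convention so that `end_bp - start_bp` is the interval
#' length.
#'
#' @param path File path.
#' @return A tibble with `chrom`, `start_bp`, `end_bp`.
#' @export
read_bed_mask <- function(path) {
  bed <- read.table(path, header = FALSE,
                    colClasses = c("character", "numeric", "numeric"))
  tibble(chrom = bed[[1]],
         start_bp = as.integer(bed[[2]]) + 1L,
         end_bp = as.integer(bed[[3]]) + 1L)
}
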