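#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

VARIANT_CLASSES <- c("SNV", "INSERTION", "DELETION", "MNV")

VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "vclass", "indel_len",
                  "sample", "filter_pass", "info")

#' Normalize a variant to its minimal representation
#'
#' Trims bases shared by the reference and alternate alleles so that
#' equivalent variant representations compare equal. Shared trailing bases
#' are removed first, then shared leading bases, always retaining one anchor
#' base when either allele would otherwise become empty. The position is
#' advanced by the number of leading bases removed. The operation is
#' idempotent and never changes the genomic change the variant encodes.
#'
#' @param pos Integer vector of 1-based positions.
#' @param ref Character vector of reference alleles (ACGTN).
#' @param alt Character vector of alternate alleles (ACGTN).
#' @return A `data.frame` with columns `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant(100, "CAG", "CG")   # -> pos 100, CA / C
#' normalize_variant(100, "TAAA", "TAA") # -> pos 100, TA / T
#' @export
normalize_variant <- function(pos, ref, alt) {
  n <- length(pos)
  stopifnot(length(ref) == n, length(alt) == n)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("invalid variant: empty allele")
  if (any(ref == alt))
    stop("invalid variant: ref == alt")
  out_pos <- pos; out_ref <- ref; out_alt <- alt
  for (i in seq_len(n)) {
    r <- strsplit(out_ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(out_alt[i], "", fixed = TRUE)[[1]]
    # trim shared suffix, keep at least 1 base in each allele
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim shared prefix, keeping one anchor base when either allele would empty
    shift <- 0L
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      shift <- shift + 1L
    }
    out_pos[i] <- out_pos[i] + shift
    out_ref[i] <- paste(r, collapse = "")
    out_alt[i] <- paste(a, collapse = "")
  }
  data.frame(pos = out_pos, ref = out_ref, alt = out_alt,
             stringsAsFactors = FALSE)
}

#' Classify a normalized variant
#'
#' Assigns one of `SNV`, `INSERTION`, `DELETION`, `MNV` from normalized
#' allele lengths, together with the indel length (absolute allele length
#' difference; 0 for SNV and MNV).
#'
#' @param ref,alt Character vectors of normalized alleles (ACGTN).
#' @return A `data.frame` with columns `vclass` and `indel_len`.
#' @examples
#' classify_variant("A", "G")     # SNV
#' classify_variant("ACGT", "A")  # 3 bp DELETION
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(grepl("[^ACGTN]", c(ref, alt))))
    stop("invalid allele: non-ACGTN character")
  lr <- nchar(ref); la <- nchar(alt)
  indel_len <- abs(lr - la)
  vclass <- ifelse(lr == 1L & la == 1L, "SNV",
            ifelse(la > lr, "INSERTION",
            ifelse(lr > la, "DELETION", "MNV")))
  data.frame(vclass = vclass, indel_len = as.integer(indel_len),
             stringsAsFactors = FALSE)
}

#' Variant identity keys
#'
#' Two records are the same variant, for overlap and membership purposes,
#' iff they have equal keys: chromosome, normalized position and normalized
#' alleles.
#'
#' @param variants A variant `data.frame` (columns `chrom`, `pos`, `ref`,
#'   `alt`).
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

# Read header lines of a (possibly gzipped) VCF and validate.
.check_vcf_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L)
    stop("VCF format error in '", path, "': empty file (line 1)")
  if (!startsWith(first, "##fileformat=VCF"))
    stop("VCF format error in '", path,
         "': line 1 must be a ##fileformat=VCF header, got: ",
         substr(first, 1, 60))
  invisible(TRUE)
}

#' Read a VCF file into normalized, classified variant records
#'
#' Parses a VCF v4.x file (plain or gzip/bgzip compressed), splits
#' multi-allelic sites into one record per ALT allele, normalizes each
#' allele pair ([normalize_variant()]) and classifies it
#' ([classify_variant()]). Symbolic ALT alleles (`<DEL>`, breakends, `*`)
#' are skipped and counted in the `n_skipped_symbolic` attribute. INFO
#' strings are preserved verbatim.
#'
#' For multi-sample VCFs read with `sample_label = NULL`, one record is
#' emitted per sample column carrying a non-reference genotype call;
#' genotypes themselves are not otherwise used.
#'
#' @param path Path to a VCF file.
#' @param sample_label Sample label attached to every record. If `NULL` and
#'   the VCF has genotype columns, the VCF sample names are used and records
#'   are attributed to samples with a non-reference genotype.
#' @param pass_only If `TRUE` (default), keep only records whose FILTER is
#'   `PASS` or `.`.
#' @return A `data.frame` of variant records with columns `chrom`, `pos`,
#'   `ref`, `alt`, `vclass`, `indel_len`, `sample`, `filter_pass`, `info`.
#' @export
read_vcf <- function(path, sample_label = NULL, pass_only = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: no such file '", path, "'")
  .check_vcf_header(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vclass = character(),
                      indel_len = integer(), sample = character(),
                      filter_pass = logical(), info = character(),
                      stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    attr(empty, "n_skipped_symbolic") <- 0L
    return(empty)
  }
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  filter_pass <- filt %in% c("PASS", ".")
  info <- fix[, "INFO"]
  info[is.na(info)] <- "."

  # per-site sample attribution
  gt_samples <- NULL
  if (is.null(sample_label)) {
    if (ncol(v@gt) >= 2L) {
      gtm <- vcfR::extract.gt(v, element = "GT")
      gt_samples <- colnames(gtm)
    } else {
      stop("VCF '", path, "' has no genotype columns; supply sample_label")
    }
  }

  rows <- vector("list", nrow(fix))
  n_sym <- 0L
  for (i in seq_len(nrow(fix))) {
    if (pass_only && !filter_pass[i]) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ref0 <- fix[i, "REF"]
    pos0 <- as.integer(fix[i, "POS"])
    for (j in seq_along(alts)) {
      a <- alts[j]
      if (is.na(a) || a == "" || grepl("[^ACGTNacgtn]", a)) {
        n_sym <- n_sym + 1L
        next
      }
      if (toupper(a) == toupper(ref0)) next
      labs <- if (!is.null(sample_label)) sample_label else {
        gts <- gtm[i, , drop = TRUE]
        carriers <- vapply(seq_along(gts), function(s) {
          g <- gts[s]
          if (is.na(g)) return(FALSE)
          as.character(j) %in% strsplit(g, "[/|]")[[1]]
        }, logical(1))
        gt_samples[carriers]
      }
      if (length(labs) == 0L) next
      nv <- normalize_variant(pos0, ref0, a)
      cl <- classify_variant(nv$ref, nv$alt)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = nv$pos, ref = nv$ref, alt = nv$alt,
        vclass = cl$vclass, indel_len = cl$indel_len,
        sample = labs, filter_pass = filter_pass[i], info = info[i],
        stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "n_skipped_symbolic") <- n_sym
  out
}

#' Assemble a replicated cohort from a file manifest
#'
#' Builds the cohort object that all summaries run over: named groups of
#' replicate samples, each sample backed by the variant records of one VCF
#' file. Sample order follows manifest order.
#'
#' @param manifest A `data.frame` with columns `path`, `group`, `sample`
#'   (one VCF file per row), or a path to a TSV/CSV file with those columns.
#' @param pass_only Passed to [read_vcf()].
#' @return A `variant_cohort` object: a list with elements `samples`
#'   (data.frame `sample`, `group` in manifest order) and `variants` (row-bound
#'   variant records of all samples).
#' @export
assemble_cohort <- function(manifest, pass_only = TRUE) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  req <- c("path", "group", "sample")
  if (!is.data.frame(manifest) || !all(req %in% names(manifest)))
    stop("configuration error: manifest needs columns path, group, sample")
  if (nrow(manifest) == 0L)
    stop("configuration error: empty manifest")
  if (anyDuplicated(manifest$sample))
    stop("configuration error: duplicate sample label(s): ",
         paste(unique(manifest$sample[duplicated(manifest$sample)]),
               collapse = ", "))
  vars <- lapply(seq_len(nrow(manifest)), function(i)
    read_vcf(manifest$path[i], sample_label = manifest$sample[i],
             pass_only = pass_only))
  variants <- do.call(rbind, vars)
  rownames(variants) <- NULL
  new_cohort(variants,
             samples = data.frame(sample = manifest$sample,
                                  group = manifest$group,
                                  stringsAsFactors = FALSE))
}

#' Construct a cohort from in-memory variant records
#'
#' @param variants Variant record `data.frame` (see [read_vcf()]).
#' @param samples `data.frame` with columns `sample` and `group`; defines the
#'   group/replicate structure and the canonical sample order.
#' @return A `variant_cohort` object.
#' @export
new_cohort <- function(variants, samples) {
  stopifnot(is.data.frame(samples), all(c("sample", "group") %in% names(samples)))
  if (anyDuplicated(samples$sample))
    stop("configuration error: duplicate sample label")
  if (nrow(samples) == 0L)
    stop("configuration error: no samples")
  missing_cols <- setdiff(VARIANT_COLS, names(variants))
  if (length(missing_cols))
    stop("variant table missing columns: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(unique(variants$sample), samples$sample)
  if (length(unknown))
    stop("configuration error: variants for unlisted sample(s): ",
         paste(unknown, collapse = ", "))
  structure(list(variants = as.data.frame(variants),
                 samples = data.frame(sample = as.character(samples$sample),
                                      group = as.character(samples$group),
                                      stringsAsFactors = FALSE)),
            class = "variant_cohort")
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat("variant_cohort:", nrow(x$samples), "samples in",
      length(unique(x$samples$group)), "groups;",
      nrow(x$variants), "variant records\n")
  tab <- table(factor(x$variants$sample, levels = x$samples$sample))
  for (g in unique(x$samples$group)) {
    s <- x$samples$sample[x$samples$group == g]
    cat("  ", g, ": ", paste(sprintf("%s(%d)", s, tab[s]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Samples of one group of a cohort
#' @param cohort A `variant_cohort`.
#' @param group Group label.
#' @return Character vector of sample labels in cohort order.
#' @export
group_samples <- function(cohort, group) {
  if (!group %in% cohort$samples$group)
    stop("configuration error: unknown group '", group, "'")
  cohort$samples$sample[cohort$samples$group == group]
}

#' Extract a single INFO key from variant records
#'
#' @param variants Variant record `data.frame`.
#' @param key INFO key name.
#' @return Character vector of values (`NA` where absent).
#' @export
info_field <- function(variants, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(variants$info, regexec(pat, variants$info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Write variant records as a long-format TSV
#'
#' Stable column order, LF line endings; the `group` column is filled from
#' the cohort's sample table. Annotation columns (`feature`, `genes`,
#' `distance`, `known_site`) are appended when present.
#'
#' @param cohort A `variant_cohort`.
#' @param path Output path.
#' @return Invisibly, the written path.
#' @export
write_variants_tsv <- function(cohort, path) {
  v <- cohort$variants
  v$group <- cohort$samples$group[match(v$sample, cohort$samples$sample)]
  cols <- c("sample", "group", "chrom", "pos", "ref", "alt", "vclass",
            "indel_len", "filter_pass", "info")
  extra <- intersect(c("feature", "genes", "distance", "known_site",
                       "site_id"), names(v))
  write_tsv_atomic(v[, c(cols, extra)], path)
}

#' Write variant records of a cohort back to per-sample VCF files
#'
#' Emits one minimal, valid VCF v4.2 per sample (fileformat, contig and
#' FILTER header lines; records sorted by chromosome then position).
#'
#' @param cohort A `variant_cohort`.
#' @param dir Output directory (created if absent).
#' @param contigs Named integer vector of chromosome lengths for the header.
#' @return Named character vector of written paths (by sample).
#' @export
write_cohort_vcfs <- function(cohort, dir, contigs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in cohort$samples$sample) {
    v <- cohort$variants[cohort$variants$sample == s, , drop = FALSE]
    p <- file.path(dir, paste0(s, ".vcf"))
    write_vcf(v, p, contigs)
    paths[s] <- p
  }
  paths
}

# Write a single-sample VCF from variant records.
write_vcf <- function(variants, path, contigs) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "##FILTER=<ID=PASS,Description=\"All filters passed\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  v <- variants[order(match(variants$chrom, names(contigs)), variants$pos,
                      variants$ref, variants$alt), , drop = FALSE]
  info <- if ("info" %in% names(v)) v$info else rep(".", nrow(v))
  info[is.na(info) | info == ""] <- "."
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  v$chrom, v$pos, v$ref, v$alt,
                  ifelse(v$filter_pass, "PASS", "lowqual"), info)
  writeLines(c(hdr, body), path, sep = "\n")
  invisible(path)
}

# Deterministic TSV writer: tab separated, LF endings, write-to-temp then
# atomic rename so failed runs leave no partial files.
write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  data.table::fwrite(df, tmp, sep = "\t", quote = FALSE, eol = "\n",
                     na = "NA")
  if (!file.rename(tmp, path)) stop("cannot write '", path, "'")
  invisible(path)
}
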