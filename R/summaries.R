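SUB12 <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
           "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
SUB6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Collapse a base substitution to its pyrimidine-reference class
#'
#' Substitutions with a purine reference (A or G) are mapped to the
#' strand-complementary pyrimidine class by complementing both alleles
#' (e.g. `G>T` -> `C>A`); pyrimidine-reference classes pass through.
#'
#' @param sub Character vector of 12-class labels (`"A>C"` ... `"T>G"`).
#' @return Character vector of 6-class labels.
#' @export
collapse_substitution <- function(sub) {
  ref <- substr(sub, 1, 1)
  alt <- substr(sub, 3, 3)
  purine <- ref %in% c("A", "G")
  ref[purine] <- .COMPLEMENT[substr(sub, 1, 1)[purine]]
  alt[purine] <- .COMPLEMENT[substr(sub, 3, 3)[purine]]
  paste0(ref, ">", alt)
}

.sample_group <- function(cohort) {
  stats::setNames(cohort$samples$group, cohort$samples$sample)
}

# Long-format summary assembly: one row per sample x category, counts from
# `tab` (named by category within sample), zero-filled, frequencies within
# sample. Sample order = cohort order; category order = `levels`.
.long_summary <- function(cohort, per_sample_counts, levels) {
  grp <- .sample_group(cohort)
  out <- do.call(rbind, lapply(cohort$samples$sample, function(s) {
    cnt <- per_sample_counts[[s]]
    if (is.null(cnt)) cnt <- integer(0)
    full <- stats::setNames(rep(0L, length(levels)), levels)
    full[names(cnt)] <- as.integer(cnt)
    tot <- sum(full)
    data.frame(sample = s, group = unname(grp[s]), category = levels,
               count = as.integer(full),
               frequency = if (tot > 0) as.numeric(full) / tot else rep(0, length(full)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample variant totals by class
#'
#' Counts total, SNV, insertion, deletion and MNV records per sample. The
#' `frequency` column is the class share of the sample total; the `total`
#' row carries frequency 1 (or 0 for an empty sample).
#'
#' @param cohort A `variant_cohort`.
#' @return Long-format summary `data.frame` (`sample`, `group`, `category`,
#'   `count`, `frequency`).
#' @export
count_variants <- function(cohort) {
  v <- cohort$variants
  counts <- lapply(stats::setNames(nm = cohort$samples$sample), function(s) {
    tab <- table(factor(v$vclass[v$sample == s], levels = VARIANT_CLASSES))
    c(tab, total = sum(tab))
  })
  out <- .long_summary(cohort, lapply(counts, function(x) x[VARIANT_CLASSES]),
                       VARIANT_CLASSES)
  tot <- do.call(rbind, lapply(cohort$samples$sample, function(s)
    data.frame(sample = s, group = .sample_group(cohort)[[s]],
               category = "total", count = as.integer(counts[[s]]["total"]),
               frequency = as.numeric(counts[[s]]["total"] > 0),
               stringsAsFactors = FALSE)))
  out <- rbind(tot, out)
  out <- out[order(match(out$sample, cohort$samples$sample),
                   match(out$category, c("total", VARIANT_CLASSES))), ]
  rownames(out) <- NULL
  out
}

#' Replicate overlap (Venn region) counts for one group
#'
#' Counts, for every non-empty subset of a group's replicate samples, the
#' variants (by normalized [variant_key()]) present in exactly that subset
#' of replicates. Region counts sum to the size of the union of the group's
#' key sets.
#'
#' @param cohort A `variant_cohort`.
#' @param group Group label.
#' @return A `data.frame` with columns `subset` (sample labels joined by
#'   `&`, in cohort order), `n_samples`, `count`; one row per non-empty
#'   subset, including empty regions.
#' @export
replicate_overlap <- function(cohort, group) {
  samples <- group_samples(cohort, group)
  keysets <- lapply(samples, function(s)
    unique(variant_key(cohort$variants[cohort$variants$sample == s, ,
                                       drop = FALSE])))
  names(keysets) <- samples
  allkeys <- unique(unlist(keysets, use.names = FALSE))
  member <- vapply(keysets, function(k) allkeys %in% k,
                   logical(length(allkeys)))
  if (length(allkeys) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, samples))
  n <- length(samples)
  subsets <- lapply(seq_len(2^n - 1L), function(m)
    which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L))
  out <- do.call(rbind, lapply(subsets, function(ix) {
    inside <- rep(TRUE, length(allkeys))
    if (length(allkeys)) {
      for (j in seq_len(n)) {
        want <- j %in% ix
        inside <- inside & (member[, j] == want)
      }
    }
    data.frame(subset = paste(samples[ix], collapse = "&"),
               n_samples = length(ix),
               count = sum(inside), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$n_samples, out$subset), ]
  rownames(out) <- NULL
  attr(out, "union_size") <- length(allkeys)
  out
}

#' Base substitution spectrum per sample
#'
#' Tallies SNV base changes per sample as frequencies against the sample's
#' total SNV background. With `collapse = TRUE` (default) the six
#' pyrimidine-reference classes are used ([collapse_substitution()]); with
#' `collapse = FALSE` all twelve directed classes. Samples with no SNVs
#' get zero counts and zero frequencies and are listed in the
#' `zero_snv_samples` attribute.
#'
#' @param cohort A `variant_cohort`.
#' @param collapse Collapse to 6 pyrimidine-reference classes?
#' @return Long-format summary `data.frame`.
#' @export
substitution_spectrum <- function(cohort, collapse = TRUE) {
  v <- cohort$variants[cohort$variants$vclass == "SNV", , drop = FALSE]
  sub <- paste0(v$ref, ">", v$alt)
  if (collapse) sub <- collapse_substitution(sub)
  levels <- if (collapse) SUB6 else SUB12
  counts <- lapply(stats::setNames(nm = cohort$samples$sample), function(s)
    table(factor(sub[v$sample == s], levels = levels)))
  out <- .long_summary(cohort, counts, levels)
  zero <- cohort$samples$sample[vapply(counts, sum, 0) == 0]
  attr(out, "zero_snv_samples") <- zero
  out
}

# Bin labels from integer lower bounds, e.g. c(1,2,3,4,6,11) ->
# "1","2","3","4-5","6-10",">10".
indel_bin_labels <- function(bin_edges) {
  n <- length(bin_edges)
  labs <- character(n)
  for (i in seq_len(n - 1L)) {
    lo <- bin_edges[i]; hi <- bin_edges[i + 1L] - 1L
    labs[i] <- if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }
  labs[n] <- paste0(">", bin_edges[n] - 1L)
  labs
}

#' Indel length distribution per sample
#'
#' Bins insertion and deletion lengths into ranges and reports per-sample
#' counts and frequencies, separately for insertions and deletions. The
#' default bins are 1, 2, 3, 4-5, 6-10 and >10 bp.
#'
#' @param cohort A `variant_cohort`.
#' @param bin_edges Strictly increasing integer lower bounds of the bins;
#'   the last bin is open-ended.
#' @return Long-format summary `data.frame` with an extra `indel_type`
#'   column (`INSERTION`/`DELETION`); frequencies are within sample and
#'   indel type.
#' @export
indel_length_distribution <- function(cohort, bin_edges = c(1L, 2L, 3L, 4L, 6L, 11L)) {
  if (length(bin_edges) < 1L || is.unsorted(bin_edges, strictly = TRUE))
    stop("configuration error: bin_edges must be strictly increasing")
  if (bin_edges[1] != 1L)
    stop("configuration error: first bin must start at length 1")
  labs <- indel_bin_labels(bin_edges)
  out <- do.call(rbind, lapply(c("INSERTION", "DELETION"), function(ty) {
    v <- cohort$variants[cohort$variants$vclass == ty, , drop = FALSE]
    bin <- labs[findInterval(v$indel_len, bin_edges)]
    counts <- lapply(stats::setNames(nm = cohort$samples$sample), function(s)
      table(factor(bin[v$sample == s], levels = labs)))
    res <- .long_summary(cohort, counts, labs)
    res$indel_type <- ty
    res
  }))
  rownames(out) <- NULL
  out[, c("sample", "group", "indel_type", "category", "count", "frequency")]
}

#' Read chromosome sizes from a FASTA index or two-column TSV
#'
#' @param path Path to a `.fai` index (name/length in the first two columns)
#'   or a `chrom<TAB>length` TSV.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (is.character(df[[2]]) && is.na(suppressWarnings(as.integer(df[[2]][1]))))
    df <- df[-1, , drop = FALSE]  # header line
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Per-window variant density across the genome
#'
#' Tiles each chromosome with fixed-width windows (`[1, w]`, `[w+1, 2w]`,
#' ..., last truncated at the chromosome end) and counts SNVs and indels per
#' window per sample — the data behind a Circos-style density track. MNVs
#' are counted in neither column. Variants on chromosomes absent from
#' `chrom_sizes` go to an `unplaced` row (with `NA` coordinates) and raise a
#' warning.
#'
#' @param cohort A `variant_cohort`.
#' @param chrom_sizes Named integer vector of chromosome lengths, or a path
#'   accepted by [read_chrom_sizes()].
#' @param window_bp Window width in bp (default 1e6).
#' @return A `data.frame` with columns `chrom`, `window_start`,
#'   `window_end`, `sample`, `snv_count`, `indel_count`.
#' @export
genome_distribution <- function(cohort, chrom_sizes, window_bp = 1e6) {
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  window_bp <- as.integer(window_bp)
  if (window_bp < 1L) stop("configuration error: window_bp must be >= 1")
  wins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(1L, len, by = window_bp)
    data.frame(chrom = ch, window_start = starts,
               window_end = pmin(starts + window_bp - 1L, len),
               stringsAsFactors = FALSE)
  }))
  v <- cohort$variants
  unplaced <- !(v$chrom %in% names(chrom_sizes))
  if (any(unplaced))
    warning(sum(unplaced), " variant(s) on chromosomes absent from ",
            "chrom_sizes; counted as 'unplaced'")
  out <- do.call(rbind, lapply(cohort$samples$sample, function(s) {
    vs <- v[v$sample == s, , drop = FALSE]
    up <- !(vs$chrom %in% names(chrom_sizes))
    w <- wins
    w$sample <- s
    vin <- vs[!up, , drop = FALSE]
    widx <- match(vin$chrom, names(chrom_sizes))
    key <- paste(vin$chrom, (vin$pos - 1L) %/% window_bp)
    wkey <- paste(w$chrom, (w$window_start - 1L) %/% window_bp)
    w$snv_count <- as.integer(
      table(factor(key[vin$vclass == "SNV"], levels = wkey)))
    w$indel_count <- as.integer(
      table(factor(key[vin$vclass %in% c("INSERTION", "DELETION")],
                   levels = wkey)))
    if (any(up)) {
      w <- rbind(w, data.frame(
        chrom = "unplaced", window_start = NA_integer_,
        window_end = NA_integer_, sample = s,
        snv_count = sum(up & vs$vclass == "SNV"),
        indel_count = sum(up & vs$vclass %in% c("INSERTION", "DELETION")),
        stringsAsFactors = FALSE))
    }
    w
  }))
  rownames(out) <- NULL
  out[, c("chrom", "window_start", "window_end", "sample", "snv_count",
          "indel_count")]
}

#' Variant distribution over genomic feature categories
#'
#' Per-sample counts and frequencies over the eight feature categories
#' (exonic, splicing, UTR5, UTR3, intronic, upstream, downstream,
#' intergenic). Requires annotated variants ([annotate_variants()]).
#'
#' @param cohort An annotated `variant_cohort`.
#' @return Long-format summary `data.frame`.
#' @export
feature_distribution <- function(cohort) {
  v <- cohort$variants
  if (!"feature" %in% names(v))
    stop("precondition error: cohort is not annotated (no feature column)")
  bad <- unique(v$sample[is.na(v$feature)])
  if (length(bad))
    stop("precondition error: unannotated variants in sample(s): ",
         paste(bad, collapse = ", "))
  counts <- lapply(stats::setNames(nm = cohort$samples$sample), function(s)
    table(factor(v$feature[v$sample == s], levels = FEATURE_CATEGORIES)))
  .long_summary(cohort, counts, FEATURE_CATEGORIES)
}

#' High-frequency mutated genes per sample
#'
#' Ranks genes by descending variant count per sample, restricted to a
#' feature-category subset (default: exonic, splicing, UTR5, UTR3). A
#' variant reporting several genes counts once for each. Ties are broken
#' lexicographically by gene name.
#'
#' @param cohort An annotated `variant_cohort`.
#' @param categories Feature categories to count (subset of the vocabulary).
#' @param top_n Rows to keep per sample.
#' @return `data.frame` with columns `sample`, `group`, `gene`, `count`,
#'   `rank`.
#' @export
gene_mutation_ranking <- function(cohort,
                                  categories = c("exonic", "splicing",
                                                 "UTR5", "UTR3"),
                                  top_n = 10L) {
  if (top_n < 1L) stop("configuration error: top_n must be >= 1")
  if (!all(categories %in% FEATURE_CATEGORIES))
    stop("configuration error: unknown feature categories: ",
         paste(base::setdiff(categories, FEATURE_CATEGORIES), collapse = ", "))
  v <- cohort$variants
  if (!"feature" %in% names(v))
    stop("precondition error: cohort is not annotated (no feature column)")
  grp <- .sample_group(cohort)
  out <- do.call(rbind, lapply(cohort$samples$sample, function(s) {
    vs <- v[v$sample == s & v$feature %in% categories & nzchar(v$genes), ,
            drop = FALSE]
    genes <- unlist(strsplit(vs$genes, ",", fixed = TRUE), use.names = FALSE)
    if (length(genes) == 0L) return(NULL)
    tab <- sort(table(genes), decreasing = TRUE)
    df <- data.frame(sample = s, group = unname(grp[s]),
                     gene = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$gene), , drop = FALSE]
    df <- utils::head(df, top_n)
    df$rank <- seq_len(nrow(df))
    df
  }))
  if (is.null(out))
    out <- data.frame(sample = character(), group = character(),
                      gene = character(), count = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a driver gene list
#'
#' One gene name per line (first column of a TSV; `#` comments and a
#' `gene`/`symbol` header line are ignored).
#'
#' @param path Path to the list file.
#' @return Character vector of gene names.
#' @export
read_driver_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  g <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  g <- g[!tolower(g) %in% c("gene", "symbol", "gene_symbol")]
  unique(g)
}

#' Variant tallies in cancer driver genes
#'
#' Counts, per sample, variants located within genes from a driver-gene
#' list (exact, case-sensitive name match). "Within" means the variant's
#' feature call lies inside the gene body: exonic, splicing, UTR5, UTR3 or
#' intronic; flanking calls (upstream/downstream/intergenic) do not count.
#'
#' @param cohort An annotated `variant_cohort`.
#' @param driver_genes Character vector of driver gene names, or a path
#'   readable by [read_driver_genes()].
#' @return A list of class `driver_tally`: `per_gene` (`sample`, `group`,
#'   `gene`, `count`; only genes with >= 1 variant) and `totals` (`sample`,
#'   `group`, `count`).
#' @export
driver_gene_tally <- function(cohort, driver_genes) {
  if (is.character(driver_genes) && length(driver_genes) == 1L &&
      file.exists(driver_genes))
    driver_genes <- read_driver_genes(driver_genes)
  if (length(driver_genes) == 0L)
    stop("configuration error: empty driver gene list")
  v <- cohort$variants
  if (!"feature" %in% names(v))
    stop("precondition error: cohort is not annotated (no feature column)")
  in_gene <- c("exonic", "splicing", "UTR5", "UTR3", "intronic")
  grp <- .sample_group(cohort)
  per_gene <- list(); totals <- list()
  for (s in cohort$samples$sample) {
    vs <- v[v$sample == s & v$feature %in% in_gene, , drop = FALSE]
    hits <- lapply(strsplit(vs$genes, ",", fixed = TRUE), function(g)
      g[g %in% driver_genes])
    n_hit <- lengths(hits) > 0L
    totals[[s]] <- data.frame(sample = s, group = unname(grp[s]),
                              count = sum(n_hit), stringsAsFactors = FALSE)
    genes <- unlist(hits, use.names = FALSE)
    if (length(genes)) {
      tab <- table(genes)
      df <- data.frame(sample = s, group = unname(grp[s]), gene = names(tab),
                       count = as.integer(tab), stringsAsFactors = FALSE)
      per_gene[[s]] <- df[order(-df$count, df$gene), , drop = FALSE]
    }
  }
  per_gene <- if (length(per_gene)) do.call(rbind, per_gene) else
    data.frame(sample = character(), group = character(), gene = character(),
               count = integer(), stringsAsFactors = FALSE)
  totals <- do.call(rbind, totals)
  rownames(per_gene) <- rownames(totals) <- NULL
  structure(list(per_gene = per_gene, totals = totals),
            class = "driver_tally")
}

#' Write a summary table as deterministic TSV
#'
#' Tab-separated, LF line endings, written atomically (temp file + rename).
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_summary_tsv <- function(df, path) write_tsv_atomic(df, path)
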