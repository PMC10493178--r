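#' @importFrom GenomicRanges GRanges mcols strand seqnames start end width
#'   findOverlaps flank distanceToNearest resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

FEATURE_CATEGORIES <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                        "upstream", "downstream", "intergenic")

#' Annotation parameters
#'
#' @param upstream_downstream_bp Width in bp of the upstream/downstream
#'   windows flanking each transcript, measured on the transcript strand
#'   (default 1000).
#' @param splice_window_bp Intronic positions within this many bp of an
#'   exon/intron boundary are called `splicing` (default 2).
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(upstream_downstream_bp = 1000L,
                              splice_window_bp = 2L) {
  stopifnot(upstream_downstream_bp >= 0, splice_window_bp >= 0)
  structure(list(upstream_downstream_bp = as.integer(upstream_downstream_bp),
                 splice_window_bp = as.integer(splice_window_bp)),
            class = "annotation_config")
}

#' Load gene models from a GTF or GFF3 file
#'
#' Builds an interval index over transcripts, exons, CDS and UTRs supporting
#' feature-category queries. UTRs are derived from CDS versus exon extents
#' when not given explicitly; transcripts without CDS are treated as
#' non-coding and their exons count as exonic. GTF (Ensembl dialect) and
#' GFF3 files describing the same models yield identical query results.
#'
#' @param path Path to a GTF or GFF3 file; the dialect is detected from the
#'   extension (`.gtf` vs `.gff`/`.gff3`) unless `format` is given.
#' @param format Optional override: `"gtf"` or `"gff3"`.
#' @return A `gene_model_index` object.
#' @export
load_gene_models <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read gene models: '", path, "'")
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext == "gtf") "gtf" else "gff3"
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stop("gene model format error in '",
                                          path, "': ", conditionMessage(e)))
  if (length(gr) == 0L) stop("gene model format error: no features in '", path, "'")
  typ <- as.character(gr$type)
  is_tx <- typ %in% c("transcript", "mRNA")
  if (!any(is_tx))
    stop("gene model format error: no transcript features found in '", path, "'")

  if (format == "gtf") {
    tx_id_of <- function(g) as.character(g$transcript_id)
    gene_of_tx <- function(g) as.character(g$gene_id)
    parent_tx <- function(g) as.character(g$transcript_id)
  } else {
    getp <- function(g) vapply(as.list(g$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    tx_id_of <- function(g) as.character(g$ID)
    gene_of_tx <- function(g) getp(g)
    parent_tx <- function(g) getp(g)
  }

  txs <- gr[is_tx]
  tx <- data.frame(tx_id = tx_id_of(txs),
                   gene = gene_of_tx(txs),
                   chrom = as.character(seqnames(txs)),
                   start = start(txs), end = end(txs),
                   strand = as.character(strand(txs)),
                   stringsAsFactors = FALSE)
  if (anyNA(tx$tx_id) || anyNA(tx$gene))
    stop("gene model format error: transcript without identifier/gene in '",
         path, "'")

  pick <- function(what) {
    g <- gr[typ == what]
    if (length(g) == 0L) return(NULL)
    parent <- parent_tx(g)
    bad <- is.na(parent) | !(parent %in% tx$tx_id)
    if (any(bad))
      stop("gene model format error: ", what,
           " without parent transcript (feature #",
           which(typ == what)[which(bad)[1]], ") in '", path, "'")
    data.frame(tx_id = parent, chrom = as.character(seqnames(g)),
               start = start(g), end = end(g), stringsAsFactors = FALSE)
  }
  exons <- pick("exon")
  if (is.null(exons))
    stop("gene model format error: no exon features found in '", path, "'")
  cds <- pick("CDS")

  # exon-within-transcript sanity
  m <- match(exons$tx_id, tx$tx_id)
  if (any(exons$start < tx$start[m] | exons$end > tx$end[m]))
    stop("gene model format error: exon outside its transcript in '", path, "'")

  # Partition each coding transcript's exons into CDS / UTR5 / UTR3 by the
  # CDS extent; strand decides which side is 5'.
  utr5 <- utr3 <- coding_exon <- list()
  noncoding_exon <- list()
  introns <- list()
  for (k in seq_len(nrow(tx))) {
    id <- tx$tx_id[k]
    ex <- exons[exons$tx_id == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L) {
      introns[[id]] <- data.frame(tx_id = id, chrom = tx$chrom[k],
                                  start = head(ex$end, -1) + 1L,
                                  end = tail(ex$start, -1) - 1L,
                                  stringsAsFactors = FALSE)
    }
    cd <- if (is.null(cds)) cds else cds[cds$tx_id == id, , drop = FALSE]
    if (is.null(cd) || nrow(cd) == 0L) {
      noncoding_exon[[id]] <- ex
      next
    }
    cs <- min(cd$start); ce <- max(cd$end)
    cod <- ex
    cod$start <- pmax(cod$start, cs); cod$end <- pmin(cod$end, ce)
    coding_exon[[id]] <- cod[cod$start <= cod$end, , drop = FALSE]
    left <- ex; left$end <- pmin(left$end, cs - 1L)
    left <- left[left$start <= left$end, , drop = FALSE]
    right <- ex; right$start <- pmax(right$start, ce + 1L)
    right <- right[right$start <= right$end, , drop = FALSE]
    if (tx$strand[k] == "-") { tmp <- left; left <- right; right <- tmp }
    utr5[[id]] <- left; utr3[[id]] <- right
  }
  bindgr <- function(lst) {
    df <- do.call(rbind, lst)
    if (is.null(df) || nrow(df) == 0L) {
      g <- GRanges()
      g$tx_id <- character(0)
      g$gene <- character(0)
      return(g)
    }
    g <- GRanges(df$chrom, IRanges(df$start, df$end))
    g$tx_id <- df$tx_id
    g$gene <- tx$gene[match(df$tx_id, tx$tx_id)]
    g
  }
  gr_tx <- GRanges(tx$chrom, IRanges(tx$start, tx$end), strand = tx$strand)
  gr_tx$tx_id <- tx$tx_id; gr_tx$gene <- tx$gene
  gene_df <- do.call(rbind, lapply(split(tx, tx$gene), function(d)
    data.frame(gene = d$gene[1], chrom = d$chrom[1], start = min(d$start),
               end = max(d$end), stringsAsFactors = FALSE)))
  gr_gene <- GRanges(gene_df$chrom, IRanges(gene_df$start, gene_df$end))
  gr_gene$gene <- gene_df$gene

  structure(list(
    tx = tx,
    gr_tx = gr_tx,
    gr_gene = gr_gene,
    gr_exonic = c(bindgr(coding_exon), bindgr(noncoding_exon)),
    gr_utr5 = bindgr(utr5),
    gr_utr3 = bindgr(utr3),
    gr_intron = bindgr(introns),
    n_genes = length(unique(tx$gene)),
    n_transcripts = nrow(tx)
  ), class = "gene_model_index")
}

#' @export
print.gene_model_index <- function(x, ...) {
  cat("gene_model_index:", x$n_genes, "genes,", x$n_transcripts,
      "transcripts on", length(unique(x$tx$chrom)), "chromosome(s)\n")
  invisible(x)
}

.join_genes <- function(genes) paste(sort(unique(genes)), collapse = ",")

#' Annotate variants with genomic feature categories
#'
#' Assigns each variant exactly one feature category by fixed precedence:
#' `exonic > splicing > UTR5 > UTR3 > intronic > upstream > downstream >
#' intergenic`. A variant is exonic if any transcript of any gene places it
#' in a (coding or non-coding) exon; `splicing` means an intronic position
#' within `splice_window_bp` of an exon/intron boundary; upstream and
#' downstream are measured from transcript ends on the transcript strand.
#' Indels are annotated by their anchor (leftmost) position. Intergenic
#' variants report the nearest flanking gene(s) and the distance to the
#' nearest gene; all other categories report the gene(s) that produced the
#' winning category (comma-joined, lexicographically sorted).
#'
#' @param variants Variant record `data.frame` or a `variant_cohort`.
#' @param index A [gene_model_index][load_gene_models()].
#' @param cfg An [annotation_config()].
#' @return The variant table (or cohort) with columns `feature`, `genes`,
#'   `distance` appended.
#' @export
annotate_variants <- function(variants, index, cfg = annotation_config()) {
  if (inherits(variants, "variant_cohort")) {
    variants$variants <- annotate_variants(variants$variants, index, cfg)
    return(variants)
  }
  stopifnot(inherits(index, "gene_model_index"),
            inherits(cfg, "annotation_config"))
  n <- nrow(variants)
  feature <- rep(NA_character_, n)
  genes <- rep("", n)
  distance <- rep(0L, n)
  if (n == 0L) {
    variants$feature <- character(0); variants$genes <- character(0)
    variants$distance <- integer(0)
    return(variants)
  }
  known_chroms <- unique(index$tx$chrom)
  off <- !(variants$chrom %in% known_chroms)
  if (any(off))
    warning(sum(off), " variant(s) on chromosome(s) absent from the gene ",
            "model index; annotated as intergenic with no gene")
  feature[off] <- "intergenic"
  distance[off] <- NA_integer_

  pos <- GRanges(variants$chrom, IRanges(variants$pos, variants$pos))
  assign_cat <- function(gset, cat, current) {
    if (length(gset) == 0L) return(current)
    hit <- suppressWarnings(findOverlaps(pos, gset, ignore.strand = TRUE))
    qi <- queryHits(hit)
    use <- is.na(current)[qi]
    if (!any(use)) return(current)
    qi <- qi[use]; si <- subjectHits(hit)[use]
    gl <- split(gset$gene[si], qi)
    idx <- as.integer(names(gl))
    feature[idx] <<- cat
    genes[idx] <<- vapply(gl, .join_genes, character(1))
    current[idx] <- cat
    current
  }
  cur <- feature
  cur <- assign_cat(index$gr_exonic, "exonic", cur)
  # splice windows: first/last splice_window_bp of each intron
  w <- cfg$splice_window_bp
  if (w > 0L && length(index$gr_intron) > 0L) {
    gi <- index$gr_intron
    left <- GenomicRanges::resize(gi, width = pmin(w, width(gi)), fix = "start")
    right <- GenomicRanges::resize(gi, width = pmin(w, width(gi)), fix = "end")
    sp <- c(left, right)
    cur <- assign_cat(sp, "splicing", cur)
  }
  cur <- assign_cat(index$gr_utr5, "UTR5", cur)
  cur <- assign_cat(index$gr_utr3, "UTR3", cur)
  cur <- assign_cat(index$gr_tx, "intronic", cur)
  ud <- cfg$upstream_downstream_bp
  if (ud > 0L && length(index$gr_tx) > 0L) {
    gr_up <- flank(index$gr_tx, width = ud, start = TRUE)
    gr_dn <- flank(index$gr_tx, width = ud, start = FALSE)
    gr_up <- IRanges::restrict(gr_up, start = 1L)
    gr_dn <- IRanges::restrict(gr_dn, start = 1L)
    cur <- assign_cat(gr_up, "upstream", cur)
    cur <- assign_cat(gr_dn, "downstream", cur)
  }
  # remaining: intergenic; nearest flanking genes + distance
  left_ix <- which(is.na(cur))
  if (length(left_ix)) {
    feature[left_ix] <- "intergenic"
    gdf <- data.frame(chrom = as.character(seqnames(index$gr_gene)),
                      start = start(index$gr_gene),
                      end = end(index$gr_gene),
                      gene = index$gr_gene$gene, stringsAsFactors = FALSE)
    gsplit <- split(gdf, gdf$chrom)
    for (i in left_ix) {
      same <- gsplit[[variants$chrom[i]]]
      if (is.null(same) || nrow(same) == 0L) {
        genes[i] <- ""
        distance[i] <- NA_integer_
        next
      }
      pp <- variants$pos[i]
      dl <- ifelse(same$end < pp, pp - same$end,
                   ifelse(same$start > pp, same$start - pp, 0L))
      lft <- same$end < pp
      rgt <- same$start > pp
      fl <- character(0)
      if (any(lft)) fl <- c(fl, same$gene[lft][which.max(same$end[lft])])
      if (any(rgt)) fl <- c(fl, same$gene[rgt][which.min(same$start[rgt])])
      if (!length(fl)) fl <- same$gene[which.min(dl)]
      genes[i] <- .join_genes(fl)
      distance[i] <- as.integer(min(dl))
    }
  }
  # upstream/downstream distances: bp to the nearest transcript end that
  # produced the call
  for (cat in c("upstream", "downstream")) {
    ix <- which(feature == cat)
    if (!length(ix)) next
    d <- GenomicRanges::distanceToNearest(pos[ix], index$gr_tx,
                                          ignore.strand = TRUE)
    distance[ix[queryHits(d)]] <- as.integer(mcols(d)$distance) + 1L
  }
  variants$feature <- feature
  variants$genes <- genes
  variants$distance <- distance
  variants
}

#' Map Annovar-style INFO annotations onto feature calls
#'
#' For VCFs that already carry Annovar annotation keys (`Func.refGene`,
#' `Gene.refGene`), maps the Annovar category vocabulary onto this package's
#' eight feature categories instead of re-annotating. Mapping table:
#' `exonic`/`ncRNA_exonic` -> exonic; `splicing`/`ncRNA_splicing` ->
#' splicing; `UTR5` -> UTR5; `UTR3` -> UTR3; `intronic`/`ncRNA_intronic` ->
#' intronic; `upstream` -> upstream; `downstream` -> downstream;
#' `intergenic` -> intergenic. Compound calls (`upstream;downstream`) take
#' the first, highest-precedence term.
#'
#' @param variants Variant record `data.frame` or `variant_cohort` whose
#'   INFO strings carry `Func.refGene`/`Gene.refGene`.
#' @return Input with `feature`, `genes`, `distance` columns appended;
#'   records without the keys get `NA` feature.
#' @export
parse_annovar_annotation <- function(variants) {
  if (inherits(variants, "variant_cohort")) {
    variants$variants <- parse_annovar_annotation(variants$variants)
    return(variants)
  }
  map <- c(exonic = "exonic", ncRNA_exonic = "exonic",
           splicing = "splicing", ncRNA_splicing = "splicing",
           UTR5 = "UTR5", UTR3 = "UTR3",
           intronic = "intronic", ncRNA_intronic = "intronic",
           upstream = "upstream", downstream = "downstream",
           intergenic = "intergenic")
  func <- info_field(variants, "Func.refGene")
  first <- vapply(strsplit(func, "[;\\\\]"), function(x)
    if (length(x)) x[1] else NA_character_, character(1))
  variants$feature <- unname(map[first])
  g <- info_field(variants, "Gene.refGene")
  g <- gsub("\\\\x3b", ",", g)
  variants$genes <- ifelse(is.na(g), "", g)
  variants$distance <- ifelse(variants$feature %in%
                                c("upstream", "downstream", "intergenic"),
                              NA_integer_, 0L)
  variants
}

#' Flag variants present in a known-sites table
#'
#' Matches each variant against a table of known sites (dbSNP-style
#' membership). BED input (0-based half-open intervals) matches by position
#' overlap; TSV input (1-based) matches by position, and by alleles as well
#' when the table carries `ref`/`alt` columns.
#'
#' @param variants Variant record `data.frame` or `variant_cohort`.
#' @param path Path to a BED (`chrom start end [id]`) or TSV file
#'   (`chrom pos [ref alt] [id]`, header optional, 1-based).
#' @param format `"bed"`, `"tsv"`, or `NULL` to detect from the extension.
#' @return Input with logical `known_site` and character `site_id` columns.
#' @export
annotate_known_sites <- function(variants, path, format = NULL) {
  if (inherits(variants, "variant_cohort")) {
    variants$variants <- annotate_known_sites(variants$variants, path, format)
    return(variants)
  }
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "bed") "bed" else "tsv"
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  variants$known_site <- rep(FALSE, nrow(variants))
  variants$site_id <- rep(NA_character_, nrow(variants))
  if (length(lines) == 0L) return(variants)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "bed") {
    if (any(nf < 3L))
      stop("known-sites format error: BED line ", which(nf < 3L)[1],
           " has fewer than 3 columns")
    st <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    en <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    if (anyNA(st) || anyNA(en))
      stop("known-sites format error: non-numeric interval at line ",
           which(is.na(st) | is.na(en))[1])
    sites <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                        start1 = st + 1L, end1 = en,
                        id = ifelse(nf >= 4L,
                                    vapply(fields, function(x)
                                      if (length(x) >= 4) x[4] else NA_character_,
                                      character(1)), NA_character_),
                        stringsAsFactors = FALSE)
    gs <- GRanges(sites$chrom, IRanges(sites$start1, sites$end1))
    gv <- GRanges(variants$chrom, IRanges(variants$pos, variants$pos))
    hit <- findOverlaps(gv, gs)
    qi <- queryHits(hit); si <- subjectHits(hit)
    keep <- !duplicated(qi)
    variants$known_site[qi[keep]] <- TRUE
    variants$site_id[qi[keep]] <- sites$id[si[keep]]
  } else {
    # drop a header line if the position column is not numeric
    if (suppressWarnings(is.na(as.integer(fields[[1]][2]))) ) {
      fields <- fields[-1]; nf <- nf[-1]
      if (length(fields) == 0L) return(variants)
    }
    if (any(nf < 2L))
      stop("known-sites format error: TSV line ", which(nf < 2L)[1],
           " has fewer than 2 columns")
    pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    if (anyNA(pos))
      stop("known-sites format error: non-numeric position at line ",
           which(is.na(pos))[1])
    has_alleles <- all(nf >= 4L)
    sites <- data.frame(chrom = vapply(fields, `[`, "", 1L), pos = pos,
                        stringsAsFactors = FALSE)
    if (has_alleles) {
      sites$ref <- toupper(vapply(fields, `[`, "", 3L))
      sites$alt <- toupper(vapply(fields, `[`, "", 4L))
      sites$id <- if (all(nf >= 5L)) vapply(fields, `[`, "", 5L) else NA_character_
      skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
      vkey <- variant_key(variants)
    } else {
      sites$id <- if (all(nf >= 3L)) vapply(fields, `[`, "", 3L) else NA_character_
      skey <- paste(sites$chrom, sites$pos, sep = ":")
      vkey <- paste(variants$chrom, variants$pos, sep = ":")
    }
    m <- match(vkey, skey)
    variants$known_site <- !is.na(m)
    variants$site_id <- sites$id[m]
  }
  variants
}
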