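# Synthetic fixture generators: toy genome, gene models, driver list,
# signature catalog, and replicated VCF cohorts with planted,
# manifest-recorded truth. Planted count-level quantities (class mix,
# substitution spectrum, indel lengths, feature mix) are realized by exact
# largest-remainder allocation, so downstream count summaries can be tested
# at zero tolerance; only signature-mixture channel draws are sampled.

# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Largest-remainder integer allocation of n over fractions; deterministic
# tie-break by position.
alloc_counts <- function(n, fracs) {
  stopifnot(n >= 0, all(fracs >= 0), sum(fracs) > 0)
  raw <- fracs / sum(fracs) * n
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

#' Generate a toy reference genome
#'
#' Writes a reproducible uniform-random ACGT FASTA with its `.fai` index and
#' a `chrom.sizes` TSV.
#'
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Length of each chromosome (>= 10000).
#' @param dir Output directory.
#' @return List with `fasta`, `fai`, `chrom_sizes` (paths), `sizes` (named
#'   integer vector) and `seqs` (named character vector).
#' @export
make_genome <- function(seed, n_chroms = 2L, chrom_len = 150000L,
                        dir = tempfile("genome")) {
  stopifnot(chrom_len >= 10000L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- .with_seed(seed, {
    stats::setNames(vapply(seq_len(n_chroms), function(i)
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = ""), character(1)),
      paste0("chr", seq_len(n_chroms)))
  })
  fasta <- file.path(dir, "genome.fa")
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, fasta, width = 70L)
  Rsamtools::indexFa(fasta)
  sizes <- stats::setNames(rep(as.integer(chrom_len), n_chroms), names(seqs))
  cs <- file.path(dir, "chrom.sizes")
  write_tsv_atomic(data.frame(chrom = names(sizes), length = sizes,
                              stringsAsFactors = FALSE), cs)
  list(fasta = fasta, fai = paste0(fasta, ".fai"), chrom_sizes = cs,
       sizes = sizes, seqs = seqs)
}

#' Generate toy gene models
#'
#' Lays out non-overlapping genes (1-3 transcripts each, 2-6 exons per
#' transcript, CDS flanked by UTRs) across the toy genome, with >= 3 kb gaps
#' between neighbouring genes so that upstream, downstream and intergenic
#' space all exist. The same models are written both as Ensembl-dialect GTF
#' and as GFF3.
#'
#' @param genome Result of [make_genome()].
#' @param seed Integer seed.
#' @param n_genes Number of genes (0 allowed: empty but valid model files).
#' @param dir Output directory.
#' @return List with `gtf`, `gff3` (paths), `model` (feature `data.frame`:
#'   `type`, `gene`, `tx_id`, `chrom`, `start`, `end`, `strand`) and `genes`
#'   (character vector of gene names).
#' @export
make_gene_models <- function(genome, seed, n_genes = 30L,
                             dir = tempfile("models")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- .with_seed(seed, {
    rows <- list()
    chroms <- names(genome$sizes)
    per_chrom <- alloc_counts(n_genes, stats::setNames(
      rep(1, length(chroms)), chroms))
    gi <- 0L
    for (ch in chroms) {
      cursor <- 2500L
      L <- genome$sizes[[ch]]
      for (g in seq_len(per_chrom[[ch]])) {
        gi <- gi + 1L
        gene <- sprintf("GENE%02d", gi)
        strand <- sample(c("+", "-"), 1)
        n_tx <- sample(1:3, 1)
        tx_rows <- list()
        gene_start <- cursor
        gene_end <- gene_start
        for (t in seq_len(n_tx)) {
          n_ex <- sample(2:6, 1)
          ex_len <- sample(100:300, n_ex, replace = TRUE)
          in_len <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE)
                    else integer(0)
          starts <- gene_start + c(0L, cumsum(ex_len[-n_ex] + in_len))
          ends <- starts + ex_len - 1L
          tx_id <- sprintf("%s.t%d", gene, t)
          # CDS: inside first..last exon with UTR margins on both sides
          utr_l <- min(sample(30:80, 1), ex_len[1] - 20L)
          utr_r <- min(sample(30:80, 1), ex_len[n_ex] - 20L)
          cds_s <- starts[1] + utr_l
          cds_e <- ends[n_ex] - utr_r
          tx_rows[[t]] <- rbind(
            data.frame(type = "transcript", gene = gene, tx_id = tx_id,
                       chrom = ch, start = starts[1], end = ends[n_ex],
                       strand = strand, stringsAsFactors = FALSE),
            data.frame(type = "exon", gene = gene, tx_id = tx_id, chrom = ch,
                       start = starts, end = ends, strand = strand,
                       stringsAsFactors = FALSE),
            {
              cs <- pmax(starts, cds_s); ce <- pmin(ends, cds_e)
              keep <- cs <= ce
              data.frame(type = "CDS", gene = gene, tx_id = tx_id,
                         chrom = ch, start = cs[keep], end = ce[keep],
                         strand = strand, stringsAsFactors = FALSE)
            })
          gene_end <- max(gene_end, ends[n_ex])
        }
        if (gene_end > L - 2500L) break
        rows[[gene]] <- rbind(
          data.frame(type = "gene", gene = gene, tx_id = NA_character_,
                     chrom = ch, start = gene_start, end = gene_end,
                     strand = strand, stringsAsFactors = FALSE),
          do.call(rbind, tx_rows))
        cursor <- gene_end + sample(3000:4500, 1)
        if (cursor > L - 4000L) break
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(type = character(), gene = character(), tx_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
  })
  rownames(model) <- NULL
  gtf <- file.path(dir, "models.gtf")
  gff3 <- file.path(dir, "models.gff3")
  .write_gtf(model, gtf)
  .write_gff3(model, gff3)
  list(gtf = gtf, gff3 = gff3, model = model,
       genes = unique(model$gene[model$type == "gene"]))
}

.write_gtf <- function(model, path) {
  lines <- character(nrow(model))
  for (i in seq_len(nrow(model))) {
    r <- model[i, ]
    attrs <- if (r$type == "gene")
      sprintf('gene_id "%s";', r$gene)
    else
      sprintf('gene_id "%s"; transcript_id "%s";', r$gene, r$tx_id)
    lines[i] <- paste(r$chrom, "synthetic", r$type, r$start, r$end, ".",
                      r$strand, ".", attrs, sep = "\t")
  }
  writeLines(c("##gff-version 2", lines), path)
}

.write_gff3 <- function(model, path) {
  lines <- character(nrow(model))
  cds_n <- 0L
  for (i in seq_len(nrow(model))) {
    r <- model[i, ]
    attrs <- switch(r$type,
      gene = sprintf("ID=%s;Name=%s", r$gene, r$gene),
      transcript = sprintf("ID=%s;Parent=%s", r$tx_id, r$gene),
      exon = sprintf("Parent=%s", r$tx_id),
      CDS = { cds_n <- cds_n + 1L
              sprintf("ID=cds%d;Parent=%s", cds_n, r$tx_id) })
    typ <- if (r$type == "transcript") "mRNA" else r$type
    lines[i] <- paste(r$chrom, "synthetic", typ, r$start, r$end, ".",
                      r$strand, ".", attrs, sep = "\t")
  }
  writeLines(c("##gff-version 3", lines), path)
}

#' Write a driver-gene list fixture
#'
#' @param models Result of [make_gene_models()].
#' @param seed Integer seed.
#' @param n Number of genes to draw.
#' @param path Output TSV path.
#' @return Character vector of the chosen gene names.
#' @export
make_driver_list <- function(models, seed, n = 8L,
                             path = tempfile("drivers", fileext = ".tsv")) {
  genes <- .with_seed(seed, sort(sample(models$genes, min(n, length(models$genes)))))
  writeLines(c("gene", genes), path)
  genes
}

#' Generate a synthetic signature set / catalog
#'
#' Builds `k` well-separated column-stochastic SBS96 signatures: each
#' signature concentrates its mass on its own block of a random channel
#' partition (plus a tiny uniform floor), giving pairwise cosines well
#' below 0.3.
#'
#' @param seed Integer seed.
#' @param k Number of signatures.
#' @param path Optional TSV path to write a COSMIC-style catalog.
#' @return 96 x k signature matrix (channels in [sbs96_channels()] order).
#' @export
make_signature_set <- function(seed, k = 4L, path = NULL) {
  chans <- sbs96_channels()
  S <- .with_seed(seed, {
    blocks <- split(sample(96L), rep(seq_len(k), length.out = 96L))
    m <- matrix(1e-4, 96L, k, dimnames = list(chans, paste0("SigSynth", seq_len(k))))
    for (j in seq_len(k)) {
      w <- stats::rgamma(length(blocks[[j]]), shape = 1.2)
      m[blocks[[j]], j] <- m[blocks[[j]], j] + w
    }
    sweep(m, 2, colSums(m), "/")
  })
  if (!is.null(path)) write_sbs96_tsv(S, path)
  S
}

#' Simulate an SBS96 count matrix from signatures and exposures
#'
#' Draws each sample's channel counts from the mixture distribution
#' `signatures %*% exposure_fractions`, either multinomially with the
#' sample's exact total, or as independent Poisson counts with that mean.
#'
#' @param signatures 96 x k column-stochastic matrix.
#' @param exposures k x n matrix of per-sample attributed mutation counts.
#' @param seed Integer seed.
#' @param model `"multinomial"` or `"poisson"`.
#' @return 96 x n integer count matrix.
#' @export
simulate_sbs96 <- function(signatures, exposures, seed,
                           model = c("multinomial", "poisson")) {
  model <- match.arg(model)
  stopifnot(ncol(signatures) == nrow(exposures))
  mu <- signatures %*% exposures
  .with_seed(seed, {
    counts <- matrix(0L, nrow(mu), ncol(mu),
                     dimnames = list(rownames(signatures), colnames(exposures)))
    for (j in seq_len(ncol(mu))) {
      counts[, j] <- if (model == "poisson")
        stats::rpois(nrow(mu), mu[, j])
      else
        as.integer(stats::rmultinom(1, round(sum(exposures[, j])),
                                    mu[, j] / sum(mu[, j])))
    }
    counts
  })
}

# Per-position feature category and owning gene, painted in increasing
# precedence so that later (higher-precedence) categories overwrite earlier
# ones: intergenic < downstream < upstream < intronic < UTR3 < UTR5 <
# splicing < exonic. This mirrors the annotation precedence by an
# independent whole-genome construction.
.paint_genome <- function(model, sizes, cfg = annotation_config()) {
  out <- list()
  for (ch in names(sizes)) {
    L <- sizes[[ch]]
    cat <- rep.int("intergenic", L)
    gene <- rep.int(".", L)
    paint <- function(s, e, category, g) {
      s <- max(1L, as.integer(s)); e <- min(L, as.integer(e))
      if (s > e) return(invisible())
      cat[s:e] <<- category
      gene[s:e] <<- g
    }
    txs <- model[model$type == "transcript" & model$chrom == ch, , drop = FALSE]
    ud <- cfg$upstream_downstream_bp
    # downstream, then upstream (upstream wins where flanks of two genes meet)
    for (i in seq_len(nrow(txs))) {
      r <- txs[i, ]
      if (r$strand == "+") paint(r$end + 1L, r$end + ud, "downstream", r$gene)
      else paint(r$start - ud, r$start - 1L, "downstream", r$gene)
    }
    for (i in seq_len(nrow(txs))) {
      r <- txs[i, ]
      if (r$strand == "+") paint(r$start - ud, r$start - 1L, "upstream", r$gene)
      else paint(r$end + 1L, r$end + ud, "upstream", r$gene)
    }
    for (i in seq_len(nrow(txs))) paint(txs$start[i], txs$end[i], "intronic",
                                        txs$gene[i])
    # per-transcript exon partition
    w <- cfg$splice_window_bp
    utr_paint <- list(UTR3 = list(), UTR5 = list(), splicing = list(),
                      exonic = list())
    for (i in seq_len(nrow(txs))) {
      tx_id <- txs$tx_id[i]; g <- txs$gene[i]
      ex <- model[model$type == "exon" & model$tx_id == tx_id, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cd <- model[model$type == "CDS" & model$tx_id == tx_id, , drop = FALSE]
      add <- function(slot, s, e) {
        if (length(s) && any(s <= e))
          utr_paint[[slot]][[length(utr_paint[[slot]]) + 1L]] <<-
            data.frame(s = s[s <= e], e = e[s <= e], g = g)
      }
      if (nrow(cd)) {
        cs <- min(cd$start); ce <- max(cd$end)
        add("exonic", pmax(ex$start, cs), pmin(ex$end, ce))
        ls <- ex$start; le <- pmin(ex$end, cs - 1L)
        rs <- pmax(ex$start, ce + 1L); re <- ex$end
        if (txs$strand[i] == "+") {
          add("UTR5", ls, le); add("UTR3", rs, re)
        } else {
          add("UTR3", ls, le); add("UTR5", rs, re)
        }
      } else {
        add("exonic", ex$start, ex$end)
      }
      if (nrow(ex) > 1L && w > 0L) {
        is_ <- utils::head(ex$end, -1) + 1L
        ie <- utils::tail(ex$start, -1) - 1L
        add("splicing", is_, pmin(ie, is_ + w - 1L))
        add("splicing", pmax(is_, ie - w + 1L), ie)
      }
    }
    for (slot in c("UTR3", "UTR5", "splicing", "exonic")) {
      for (d in utr_paint[[slot]]) {
        for (r in seq_len(nrow(d))) paint(d$s[r], d$e[r], slot, d$g[r])
      }
    }
    out[[ch]] <- list(category = cat, gene = gene)
  }
  out
}

#' Declare a synthetic cohort's planted structure
#'
#' Defines the study conditions the cohort generator realizes: the
#' group/replicate layout, the shared-core / private split that fixes the
#' replicate overlap, and the planted class mix, substitution spectrum,
#' indel length distribution and feature-category mix (each realized by
#' exact allocation). Supplying `signature_mix` switches SNV planting from
#' the 6-class spectrum to SBS96 channels drawn from the given signature
#' mixture (feature mix is then not planted).
#'
#' @param groups Named list: group label -> number of replicate samples.
#' @param n_core Variants shared by all replicates of a group.
#' @param n_private Variants private to each replicate.
#' @param class_mix Named fractions over SNV/INSERTION/DELETION/MNV.
#' @param spectrum Named fractions over the six pyrimidine-reference
#'   substitution classes.
#' @param indel_lens Named fractions over indel lengths (names = lengths).
#' @param feature_mix Named fractions over feature categories, or `NULL`
#'   to place variants without feature constraints.
#' @param signature_mix Optional list with `signatures` (96 x k matrix) and
#'   `mix` (named list: group -> length-k exposure fractions).
#' @param window_bp Window size recorded for per-window truth.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = list(tumor = 3L, normal = 3L),
                        n_core = 1400L, n_private = 600L,
                        class_mix = c(SNV = 0.84, INSERTION = 0.07,
                                      DELETION = 0.07, MNV = 0.02),
                        spectrum = c("C>A" = 0.08, "C>G" = 0.06,
                                     "C>T" = 0.45, "T>A" = 0.07,
                                     "T>C" = 0.28, "T>G" = 0.06),
                        indel_lens = c("1" = 0.45, "2" = 0.20, "3" = 0.12,
                                       "4" = 0.08, "5" = 0.05, "7" = 0.04,
                                       "9" = 0.03, "12" = 0.03),
                        feature_mix = c(exonic = 0.20, splicing = 0.01,
                                        UTR5 = 0.04, UTR3 = 0.05,
                                        intronic = 0.28, upstream = 0.06,
                                        downstream = 0.06,
                                        intergenic = 0.30),
                        signature_mix = NULL,
                        window_bp = 25000L) {
  stopifnot(length(groups) >= 1L, all(unlist(groups) >= 1L))
  stopifnot(setequal(names(class_mix), VARIANT_CLASSES) ||
              setequal(names(class_mix), c("SNV", "INSERTION", "DELETION")))
  stopifnot(setequal(names(spectrum), SUB6))
  if (!is.null(feature_mix))
    stopifnot(all(names(feature_mix) %in% FEATURE_CATEGORIES))
  structure(list(groups = groups, n_core = as.integer(n_core),
                 n_private = as.integer(n_private), class_mix = class_mix,
                 spectrum = spectrum, indel_lens = indel_lens,
                 feature_mix = feature_mix, signature_mix = signature_mix,
                 window_bp = as.integer(window_bp)),
            class = "cohort_spec")
}

#' Generate a replicated VCF cohort with planted, manifest-recorded truth
#'
#' Realizes a [cohort_spec()] on a toy genome: each group gets a shared core
#' variant set plus one private set per replicate (so the replicate-overlap
#' regions are exactly core / private), with SNV classes, indel lengths and
#' feature categories placed by exact allocation at positions drawn from
#' precomputed per-category pools. All positions are unique across the
#' cohort. Reference alleles are taken from the genome sequence. One VCF
#' per sample is written, plus an `annotated/` copy carrying Annovar-style
#' `Func.refGene`/`Gene.refGene` INFO keys.
#'
#' The returned manifest records, per sample, the realized class counts,
#' 6-class spectrum counts, insertion/deletion length counts, feature
#' category counts, per-gene counts (gene-body categories), SBS96 channel
#' counts, and per-window SNV/indel counts — sufficient to predict every
#' count-level summary exactly.
#'
#' @param genome Result of [make_genome()].
#' @param models Result of [make_gene_models()].
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; byte-reproducible output.
#' @param dir Output directory.
#' @return List with `manifest` (list; also written as `manifest.yaml`),
#'   `file_manifest` (`data.frame` `path`/`group`/`sample` for
#'   [assemble_cohort()]), `annotated_manifest` (same for the annotated
#'   copies) and `dir`.
#' @export
make_cohort <- function(genome, models, spec = cohort_spec(), seed = 1L,
                        dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "annotated"), showWarnings = FALSE)
  paintcfg <- annotation_config()
  paintmap <- .paint_genome(models$model, genome$sizes, paintcfg)
  seqs <- genome$seqs
  sizes <- genome$sizes
  base_at <- function(ch, p) substr(seqs[[ch]], p, p)

  # position pools: per chromosome, eligible positions (margin from both
  # ends so deletions/contexts never run off), minus already-used positions
  margin <- 25L
  used <- lapply(sizes, function(L) rep(FALSE, L))
  chrom_base <- lapply(names(sizes), function(ch)
    strsplit(seqs[[ch]], "", fixed = TRUE)[[1]])
  names(chrom_base) <- names(sizes)

  # pyrimidine-oriented trinucleotide context per position (for channel
  # planting); NA at chromosome edges
  ctx_of <- NULL
  if (!is.null(spec$signature_mix)) {
    ctx_of <- lapply(names(sizes), function(ch) {
      b <- chrom_base[[ch]]
      L <- length(b)
      tri <- paste0(b[seq_len(L - 2L)], b[2:(L - 1L)], b[3:L])
      tri <- c(NA, tri, NA)
      pur <- b %in% c("A", "G")
      tri[pur] <- .revcomp(tri[pur])
      tri
    })
    names(ctx_of) <- names(sizes)
  }

  draw_positions <- function(want, n) {
    # want(ch) -> logical vector of eligible positions on chromosome ch
    cand <- do.call(rbind, lapply(names(sizes), function(ch) {
      ok <- want(ch)
      ok[seq_len(margin)] <- FALSE
      L <- sizes[[ch]]
      ok[(L - margin):L] <- FALSE
      ok[used[[ch]]] <- FALSE
      p <- which(ok)
      if (length(p)) data.frame(chrom = ch, pos = p, stringsAsFactors = FALSE)
    }))
    if (is.null(cand) || nrow(cand) < n)
      stop("fixture generation error: requested ", n,
           " placements but only ", if (is.null(cand)) 0L else nrow(cand),
           " eligible positions remain")
    pick <- cand[sample.int(nrow(cand), n), , drop = FALSE]
    for (ch in unique(pick$chrom))
      used[[ch]][pick$pos[pick$chrom == ch]] <<- TRUE
    pick
  }

  cat_ok <- function(ch, categories) {
    if (is.null(categories)) rep(TRUE, sizes[[ch]])
    else paintmap[[ch]]$category %in% categories
  }

  gen_set <- function(n, group) {
    cm <- spec$class_mix
    if (!"MNV" %in% names(cm)) cm <- c(cm, MNV = 0)
    ncl <- alloc_counts(n, cm[VARIANT_CLASSES])
    rows <- list()
    fmix <- spec$feature_mix
    place_class <- function(count, eligible_bases, cat) {
      want <- function(ch) {
        ok <- cat_ok(ch, cat)
        if (!is.null(eligible_bases))
          ok <- ok & chrom_base[[ch]] %in% eligible_bases
        ok
      }
      draw_positions(want, count)
    }
    # --- SNVs ---
    if (!is.null(spec$signature_mix)) {
      S <- spec$signature_mix$signatures
      mix <- spec$signature_mix$mix[[group]]
      p <- as.vector(S %*% (mix / sum(mix)))
      chan_counts <- as.integer(stats::rmultinom(1, ncl[["SNV"]], p))
      names(chan_counts) <- sbs96_channels()
      for (chan in names(chan_counts)[chan_counts > 0]) {
        cc <- chan_counts[[chan]]
        ctx <- paste0(substr(chan, 1, 1), substr(chan, 3, 3), substr(chan, 7, 7))
        alt_p <- substr(chan, 5, 5)
        want <- function(ch) !is.na(ctx_of[[ch]]) & ctx_of[[ch]] == ctx
        pick <- draw_positions(want, cc)
        ref <- mapply(base_at, pick$chrom, pick$pos)
        alt <- ifelse(ref %in% c("C", "T"), alt_p,
                      unname(.COMPLEMENT[alt_p]))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = pick$chrom, pos = pick$pos, ref = unname(ref),
          alt = unname(alt), vclass = "SNV",
          indel_len = 0L, category = NA_character_, gene = NA_character_,
          channel = chan, stringsAsFactors = FALSE)
      }
    } else {
      spec_counts <- alloc_counts(ncl[["SNV"]], spec$spectrum)
      for (cls in names(spec_counts)[spec_counts > 0]) {
        pyr <- substr(cls, 1, 1); altb <- substr(cls, 3, 3)
        bases <- c(pyr, unname(.COMPLEMENT[pyr]))
        cat_counts <- if (is.null(fmix)) stats::setNames(spec_counts[[cls]], NA)
          else alloc_counts(spec_counts[[cls]], fmix)
        for (ci in seq_along(cat_counts)) {
          cc <- cat_counts[[ci]]
          if (cc == 0L) next
          cat <- if (is.null(fmix)) NULL else names(cat_counts)[ci]
          pick <- place_class(cc, bases, cat)
          ref <- mapply(base_at, pick$chrom, pick$pos)
          alt <- ifelse(ref == pyr, altb, unname(.COMPLEMENT[altb]))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = pick$chrom, pos = pick$pos, ref = unname(ref),
            alt = unname(alt), vclass = "SNV", indel_len = 0L,
            category = if (is.null(cat)) NA_character_ else cat,
            gene = if (is.null(cat)) NA_character_ else
              mapply(function(ch, p) paintmap[[ch]]$gene[p], pick$chrom,
                     pick$pos),
            channel = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    # --- indels & MNVs ---
    for (ty in c("INSERTION", "DELETION", "MNV")) {
      nt <- ncl[[ty]]
      if (nt == 0L) next
      lens <- if (ty == "MNV") stats::setNames(nt, "2") else {
        lc <- alloc_counts(nt, spec$indel_lens)
        lc[lc > 0]
      }
      for (ln in names(lens)) {
        lv <- as.integer(ln)
        cat_counts <- if (is.null(fmix)) stats::setNames(lens[[ln]], NA)
          else alloc_counts(lens[[ln]], fmix)
        for (ci in seq_along(cat_counts)) {
          cc <- cat_counts[[ci]]
          if (cc == 0L) next
          cat <- if (is.null(fmix)) NULL else names(cat_counts)[ci]
          pick <- place_class(cc, NULL, cat)
          ref <- alt <- character(nrow(pick))
          for (r in seq_len(nrow(pick))) {
            ch <- pick$chrom[r]; p <- pick$pos[r]
            anchor <- base_at(ch, p)
            if (ty == "INSERTION") {
              ins <- paste(sample(c("A", "C", "G", "T"), lv, replace = TRUE),
                           collapse = "")
              ref[r] <- anchor; alt[r] <- paste0(anchor, ins)
            } else if (ty == "DELETION") {
              ref[r] <- substr(seqs[[ch]], p, p + lv)
              alt[r] <- anchor
            } else {
              rr <- substr(seqs[[ch]], p, p + 1L)
              a1 <- sample(base::setdiff(c("A", "C", "G", "T"),
                                         substr(rr, 1, 1)), 1)
              a2 <- sample(base::setdiff(c("A", "C", "G", "T"),
                                         substr(rr, 2, 2)), 1)
              ref[r] <- rr; alt[r] <- paste0(a1, a2)
            }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = pick$chrom, pos = pick$pos, ref = ref, alt = alt,
            vclass = ty, indel_len = if (ty == "MNV") 0L else lv,
            category = if (is.null(cat)) NA_character_ else cat,
            gene = if (is.null(cat)) NA_character_ else
              mapply(function(ch, p) paintmap[[ch]]$gene[p], pick$chrom,
                     pick$pos),
            channel = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  }

  result <- .with_seed(seed, {
    samples <- do.call(rbind, lapply(names(spec$groups), function(g)
      data.frame(sample = sprintf("%s_rep%d", g, seq_len(spec$groups[[g]])),
                 group = g, stringsAsFactors = FALSE)))
    sets <- list()
    per_sample <- list()
    for (g in names(spec$groups)) {
      core <- gen_set(spec$n_core, g)
      reps <- samples$sample[samples$group == g]
      for (s in reps) {
        priv <- gen_set(spec$n_private, g)
        per_sample[[s]] <- rbind(core, priv)
      }
    }
    list(samples = samples, per_sample = per_sample)
  })
  samples <- result$samples
  per_sample <- result$per_sample

  # realized truth per sample
  window_key <- function(df) {
    paste(df$chrom, (df$pos - 1L) %/% spec$window_bp)
  }
  truth <- list()
  for (s in samples$sample) {
    df <- per_sample[[s]]
    snv <- df[df$vclass == "SNV", , drop = FALSE]
    t6 <- table(factor(collapse_substitution(paste0(snv$ref, ">", snv$alt)),
                       levels = SUB6))
    ins <- df[df$vclass == "INSERTION", , drop = FALSE]
    del <- df[df$vclass == "DELETION", , drop = FALSE]
    feat <- if (!is.null(spec$feature_mix))
      as.list(table(factor(df$category, levels = FEATURE_CATEGORIES)))
    else NULL
    body_cat <- c("exonic", "splicing", "UTR5", "UTR3", "intronic")
    gtab <- if (!is.null(spec$feature_mix)) {
      gg <- df$gene[df$category %in% body_cat & df$gene != "."]
      as.list(table(gg))
    } else NULL
    chan <- if (!is.null(spec$signature_mix))
      as.list(table(factor(snv$channel, levels = sbs96_channels())))
    else NULL
    wins <- split(df, window_key(df))
    win_counts <- lapply(wins, function(d)
      list(chrom = d$chrom[1],
           window_start = ((d$pos[1] - 1L) %/% spec$window_bp) *
             spec$window_bp + 1L,
           snv = sum(d$vclass == "SNV"),
           indel = sum(d$vclass %in% c("INSERTION", "DELETION"))))
    truth[[s]] <- list(
      class_counts = as.list(table(factor(df$vclass,
                                          levels = VARIANT_CLASSES))),
      spectrum6 = as.list(t6),
      ins_lengths = as.list(table(ins$indel_len)),
      del_lengths = as.list(table(del$indel_len)),
      feature_counts = feat,
      gene_counts = gtab,
      channel_counts = chan,
      window_counts = win_counts)
  }

  # write VCFs (plain + annotated copies with Annovar-style INFO keys)
  file_manifest <- samples
  file_manifest$path <- NA_character_
  ann_manifest <- samples
  ann_manifest$path <- NA_character_
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]
    df <- per_sample[[s]]
    v <- df
    v$filter_pass <- TRUE
    v$info <- "."
    p <- file.path(dir, paste0(s, ".vcf"))
    write_vcf(v, p, sizes)
    file_manifest$path[i] <- p
    if (!is.null(spec$feature_mix)) {
      v$info <- sprintf("Func.refGene=%s;Gene.refGene=%s", df$category,
                        ifelse(df$gene == ".", "NONE", df$gene))
      pa <- file.path(dir, "annotated", paste0(s, ".annot.vcf"))
      write_vcf(v, pa, sizes)
      ann_manifest$path[i] <- pa
    }
  }
  manifest <- list(
    seed = as.integer(seed),
    window_bp = spec$window_bp,
    chromosomes = as.list(sizes),
    groups = lapply(names(spec$groups), function(g)
      list(group = g, samples = samples$sample[samples$group == g],
           n_core = spec$n_core, n_private = spec$n_private)),
    samples = truth)
  names(manifest$groups) <- names(spec$groups)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  write_tsv_atomic(file_manifest[, c("path", "group", "sample")],
                   file.path(dir, "file_manifest.tsv"))
  list(manifest = manifest, file_manifest = file_manifest[, c("path", "group",
                                                              "sample")],
       annotated_manifest = if (!is.null(spec$feature_mix))
         ann_manifest[, c("path", "group", "sample")] else NULL,
       dir = dir, spec = spec)
}
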