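#' SBS96 channel labels in canonical order
#'
#' Substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3'
#' flank, each A < C < G < T: `A[C>A]A`, `A[C>A]C`, ..., `T[T>G]T`. All
#' matrices and catalog files in this package use this row order.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  ctx <- c("A", "C", "G", "T")
  unlist(lapply(SUB6, function(s)
    unlist(lapply(ctx, function(x) paste0(x, "[", s, "]", ctx)))),
    use.names = FALSE)
}

.revcomp <- function(s) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Trinucleotide SBS96 channel of SNVs
#'
#' Looks up the reference base immediately 5' and 3' of each SNV and builds
#' the `X[R>A]Y` channel label. When the reference base is a purine, both
#' alleles and flanks are reverse-complemented so that the reported
#' reference is a pyrimidine (C or T). SNVs whose context runs off the
#' chromosome or contains N, or whose reference allele disagrees with the
#' genome, get `NA` (they are counted as dropped by [build_sbs96()]).
#'
#' @param variants Variant record `data.frame` (SNV rows are used; others
#'   get `NA`).
#' @param genome Path to an indexed FASTA, an open [Rsamtools::FaFile], or a
#'   named [Biostrings::DNAStringSet].
#' @return Character vector of channel labels (with `NA` for dropped SNVs),
#'   one per input row.
#' @export
trinucleotide_context <- function(variants, genome) {
  seqs <- .genome_seqs(genome)
  out <- rep(NA_character_, nrow(variants))
  is_snv <- variants$vclass == "SNV"
  for (i in which(is_snv)) {
    ch <- variants$chrom[i]
    if (!ch %in% names(seqs))
      stop("chromosome '", ch, "' missing from the reference FASTA")
    len <- nchar(seqs[[ch]])
    p <- variants$pos[i]
    if (p - 1L < 1L || p + 1L > len) next
    tri <- toupper(substr(seqs[[ch]], p - 1L, p + 1L))
    if (grepl("N", tri)) next
    if (substr(tri, 2, 2) != variants$ref[i]) next
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (ref %in% c("A", "G")) {
      tri <- .revcomp(tri)
      ref <- unname(.COMPLEMENT[ref]); alt <- unname(.COMPLEMENT[alt])
    }
    out[i] <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                     substr(tri, 3, 3))
  }
  out
}

# Accept a FASTA path, FaFile, or DNAStringSet; return named character
# vector of chromosome sequences.
.genome_seqs <- function(genome) {
  if (is.character(genome) && !is.null(names(genome)) && length(genome) >= 1L &&
      !any(file.exists(genome)))
    return(genome)
  if (is.character(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(stats::setNames(as.character(seqs), names(seqs)))
  }
  if (methods::is(genome, "FaFile")) {
    seqs <- Rsamtools::scanFa(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(stats::setNames(as.character(seqs), names(seqs)))
  }
  if (methods::is(genome, "DNAStringSet"))
    return(stats::setNames(as.character(genome), names(genome)))
  stop("unsupported genome input")
}

#' Build the SBS96 count matrix of a cohort
#'
#' Counts each sample's SNVs into the 96 trinucleotide substitution
#' channels. SNVs with unusable context (chromosome edge, N in context,
#' reference mismatch) are excluded and tallied per sample in `dropped`,
#' so that `colSums(counts) + dropped` equals each sample's SNV total.
#'
#' @param cohort A `variant_cohort`.
#' @param genome Reference genome (see [trinucleotide_context()]).
#' @return An `sbs96_matrix`: list with `counts` (96 x n_samples integer
#'   matrix, rows in [sbs96_channels()] order) and `dropped` (named integer
#'   vector).
#' @export
build_sbs96 <- function(cohort, genome) {
  chans <- sbs96_channels()
  v <- cohort$variants
  labs <- trinucleotide_context(v, genome)
  samples <- cohort$samples$sample
  counts <- matrix(0L, nrow = 96L, ncol = length(samples),
                   dimnames = list(chans, samples))
  dropped <- stats::setNames(integer(length(samples)), samples)
  for (s in samples) {
    snv <- v$vclass == "SNV" & v$sample == s
    ls <- labs[snv]
    dropped[s] <- sum(is.na(ls))
    counts[, s] <- as.integer(table(factor(ls[!is.na(ls)], levels = chans)))
  }
  structure(list(counts = counts, dropped = dropped), class = "sbs96_matrix")
}

#' @export
print.sbs96_matrix <- function(x, ...) {
  cat("sbs96_matrix: 96 channels x", ncol(x$counts), "samples;",
      sum(x$counts), "mutations counted,", sum(x$dropped), "dropped\n")
  invisible(x)
}

#' Write / read an SBS96 matrix or signature catalog TSV
#'
#' COSMIC-style layout: a `Type` column with channel labels plus one column
#' per sample or signature. On read, rows are reordered to the canonical
#' [sbs96_channels()] order; a file whose channel set differs is rejected.
#'
#' @param m Numeric 96-row matrix with channel rownames (counts or
#'   signatures).
#' @param path File path.
#' @return `write_sbs96_tsv`: invisibly, the path. `read_sbs96_tsv`: the
#'   matrix, rows in canonical order.
#' @export
write_sbs96_tsv <- function(m, path) {
  if (methods::is(m, "sbs96_matrix")) m <- m$counts
  df <- data.frame(Type = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

#' @rdname write_sbs96_tsv
#' @export
read_sbs96_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  chans <- sbs96_channels()
  if (!"Type" %in% names(df) || !setequal(df$Type, chans))
    stop("catalog format error: '", path,
         "' does not carry the 96 SBS channel labels in a Type column")
  m <- as.matrix(df[match(chans, df$Type), setdiff(names(df), "Type"),
                    drop = FALSE])
  rownames(m) <- chans
  m
}

.kl_div <- function(V, WH) {
  eps <- .Machine$double.eps
  sum(ifelse(V > 0, V * log(V / pmax(WH, eps)), 0) - V + WH)
}

# One KL-NMF run with multiplicative updates from a given initialization.
.nmf_kl_run <- function(V, W, H, max_iter, tol) {
  eps <- .Machine$double.eps
  obj <- .kl_div(V, W %*% H)
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), eps)
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) / pmax(rep(1, nrow(V)) %o% rowSums(H), eps)
    if (it %% 10L == 0L) {
      new_obj <- .kl_div(V, W %*% H)
      if (is.finite(obj) && abs(obj - new_obj) <= tol * max(abs(obj), eps)) {
        obj <- new_obj
        break
      }
      obj <- new_obj
    }
  }
  list(W = W, H = H, objective = .kl_div(V, W %*% H))
}

#' De novo mutational signature extraction by KL-NMF
#'
#' Factorizes an SBS96 count matrix `V` (96 x n) into non-negative
#' signatures `W` (96 x k) and exposures `H` (k x n), minimizing the
#' generalized Kullback-Leibler divergence `D(V || WH)` with multiplicative
#' updates. The best of `n_restarts` random initializations (by final
#' objective) is kept; signatures are rescaled to column sums of 1 with the
#' scale absorbed into the exposures, and ordered by decreasing total
#' exposure. Deterministic given `seed` and `n_restarts`.
#'
#' @param m An `sbs96_matrix` or a 96 x n count matrix.
#' @param k Number of signatures (1 <= k <= min(96, n_samples)).
#' @param n_restarts Random restarts (default 10).
#' @param seed Integer seed.
#' @param max_iter Maximum multiplicative updates per restart (default 2000).
#' @param tol Relative objective tolerance for early stopping (default 1e-8).
#' @return List with `signatures` (96 x k, column-stochastic), `exposures`
#'   (k x n, attributed mutation counts), `reconstruction_error` (final KL
#'   objective) and `restart_objectives`.
#' @export
extract_signatures <- function(m, k, n_restarts = 10L, seed = 1L,
                               max_iter = 2000L, tol = 1e-8) {
  V <- if (methods::is(m, "sbs96_matrix")) m$counts else m
  V <- as.matrix(V)
  storage.mode(V) <- "double"
  if (k < 1L || k > min(nrow(V), ncol(V)))
    stop("configuration error: k must be in [1, min(96, n_samples)]")
  if (n_restarts < 1L) stop("configuration error: n_restarts must be >= 1")
  if (all(V == 0)) stop("degenerate input: all-zero count matrix")
  best <- NULL
  objs <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    W0 <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H0 <- matrix(stats::runif(k * ncol(V), 0.1, 1) * mean(V) , k, ncol(V))
    fit <- .nmf_kl_run(V, W0, H0, max_iter, tol)
    objs[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  ord <- order(-rowSums(H))
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  rownames(W) <- rownames(V)
  colnames(W) <- rownames(H) <- paste0("SigDeNovo", seq_len(k))
  colnames(H) <- colnames(V)
  list(signatures = W, exposures = H,
       reconstruction_error = best$objective, restart_objectives = objs)
}

#' Rank-scan diagnostics for signature extraction
#'
#' Runs [extract_signatures()] for each candidate rank and reports the
#' reconstruction error and restart stability (mean pairwise cosine of
#' best-matched signatures across restarts). No rank is auto-selected.
#'
#' @param m An `sbs96_matrix` or 96 x n count matrix.
#' @param ks Integer vector of candidate ranks.
#' @inheritParams extract_signatures
#' @return `data.frame` with columns `k`, `reconstruction_error`,
#'   `stability`.
#' @export
scan_signature_rank <- function(m, ks, n_restarts = 10L, seed = 1L,
                                max_iter = 2000L, tol = 1e-8) {
  V <- if (methods::is(m, "sbs96_matrix")) m$counts else as.matrix(m)
  do.call(rbind, lapply(ks, function(k) {
    sigs <- vector("list", n_restarts)
    errs <- numeric(n_restarts)
    for (r in seq_len(n_restarts)) {
      fit <- extract_signatures(V, k, n_restarts = 1L,
                                seed = as.integer(seed) + (r - 1L) * 1000L,
                                max_iter = max_iter, tol = tol)
      sigs[[r]] <- fit$signatures
      errs[r] <- fit$reconstruction_error
    }
    # stability: mean, over restart pairs, of mean cosine of greedily
    # best-matched signature columns
    pair_cos <- c()
    for (a in seq_len(n_restarts - 1L)) for (b in seq(a + 1L, n_restarts)) {
      cm <- cosine_matrix(sigs[[a]], sigs[[b]])
      matched <- numeric(0)
      free <- seq_len(k)
      for (i in seq_len(k)) {
        j <- free[which.max(cm[i, free])]
        matched <- c(matched, cm[i, j])
        free <- base::setdiff(free, j)
      }
      pair_cos <- c(pair_cos, mean(matched))
    }
    data.frame(k = k, reconstruction_error = min(errs),
               stability = if (length(pair_cos)) mean(pair_cos) else NA_real_)
  }))
}

#' Refit exposures to known signatures
#'
#' Per-sample non-negative least-squares fit of the SBS96 channel counts
#' onto a fixed set of reference signatures.
#'
#' @param m An `sbs96_matrix` or 96 x n count matrix.
#' @param refs 96 x k column-stochastic signature matrix with channel
#'   rownames in canonical order.
#' @return k x n exposure matrix (attributed mutation counts).
#' @export
fit_exposures <- function(m, refs) {
  V <- if (methods::is(m, "sbs96_matrix")) m$counts else as.matrix(m)
  refs <- as.matrix(refs)
  if (nrow(refs) != nrow(V))
    stop("format error: channel dimension mismatch between matrix and refs")
  if (!is.null(rownames(refs)) && !is.null(rownames(V)) &&
      !identical(rownames(refs), rownames(V)))
    stop("format error: channel order mismatch between matrix and refs")
  E <- matrix(0, ncol(refs), ncol(V),
              dimnames = list(colnames(refs), colnames(V)))
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    if (sum(v) == 0) next
    E[, j] <- pracma::lsqnonneg(refs, v)$x
  }
  E
}

#' Cosine similarity between signature sets
#'
#' @param a,b Matrices with signatures in columns (same row/channel order).
#' @return `ncol(a)` x `ncol(b)` cosine similarity matrix.
#' @export
cosine_matrix <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  crossprod(a, b) / (na %o% nb)
}

#' Match extracted signatures to a reference catalog
#'
#' Computes the full cosine similarity matrix between extracted signatures
#' and a catalog and reports each signature's best-matching catalog entry.
#'
#' @param sigs 96 x k signature matrix.
#' @param catalog 96 x m catalog matrix (same channel order), or a path
#'   readable by [read_sbs96_tsv()].
#' @return List with `best` (`data.frame`: `signature`, `match`, `cosine`)
#'   and `similarity` (k x m matrix).
#' @export
match_to_catalog <- function(sigs, catalog) {
  if (is.character(catalog)) catalog <- read_sbs96_tsv(catalog)
  if (!is.null(rownames(sigs)) && !is.null(rownames(catalog)) &&
      !identical(rownames(sigs), rownames(catalog)))
    stop("format error: channel order mismatch between signatures and catalog")
  cm <- cosine_matrix(sigs, catalog)
  best <- data.frame(
    signature = colnames(sigs) %||% paste0("Sig", seq_len(ncol(sigs))),
    match = colnames(catalog)[apply(cm, 1, which.max)],
    cosine = apply(cm, 1, max),
    stringsAsFactors = FALSE)
  list(best = best, similarity = cm)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
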