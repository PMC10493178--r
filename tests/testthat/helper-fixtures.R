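# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code from fixed seeds; nothing is read from disk besides what
# the generators themselves write.

.fx <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_genome <- function() .memo("genome", function()
  make_genome(7, dir = file.path(tempdir(), "fxgenome")))

fx_models <- function() .memo("models", function()
  make_gene_models(fx_genome(), 8, dir = file.path(tempdir(), "fxmodels")))

fx_index <- function() .memo("index", function()
  load_gene_models(fx_models()$gtf))

# small cohort for unit tests: 2 groups x 2 replicates, ~300 variants each
fx_small <- function() .memo("small", function()
  make_cohort(fx_genome(), fx_models(),
              cohort_spec(groups = list(grpA = 2L, grpB = 2L),
                          n_core = 200L, n_private = 100L),
              seed = 11, dir = file.path(tempdir(), "fxsmall")))

fx_small_cohort <- function() .memo("small_cohort", function()
  assemble_cohort(fx_small()$file_manifest))

# study-scale cohort: 2 groups x 3 replicates x 2000 variants
fx_full <- function() .memo("full", function()
  make_cohort(fx_genome(), fx_models(), cohort_spec(), seed = 13,
              dir = file.path(tempdir(), "fxfull")))

fx_full_cohort <- function() .memo("full_cohort", function()
  assemble_cohort(fx_full()$file_manifest))

fx_full_annotated <- function() .memo("full_annotated", function()
  annotate_variants(fx_full_cohort(), fx_index()))

# cohort with SNVs planted on SBS96 channels from a 4-signature mixture
fx_channel <- function() .memo("channel", function() {
  sigs <- make_signature_set(42, k = 4)
  mix <- list(grpA = c(0.7, 0.3, 0, 0), grpB = c(0, 0, 0.5, 0.5))
  make_cohort(fx_genome(), fx_models(),
              cohort_spec(groups = list(grpA = 2L, grpB = 2L),
                          n_core = 300L, n_private = 150L,
                          class_mix = c(SNV = 0.9, INSERTION = 0.05,
                                        DELETION = 0.05),
                          feature_mix = NULL,
                          signature_mix = list(signatures = sigs, mix = mix)),
              seed = 17, dir = file.path(tempdir(), "fxchannel"))
})

# simulated input bundle + run config for the command-surface tests
fx_bundle <- function() .memo("bundle", function() {
  out <- file.path(tempdir(), "bundle")
  suppressMessages(
    run_subcommand("simulate", list(out_dir = out, seed = 19, plots = FALSE)))
  list(dir = out, config = file.path(out, "run_config.yaml"))
})

# ---- independent oracles (deliberately plain-loop implementations) ----

# Brute-force feature annotation: linear scan over the generator's internal
# model table, applying the documented precedence per transcript.
oracle_annotate <- function(chrom, pos, model, ud = 1000L, w = 2L) {
  prec <- c("exonic", "splicing", "UTR5", "UTR3", "intronic", "upstream",
            "downstream", "intergenic")
  best <- "intergenic"
  best_genes <- character(0)
  consider <- function(cat, gene) {
    if (match(cat, prec) < match(best, prec)) {
      best <<- cat; best_genes <<- gene
    } else if (cat == best) {
      best_genes <<- union(best_genes, gene)
    }
  }
  txs <- model[model$type == "transcript" & model$chrom == chrom, ,
               drop = FALSE]
  for (i in seq_len(nrow(txs))) {
    tx <- txs[i, ]
    ex <- model[model$type == "exon" & model$tx_id == tx$tx_id, ,
                drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- model[model$type == "CDS" & model$tx_id == tx$tx_id, ,
                drop = FALSE]
    in_exon <- any(pos >= ex$start & pos <= ex$end)
    if (in_exon) {
      if (nrow(cd) == 0L) { consider("exonic", tx$gene); next }
      cs <- min(cd$start); ce <- max(cd$end)
      if (pos >= cs && pos <= ce) consider("exonic", tx$gene)
      else if (pos < cs) consider(if (tx$strand == "+") "UTR5" else "UTR3",
                                  tx$gene)
      else consider(if (tx$strand == "+") "UTR3" else "UTR5", tx$gene)
      next
    }
    if (pos >= tx$start && pos <= tx$end) {
      # intronic; splice window?
      splice <- FALSE
      if (nrow(ex) > 1L) {
        is_ <- utils::head(ex$end, -1) + 1L
        ie <- utils::tail(ex$start, -1) - 1L
        for (k in seq_along(is_)) {
          if (pos >= is_[k] && pos <= ie[k] &&
              (pos - is_[k] < w || ie[k] - pos < w))
            splice <- TRUE
        }
      }
      consider(if (splice) "splicing" else "intronic", tx$gene)
      next
    }
    if (tx$strand == "+") {
      if (pos >= tx$start - ud && pos < tx$start) consider("upstream", tx$gene)
      if (pos > tx$end && pos <= tx$end + ud) consider("downstream", tx$gene)
    } else {
      if (pos > tx$end && pos <= tx$end + ud) consider("upstream", tx$gene)
      if (pos >= tx$start - ud && pos < tx$start) consider("downstream", tx$gene)
    }
  }
  list(category = best,
       genes = paste(sort(unique(best_genes)), collapse = ","))
}

# Nested-loop Venn region counts over key sets.
oracle_venn <- function(keysets) {
  samples <- names(keysets)
  allkeys <- unique(unlist(keysets, use.names = FALSE))
  n <- length(samples)
  out <- list()
  for (m in seq_len(2^n - 1L)) {
    ix <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L)
    cnt <- 0L
    rest <- setdiff(seq_len(n), ix)
    for (k in allkeys) {
      inside <- vapply(seq_len(n), function(j) k %in% keysets[[j]],
                       logical(1))
      if (all(inside[ix]) && !any(inside[rest])) cnt <- cnt + 1L
    }
    out[[paste(samples[ix], collapse = "&")]] <- cnt
  }
  out
}

# Apply a variant to a sequence string: returns the edited sequence.
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Random non-degenerate allele pair (possibly redundant representation).
random_allele_pair <- function() {
  bases <- c("A", "C", "G", "T")
  repeat {
    core_r <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                    collapse = "")
    core_a <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                    collapse = "")
    pre <- paste(sample(bases, sample(0:3, 1), replace = TRUE), collapse = "")
    suf <- paste(sample(bases, sample(0:3, 1), replace = TRUE), collapse = "")
    ref <- paste0(pre, core_r, suf)
    alt <- paste0(pre, core_a, suf)
    if (ref != alt) return(list(ref = ref, alt = alt))
  }
}
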