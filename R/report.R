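#' @import ggplot2
NULL

#' Load a run configuration
#'
#' Reads a YAML run configuration and fills defaults. Fields: `manifest`
#' (file-manifest TSV: `path`, `group`, `sample`), `genome` (FASTA),
#' `gene_models` (GTF/GFF3), `drivers`, `catalog`, `known_sites` (optional),
#' `out_dir`, `pass_only`, `annotation_mode` (`"native"` or `"info"`),
#' `window_bp`, `indel_bins`, `upstream_downstream_bp`, `splice_window_bp`,
#' `top_n_genes`, `signatures` (`k`, `n_restarts`, `seed`), `plots`.
#'
#' @param path YAML file path, or a named list of the same fields.
#' @param overrides Named list of fields overriding the file (flags win).
#' @return A `run_config` list.
#' @export
load_run_config <- function(path, overrides = list()) {
  if (!is.list(path) && !file.exists(path))
    stop("configuration error: no such config file '", path, "'")
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  defaults <- list(pass_only = TRUE, annotation_mode = "native",
                   window_bp = 1000000L, indel_bins = c(1L, 2L, 3L, 4L, 6L, 11L),
                   upstream_downstream_bp = 1000L, splice_window_bp = 2L,
                   top_n_genes = 10L, plots = TRUE,
                   signatures = list(k = 2L, n_restarts = 10L, seed = 1L))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$signatures))
    if (is.null(cfg$signatures[[nm]]))
      cfg$signatures[[nm]] <- defaults$signatures[[nm]]
  if (is.null(cfg$out_dir))
    stop("configuration error: out_dir is required")
  structure(cfg, class = "run_config")
}

.log_stage <- function(...) message("[vcfcohort] ", ...)

# Load and (if configured) annotate the cohort defined by a run config.
.load_inputs <- function(cfg, need_annotation = FALSE) {
  if (is.null(cfg$manifest))
    stop("configuration error: manifest is required")
  cohort <- assemble_cohort(cfg$manifest, pass_only = isTRUE(cfg$pass_only))
  .log_stage("loaded cohort: ", nrow(cohort$samples), " samples, ",
             nrow(cohort$variants), " variant records")
  if (need_annotation) {
    if (identical(cfg$annotation_mode, "info")) {
      cohort <- parse_annovar_annotation(cohort)
      .log_stage("mapped Annovar-style INFO annotations onto feature calls")
    } else {
      if (is.null(cfg$gene_models))
        stop("configuration error: gene_models is required for native annotation")
      idx <- load_gene_models(cfg$gene_models)
      acfg <- annotation_config(cfg$upstream_downstream_bp,
                                cfg$splice_window_bp)
      cohort <- annotate_variants(cohort, idx, acfg)
      .log_stage("annotated ", nrow(cohort$variants),
                 " records against ", idx$n_genes, " genes")
    }
    if (!is.null(cfg$known_sites)) {
      cohort <- annotate_known_sites(cohort, cfg$known_sites)
      .log_stage("flagged ", sum(cohort$variants$known_site), " known sites")
    }
  }
  cohort
}

.save_plot <- function(p, path, width = 7, height = 5) {
  ok <- tryCatch({
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    warning("could not render plot '", path, "': ", conditionMessage(e))
    FALSE
  })
  invisible(ok)
}

#' Summary plots
#'
#' Simple static ggplot2 renderings of the summary tables: per-sample
#' totals bar chart, substitution spectrum bars, indel length histograms,
#' feature-category stacked bars, replicate-overlap region bars and driver
#' gene counts.
#'
#' @param df The corresponding summary table.
#' @return A ggplot object.
#' @name summary_plots
NULL

#' @rdname summary_plots
#' @export
plot_totals <- function(df) {
  d <- df[df$category != "total", , drop = FALSE]
  ggplot(d, aes(x = sample, y = count, fill = category)) +
    geom_col() + facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    labs(y = "variants", title = "Total variants per sample") +
    theme_bw() + theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname summary_plots
#' @export
plot_spectrum <- function(df) {
  ggplot(df, aes(x = category, y = frequency, fill = category)) +
    geom_col() + facet_wrap(~sample) +
    labs(x = "substitution", y = "frequency of sample SNVs",
         title = "Base substitution spectrum") +
    theme_bw() + theme(legend.position = "none",
                       axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname summary_plots
#' @export
plot_indels <- function(df) {
  ggplot(df, aes(x = category, y = frequency, fill = indel_type)) +
    geom_col(position = "dodge") + facet_wrap(~sample) +
    labs(x = "indel length (bp)", y = "frequency",
         title = "Indel length distribution") + theme_bw()
}

#' @rdname summary_plots
#' @export
plot_features <- function(df) {
  ggplot(df, aes(x = sample, y = frequency, fill = category)) +
    geom_col() + labs(y = "fraction of variants",
                      title = "Genomic feature distribution") +
    theme_bw() + theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname summary_plots
#' @export
plot_overlap <- function(df) {
  ggplot(df, aes(x = stats::reorder(subset, n_samples), y = count)) +
    geom_col(fill = "steelblue") + coord_flip() +
    labs(x = "replicate subset (exclusive region)", y = "variants",
         title = "Replicate overlap") + theme_bw()
}

#' @rdname summary_plots
#' @export
plot_drivers <- function(df) {
  ggplot(df, aes(x = gene, y = count, fill = sample)) +
    geom_col(position = "dodge") +
    labs(title = "Variants in cancer driver genes") + theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname summary_plots
#' @export
plot_genome_windows <- function(df) {
  d <- df[df$chrom != "unplaced", , drop = FALSE]
  ggplot(d, aes(x = window_start, y = snv_count + indel_count,
                colour = sample)) +
    geom_step() + facet_grid(chrom ~ .) +
    labs(x = "position", y = "variants / window",
         title = "Genome-wide variant density") + theme_bw()
}

#' Run one pipeline subcommand
#'
#' Non-interactive command surface over the package pipeline. Subcommands:
#' `simulate` (generate a complete synthetic input bundle into `out_dir`),
#' `annotate`, `summarize` (totals + replicate overlap), `spectrum`,
#' `indels`, `circos-data` (per-window counts), `features`, `genes`
#' (high-frequency gene ranking), `drivers`, `signatures` (SBS96 matrix,
#' de novo extraction, catalog refit/match), and `report` (everything, plus
#' static plots). All outputs are deterministic TSVs written atomically into
#' `out_dir`; a resolved copy of the configuration is written beside them.
#'
#' @param name Subcommand name.
#' @param cfg A `run_config` ([load_run_config()]), a path to one, or a
#'   named list.
#' @return Invisibly, a named list of written output paths.
#' @export
run_subcommand <- function(name, cfg) {
  subcommands <- c("simulate", "annotate", "summarize", "spectrum", "indels",
                   "circos-data", "features", "genes", "drivers",
                   "signatures", "report")
  if (!name %in% subcommands)
    stop("configuration error: unknown subcommand '", name, "'")
  if (!inherits(cfg, "run_config")) cfg <- load_run_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resolved <- unclass(cfg)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  outputs <- list()
  put <- function(df, file) {
    p <- file.path(out_dir, file)
    write_summary_tsv(df, p)
    outputs[[file]] <<- p
    .log_stage("wrote ", file, " (", nrow(df), " rows)")
    p
  }

  if (name == "simulate") {
    seed <- cfg$seed %||% 1L
    genome <- make_genome(seed, dir = file.path(out_dir, "genome"))
    models <- make_gene_models(genome, seed + 1L,
                               dir = file.path(out_dir, "models"))
    drivers <- file.path(out_dir, "drivers.tsv")
    make_driver_list(models, seed + 2L, path = drivers)
    catalog <- file.path(out_dir, "catalog.tsv")
    make_signature_set(seed + 3L, k = 4L, path = catalog)
    fx <- make_cohort(genome, models, cohort_spec(), seed = seed + 4L,
                      dir = file.path(out_dir, "cohort"))
    run_cfg <- list(manifest = file.path(fx$dir, "file_manifest.tsv"),
                    genome = genome$fasta, gene_models = models$gtf,
                    chrom_sizes = genome$chrom_sizes,
                    drivers = drivers, catalog = catalog,
                    out_dir = file.path(out_dir, "results"),
                    window_bp = fx$spec$window_bp,
                    signatures = list(k = 2L, n_restarts = 5L, seed = seed))
    yaml::write_yaml(run_cfg, file.path(out_dir, "run_config.yaml"))
    .log_stage("simulated cohort bundle in ", out_dir)
    outputs$run_config <- file.path(out_dir, "run_config.yaml")
    return(invisible(outputs))
  }

  need_ann <- name %in% c("annotate", "features", "genes", "drivers", "report")
  cohort <- .load_inputs(cfg, need_annotation = need_ann)
  plots <- isTRUE(cfg$plots) && name == "report"

  if (name %in% c("annotate")) {
    put_path <- file.path(out_dir, "annotated_variants.tsv")
    write_variants_tsv(cohort, put_path)
    outputs[["annotated_variants.tsv"]] <- put_path
    return(invisible(outputs))
  }
  if (name %in% c("summarize", "report")) {
    tot <- count_variants(cohort)
    put(tot, "variant_totals.tsv")
    ov <- do.call(rbind, lapply(unique(cohort$samples$group), function(g) {
      d <- replicate_overlap(cohort, g)
      d$group <- g
      d
    }))
    put(ov, "replicate_overlap.tsv")
    if (plots) {
      .save_plot(plot_totals(tot), file.path(out_dir, "variant_totals.png"))
      .save_plot(plot_overlap(ov), file.path(out_dir, "replicate_overlap.png"))
    }
  }
  if (name %in% c("spectrum", "report")) {
    sp6 <- substitution_spectrum(cohort, collapse = TRUE)
    sp12 <- substitution_spectrum(cohort, collapse = FALSE)
    put(sp6, "substitution_spectrum_6class.tsv")
    put(sp12, "substitution_spectrum_12class.tsv")
    if (plots)
      .save_plot(plot_spectrum(sp6), file.path(out_dir, "spectrum.png"))
  }
  if (name %in% c("indels", "report")) {
    ind <- indel_length_distribution(cohort, cfg$indel_bins)
    put(ind, "indel_length_distribution.tsv")
    if (plots)
      .save_plot(plot_indels(ind), file.path(out_dir, "indel_lengths.png"))
  }
  if (name %in% c("circos-data", "report")) {
    if (is.null(cfg$chrom_sizes))
      stop("configuration error: chrom_sizes is required for window counts")
    win <- genome_distribution(cohort, cfg$chrom_sizes, cfg$window_bp)
    put(win, "genome_windows.tsv")
    circ <- data.frame(chrom = win$chrom, start = win$window_start,
                       end = win$window_end, sample = win$sample,
                       value = win$snv_count + win$indel_count)
    put(circ, "circos_track.tsv")
    if (plots)
      .save_plot(plot_genome_windows(win), file.path(out_dir,
                                                     "genome_windows.png"))
  }
  if (name %in% c("features", "report")) {
    fd <- feature_distribution(cohort)
    put(fd, "feature_distribution.tsv")
    if (plots)
      .save_plot(plot_features(fd), file.path(out_dir, "features.png"))
  }
  if (name %in% c("genes", "report")) {
    gr <- gene_mutation_ranking(cohort, top_n = cfg$top_n_genes)
    put(gr, "gene_ranking.tsv")
  }
  if (name %in% c("drivers", "report")) {
    if (is.null(cfg$drivers))
      stop("configuration error: drivers list is required")
    dt <- driver_gene_tally(cohort, cfg$drivers)
    put(dt$per_gene, "driver_gene_counts.tsv")
    put(dt$totals, "driver_gene_totals.tsv")
    if (plots && nrow(dt$per_gene))
      .save_plot(plot_drivers(dt$per_gene), file.path(out_dir, "drivers.png"))
  }
  if (name %in% c("signatures", "report")) {
    if (is.null(cfg$genome))
      stop("configuration error: genome FASTA is required for signatures")
    sbs <- build_sbs96(cohort, cfg$genome)
    write_sbs96_tsv(sbs, file.path(out_dir, "sbs96_matrix.tsv"))
    outputs[["sbs96_matrix.tsv"]] <- file.path(out_dir, "sbs96_matrix.tsv")
    sg <- cfg$signatures
    fit <- extract_signatures(sbs, k = sg$k, n_restarts = sg$n_restarts,
                              seed = sg$seed)
    write_sbs96_tsv(fit$signatures, file.path(out_dir,
                                              "denovo_signatures.tsv"))
    outputs[["denovo_signatures.tsv"]] <-
      file.path(out_dir, "denovo_signatures.tsv")
    expo <- data.frame(signature = rownames(fit$exposures), fit$exposures,
                       check.names = FALSE)
    put(expo, "denovo_exposures.tsv")
    if (!is.null(cfg$catalog)) {
      refs <- read_sbs96_tsv(cfg$catalog)
      refit <- fit_exposures(sbs, refs)
      put(data.frame(signature = rownames(refit), refit,
                     check.names = FALSE), "refit_exposures.tsv")
      mm <- match_to_catalog(fit$signatures, refs)
      put(mm$best, "signature_catalog_match.tsv")
    }
    .log_stage("signature extraction: k=", sg$k, ", reconstruction error ",
               format(fit$reconstruction_error, digits = 6))
  }
  invisible(outputs)
}
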