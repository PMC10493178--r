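probe_df <- function(chrom, pos) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
             vclass = "SNV", indel_len = 0L, sample = "p",
             filter_pass = TRUE, info = ".", stringsAsFactors = FALSE)
}

test_that("CDS positions are exonic and report the owning gene", {
  m <- fx_models()$model
  idx <- fx_index()
  cds <- m[m$type == "CDS", ][1, ]
  p <- probe_df(cds$chrom, (cds$start + cds$end) %/% 2)
  a <- annotate_variants(p, idx)
  expect_equal(a$feature, "exonic")
  expect_equal(a$genes, cds$gene)
  expect_equal(a$distance, 0L)
})

test_that("splice window boundary: 2 bp inside an intron is splicing, 3 bp is intronic", {
  m <- fx_models()$model
  idx <- fx_index()
  # find a transcript with an intron; take the first intron of the first
  # multi-exon transcript
  found <- FALSE
  for (id in unique(m$tx_id[m$type == "exon"])) {
    ex <- m[m$type == "exon" & m$tx_id == id, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) next
    intron_start <- ex$end[1] + 1L
    # guard against another transcript's exon covering the window
    probes <- probe_df(ex$chrom[1], intron_start + c(0L, 1L, 2L))
    a <- annotate_variants(probes, idx)
    if (all(a$feature %in% c("splicing", "intronic"))) {
      expect_equal(a$feature, c("splicing", "splicing", "intronic"))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("indexed annotation equals a brute-force linear scan on 500 probes", {
  g <- fx_genome()
  m <- fx_models()
  idx <- fx_index()
  set.seed(31)
  probes <- probe_df(sample(names(g$sizes), 500, replace = TRUE),
                     sample(2000:148000, 500))
  a <- annotate_variants(probes, idx)
  for (i in seq_len(nrow(probes))) {
    o <- oracle_annotate(probes$chrom[i], probes$pos[i], m$model)
    expect_equal(a$feature[i], o$category,
                 label = sprintf("feature at %s:%d", probes$chrom[i],
                                 probes$pos[i]))
    if (o$category != "intergenic")
      expect_equal(a$genes[i], o$genes,
                   label = sprintf("genes at %s:%d", probes$chrom[i],
                                   probes$pos[i]))
  }
})

test_that("an exhaustive 1-bp scan assigns exactly one category per position", {
  idx <- fx_index()
  g <- fx_genome()
  # scan a 12 kb slab containing genes of chr1
  m <- fx_models()$model
  tx1 <- m[m$type == "transcript" & m$chrom == "chr1", ][1, ]
  from <- max(1L, tx1$start - 2000L)
  pos <- from:(from + 12000L)
  a <- annotate_variants(probe_df("chr1", pos), idx)
  expect_false(any(is.na(a$feature)))
  expect_true(all(a$feature %in%
                    c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                      "upstream", "downstream", "intergenic")))
  # category counts conserve the scanned length
  expect_equal(sum(table(a$feature)), length(pos))
})

test_that("variants on chromosomes absent from the index are flagged intergenic", {
  idx <- fx_index()
  expect_warning(a <- annotate_variants(probe_df("chrUn", 500), idx),
                 "absent")
  expect_equal(a$feature, "intergenic")
  expect_equal(a$genes, "")
})

test_that("feature category does not depend on the variant alleles", {
  idx <- fx_index()
  m <- fx_models()$model
  cds <- m[m$type == "CDS", ][1, ]
  p1 <- probe_df(cds$chrom, cds$start + 5L)
  p2 <- p1; p2$ref <- "C"; p2$alt <- "CAT"; p2$vclass <- "INSERTION"
  p2$indel_len <- 2L
  expect_equal(annotate_variants(p1, idx)$feature,
               annotate_variants(p2, idx)$feature)
})

test_that("Annovar-style INFO keys map onto the feature vocabulary", {
  v <- probe_df("chr1", c(10, 20, 30, 40))
  v$info <- c("Func.refGene=exonic;Gene.refGene=G1",
              "Func.refGene=ncRNA_intronic;Gene.refGene=G2",
              "Func.refGene=UTR5;Gene.refGene=G3",
              "DP=4")
  a <- parse_annovar_annotation(v)
  expect_equal(a$feature, c("exonic", "intronic", "UTR5", NA))
  expect_equal(a$genes[1:3], c("G1", "G2", "G3"))
})

test_that("annotated fixture VCFs parse to the planted categories", {
  fx <- fx_small()
  co <- assemble_cohort(fx$annotated_manifest)
  co <- parse_annovar_annotation(co)
  fd <- feature_distribution(co)
  s <- co$samples$sample[1]
  exp <- unlist(fx$manifest$samples[[s]]$feature_counts)
  got <- stats::setNames(fd$count[fd$sample == s], fd$category[fd$sample == s])
  expect_equal(got[names(exp)], exp)
})

test_that("known-site flags match a nested-loop comparison", {
  set.seed(41)
  n <- 1000
  v <- probe_df(sample(c("chr1", "chr2"), n, replace = TRUE),
                sample(1:5000, n, replace = TRUE))
  v$ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  v$alt <- vapply(v$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                      pos = sample(1:5000, 100),
                      id = paste0("rs", 1:100), stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(paste(sites$chrom, sites$pos, sites$id, sep = "\t"), tsv)
  a <- annotate_known_sites(v, tsv)
  exp <- vapply(seq_len(n), function(i)
    any(sites$chrom == v$chrom[i] & sites$pos == v$pos[i]), logical(1))
  expect_identical(a$known_site, exp)
  # allele-aware table only flags matching alleles
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(paste(v$chrom[1], v$pos[1], v$ref[1],
                   setdiff(c("A", "C", "G", "T"), c(v$ref[1], v$alt[1]))[1],
                   "rsX", sep = "\t"), tsv2)
  a2 <- annotate_known_sites(v[1, ], tsv2)
  expect_false(a2$known_site)
})

test_that("BED intervals flag by overlap; empty site tables flag nothing", {
  v <- probe_df("chr1", c(100, 150, 201))
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tregion1", bed)  # 0-based half-open = 100..200
  a <- annotate_known_sites(v, bed)
  expect_equal(a$known_site, c(TRUE, TRUE, FALSE))
  expect_equal(a$site_id[1], "region1")
  emptyf <- tempfile(fileext = ".tsv")
  writeLines(character(0), emptyf)
  a0 <- annotate_known_sites(v, emptyf)
  expect_false(any(a0$known_site))
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t99", bad)
  expect_error(annotate_known_sites(v, bad), "line 1")
})
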