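mini_cohort <- function(per_sample, groups = NULL) {
  # per_sample: named list of data.frames with chrom/pos/ref/alt
  rows <- list()
  for (s in names(per_sample)) {
    d <- per_sample[[s]]
    nv <- normalize_variant(d$pos, d$ref, d$alt)
    cl <- classify_variant(nv$ref, nv$alt)
    rows[[s]] <- data.frame(chrom = d$chrom, pos = nv$pos, ref = nv$ref,
                            alt = nv$alt, vclass = cl$vclass,
                            indel_len = cl$indel_len, sample = s,
                            filter_pass = TRUE, info = ".",
                            stringsAsFactors = FALSE)
  }
  if (is.null(groups))
    groups <- data.frame(sample = names(per_sample), group = "g1",
                         stringsAsFactors = FALSE)
  new_cohort(do.call(rbind, rows), groups)
}

test_that("variant totals count classes and tolerate empty samples", {
  co <- mini_cohort(list(
    s1 = data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                    ref = c("A", "C", "G", "T"),
                    alt = c("G", "T", "GAA", "A")),
    s2 = data.frame(chrom = "chr1", pos = 50, ref = "AT", alt = "A")))
  tot <- count_variants(co)
  g <- function(s, cat) tot$count[tot$sample == s & tot$category == cat]
  expect_equal(g("s1", "total"), 4L)
  expect_equal(g("s1", "SNV"), 3L)
  expect_equal(g("s1", "INSERTION"), 1L)
  expect_equal(g("s2", "DELETION"), 1L)
  expect_equal(g("s2", "SNV"), 0L)
  # empty sample: all zeros
  co2 <- new_cohort(co$variants[co$variants$sample == "s1", ],
                    data.frame(sample = c("s1", "sEmpty"), group = "g1"))
  tot2 <- count_variants(co2)
  expect_true(all(tot2$count[tot2$sample == "sEmpty"] == 0L))
})

test_that("replicate overlap computes exclusive Venn regions", {
  # A = {k1,k2,k3}, B = {k2,k3,k4} -> A-only 1, shared 2, B-only 1
  co <- mini_cohort(list(
    A = data.frame(chrom = "chr1", pos = c(1, 2, 3), ref = "A", alt = "G"),
    B = data.frame(chrom = "chr1", pos = c(2, 3, 4), ref = "A", alt = "G")))
  ov <- replicate_overlap(co, "g1")
  g <- function(sub) ov$count[ov$subset == sub]
  expect_equal(g("A"), 1L)
  expect_equal(g("B"), 1L)
  expect_equal(g("A&B"), 2L)
  expect_equal(attr(ov, "union_size"), 4L)
  expect_equal(sum(ov$count), attr(ov, "union_size"))
  # identical replicates: only the full intersection is non-zero
  co2 <- mini_cohort(list(
    r1 = data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G"),
    r2 = data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G")))
  ov2 <- replicate_overlap(co2, "g1")
  expect_equal(ov2$count[ov2$subset == "r1&r2"], 5L)
  expect_true(all(ov2$count[ov2$subset != "r1&r2"] == 0L))
  expect_error(replicate_overlap(co2, "nope"), "configuration error")
})

test_that("overlap of 3 random replicate sets matches nested-loop membership", {
  set.seed(51)
  keys <- replicate(3, sample(1:400, 200), simplify = FALSE)
  per_sample <- lapply(keys, function(k)
    data.frame(chrom = "chr1", pos = k, ref = "A", alt = "G"))
  names(per_sample) <- c("r1", "r2", "r3")
  co <- mini_cohort(per_sample)
  ov <- replicate_overlap(co, "g1")
  keysets <- lapply(per_sample, function(d) paste0("chr1:", d$pos, ":A:G"))
  exp <- oracle_venn(keysets)
  for (sub in names(exp))
    expect_equal(ov$count[ov$subset == sub], exp[[sub]], label = sub)
  expect_equal(sum(ov$count), attr(ov, "union_size"))
})

test_that("substitution spectrum collapses purine classes and normalizes", {
  # counts {C>A:3, G>T:1, T>C:4}: G>T complements to C>A -> {C>A:0.5, T>C:0.5}
  co <- mini_cohort(list(s1 = data.frame(
    chrom = "chr1", pos = 1:8,
    ref = c("C", "C", "C", "G", "T", "T", "T", "T"),
    alt = c("A", "A", "A", "T", "C", "C", "C", "C"))))
  sp <- substitution_spectrum(co, collapse = TRUE)
  f <- function(cat) sp$frequency[sp$category == cat]
  expect_equal(f("C>A"), 0.5)
  expect_equal(f("T>C"), 0.5)
  expect_equal(sum(sp$frequency), 1)
  # 12-class table keeps direction
  sp12 <- substitution_spectrum(co, collapse = FALSE)
  c12 <- stats::setNames(sp12$count, sp12$category)
  expect_equal(unname(c12[c("C>A", "G>T", "T>C")]), c(3L, 1L, 4L))
  expect_equal(sum(sp12$count), 8L)
  # 6-class equals 12-class with complementary pairs summed
  comp <- collapse_substitution(sp12$category)
  agg <- tapply(sp12$count, comp, sum)
  sp6c <- stats::setNames(sp$count, sp$category)
  expect_equal(unname(sp6c[names(agg)]), unname(as.integer(agg)))
})

test_that("spectrum of an SNV-free sample is zero and flagged", {
  co <- mini_cohort(list(s1 = data.frame(chrom = "chr1", pos = 10,
                                         ref = "A", alt = "AT")))
  sp <- substitution_spectrum(co)
  expect_true(all(sp$frequency == 0))
  expect_equal(attr(sp, "zero_snv_samples"), "s1")
})

test_that("indel lengths bin into the default ranges", {
  mkindel <- function(pos, len, ins) {
    data.frame(chrom = "chr1", pos = pos,
               ref = if (ins) "A" else paste0("A", strrep("C", len)),
               alt = if (ins) paste0("A", strrep("C", len)) else "A")
  }
  co <- mini_cohort(list(s1 = rbind(
    mkindel(10, 1, TRUE), mkindel(20, 1, TRUE), mkindel(30, 2, TRUE),
    mkindel(40, 7, TRUE), mkindel(100, 11, FALSE))))
  ind <- indel_length_distribution(co)
  ins <- ind[ind$indel_type == "INSERTION", ]
  f <- function(cat) ins$frequency[ins$category == cat]
  expect_equal(f("1"), 0.5)
  expect_equal(f("2"), 0.25)
  expect_equal(f("6-10"), 0.25)
  del <- ind[ind$indel_type == "DELETION", ]
  expect_equal(del$count[del$category == ">10"], 1L)  # len 11 -> open bin
  expect_error(indel_length_distribution(co, c(3, 2, 1)),
               "configuration error")
})

test_that("random indel histograms equal direct per-bin counting", {
  set.seed(61)
  lens <- sample(1:15, 500, replace = TRUE, prob = 15:1)
  df <- data.frame(chrom = "chr1", pos = seq_len(500) * 30,
                   ref = paste0("A", strrep("C", 1)), alt = "A")
  df$ref <- vapply(lens, function(l) paste0("A", strrep("C", l)), "")
  co <- mini_cohort(list(s1 = df))
  ind <- indel_length_distribution(co)
  del <- ind[ind$indel_type == "DELETION", ]
  edges <- c(1, 2, 3, 4, 6, 11)
  direct <- table(cut(lens, c(edges, Inf), right = FALSE))
  expect_equal(del$count, unname(as.integer(direct)))
  expect_equal(sum(del$count), 500L)
  expect_equal(sum(del$frequency), 1)
})

test_that("genome windows tile chromosomes and conserve totals", {
  co <- mini_cohort(list(s1 = data.frame(
    chrom = "chr1", pos = c(5, 50, 100, 101, 250),
    ref = c("A", "C", "G", "A", "A"),
    alt = c("G", "T", "A", "AT", "G"))))
  win <- genome_distribution(co, c(chr1 = 250L), window_bp = 100)
  expect_equal(win$window_start, c(1L, 101L, 201L))
  expect_equal(win$window_end, c(100L, 200L, 250L))
  expect_equal(win$snv_count, c(3L, 0L, 1L))
  expect_equal(win$indel_count, c(0L, 1L, 0L))
  # all variants in first window
  co2 <- mini_cohort(list(s1 = data.frame(chrom = "chr1", pos = c(10, 20),
                                          ref = "A", alt = "G")))
  win2 <- genome_distribution(co2, c(chr1 = 250L), window_bp = 100)
  expect_equal(win2$snv_count, c(2L, 0L, 0L))
  # unknown chromosome goes to the unplaced bucket with a warning
  co3 <- mini_cohort(list(s1 = data.frame(chrom = c("chr1", "chrX"),
                                          pos = c(10, 10),
                                          ref = "A", alt = "G")))
  expect_warning(win3 <- genome_distribution(co3, c(chr1 = 250L), 100),
                 "unplaced")
  expect_equal(win3$snv_count[win3$chrom == "unplaced"], 1L)
})

test_that("feature distribution frequencies are per-sample fractions", {
  co <- mini_cohort(list(s1 = data.frame(chrom = "chr1", pos = 1:10,
                                         ref = "A", alt = "G")))
  co$variants$feature <- rep(c("exonic", "intergenic"), c(4, 6))
  fd <- feature_distribution(co)
  expect_equal(fd$frequency[fd$category == "exonic"], 0.4)
  expect_equal(fd$frequency[fd$category == "intergenic"], 0.6)
  expect_equal(sum(fd$frequency), 1)
  co$variants$feature[1] <- NA
  expect_error(feature_distribution(co), "s1")
  co$variants$feature <- NULL
  expect_error(feature_distribution(co), "not annotated")
})

test_that("gene ranking orders by count with lexicographic ties", {
  co <- mini_cohort(list(s1 = data.frame(chrom = "chr1", pos = 1:8,
                                         ref = "A", alt = "G")))
  co$variants$feature <- "exonic"
  co$variants$genes <- c("GENE1", "GENE1", "GENE1", "GENE2",
                         "GENEB", "GENEB", "GENEA", "GENEA")
  r <- gene_mutation_ranking(co, top_n = 10)
  expect_equal(r$gene, c("GENE1", "GENEA", "GENEB", "GENE2"))
  expect_equal(r$count, c(3L, 2L, 2L, 1L))
  expect_equal(r$rank, 1:4)
  expect_equal(nrow(gene_mutation_ranking(co, top_n = 2)), 2L)
  expect_error(gene_mutation_ranking(co, top_n = 0), "configuration error")
  expect_error(gene_mutation_ranking(co, categories = "bogus"),
               "configuration error")
  # ranking equals a brute-force tally on the fixture cohort
  cof <- fx_full_annotated()
  r2 <- gene_mutation_ranking(cof, top_n = 5)
  s <- cof$samples$sample[1]
  vs <- cof$variants[cof$variants$sample == s &
                       cof$variants$feature %in%
                         c("exonic", "splicing", "UTR5", "UTR3"), ]
  tal <- sort(table(unlist(strsplit(vs$genes, ","))), decreasing = TRUE)
  top <- r2[r2$sample == s, ]
  expect_equal(stats::setNames(top$count, top$gene),
               stats::setNames(as.integer(tal[top$gene]), top$gene))
  expect_true(all(top$count >= max(tal[setdiff(names(tal), top$gene)])))
})

test_that("driver tallies count variants inside listed genes", {
  co <- mini_cohort(list(s1 = data.frame(chrom = "chr1", pos = 1:5,
                                         ref = "A", alt = "G")))
  co$variants$feature <- c("exonic", "intronic", "exonic", "upstream",
                           "intergenic")
  co$variants$genes <- c("DRV1", "DRV1", "OTHER", "DRV1", "DRV1")
  dt <- driver_gene_tally(co, c("DRV1", "DRV2"))
  # upstream/intergenic hits do not count as "in" the gene
  expect_equal(dt$per_gene$count[dt$per_gene$gene == "DRV1"], 2L)
  expect_equal(dt$totals$count, 2L)
  dt0 <- driver_gene_tally(co, "DRV2")
  expect_equal(nrow(dt0$per_gene), 0L)
  expect_equal(dt0$totals$count, 0L)
  expect_error(driver_gene_tally(co, character(0)), "configuration error")
})

test_that("every frequency table sums to one per contributing sample", {
  co <- fx_full_annotated()
  for (tab in list(substitution_spectrum(co, TRUE),
                   substitution_spectrum(co, FALSE),
                   feature_distribution(co))) {
    sums <- tapply(tab$frequency, tab$sample, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  ind <- indel_length_distribution(co)
  sums <- tapply(ind$frequency, paste(ind$sample, ind$indel_type), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
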