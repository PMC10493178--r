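write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf"),
                           samples = NULL) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           paste(cols, collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

test_that("a minimal VCF yields one classified SNV record", {
  p <- write_test_vcf("chr1\t100\t.\tA\tG\t.\tPASS\t.")
  v <- read_vcf(p, sample_label = "s1")
  expect_equal(nrow(v), 1L)
  expect_equal(v$chrom, "chr1")
  expect_equal(v$pos, 100L)
  expect_equal(v$vclass, "SNV")
  expect_equal(v$sample, "s1")
})

test_that("multi-allelic sites split and conserve allele count", {
  p <- write_test_vcf(c("chr1\t100\t.\tA\tG,T\t.\tPASS\t.",
                        "chr1\t200\t.\tC\tCA,CTT,G\t.\tPASS\t."))
  v <- read_vcf(p, sample_label = "s1")
  expect_equal(nrow(v), 5L)  # 2 + 3 ALT alleles
  expect_setequal(variant_key(v[v$pos == 100, ]),
                  c("chr1:100:A:G", "chr1:100:A:T"))
  expect_setequal(v$vclass[v$pos == 200], c("INSERTION", "INSERTION", "SNV"))
})

test_that("FILTER handling and symbolic ALT skipping", {
  p <- write_test_vcf(c("chr1\t100\t.\tA\tG\t.\tPASS\t.",
                        "chr1\t200\t.\tC\tT\t.\tlowqual\t.",
                        "chr1\t300\t.\tG\tA\t.\t.\t.",
                        "chr1\t400\t.\tT\t<DEL>\t.\tPASS\t."))
  v <- read_vcf(p, sample_label = "s1")
  expect_equal(v$pos, c(100L, 300L))  # '.' and PASS pass; lowqual dropped
  expect_equal(attr(v, "n_skipped_symbolic"), 1L)
  v_all <- read_vcf(p, sample_label = "s1", pass_only = FALSE)
  expect_equal(nrow(v_all), 3L)
  expect_false(all(v_all$filter_pass))
})

test_that("multi-sample VCFs attribute records to non-reference genotypes", {
  p <- write_test_vcf(
    c("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
      "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t1/1\t2/0"),
    samples = c("sampleA", "sampleB"))
  v <- read_vcf(p)
  expect_equal(v$sample[v$pos == 100], "sampleA")
  expect_setequal(variant_key(v[v$sample == "sampleB", ]), "chr1:200:C:G")
  expect_setequal(variant_key(v[v$sample == "sampleA", ]),
                  c("chr1:100:A:G", "chr1:200:C:T"))
})

test_that("missing or invalid header raises a format error naming line 1", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("chr1\t100\t.\tA\tG\t.\tPASS\t."), p)
  expect_error(read_vcf(p, "s1"), "line 1")
  expect_error(read_vcf(tempfile(), "s1"), "no such file")
})

test_that("records written back to VCF re-read with identical keys", {
  fx <- fx_small()
  cohort <- fx_small_cohort()
  dir <- tempfile("roundtrip")
  sizes <- unlist(fx$manifest$chromosomes)
  paths <- write_cohort_vcfs(cohort, dir, sizes)
  for (s in cohort$samples$sample) {
    orig <- cohort$variants[cohort$variants$sample == s, , drop = FALSE]
    back <- read_vcf(paths[[s]], sample_label = s)
    expect_setequal(variant_key(back), variant_key(orig))
  }
})

test_that("gzip-compressed VCFs read identically to plain ones", {
  p <- write_test_vcf(c("chr1\t100\t.\tA\tG\t.\tPASS\t.",
                        "chr1\t150\t.\tCA\tC\t.\tPASS\t."))
  pz <- paste0(p, ".gz")
  con <- gzfile(pz, "wb")
  writeLines(readLines(p), con)
  close(con)
  expect_equal(read_vcf(p, "s"), read_vcf(pz, "s"), ignore_attr = TRUE)
  expect_equal(variant_key(read_vcf(pz, "s")),
               variant_key(read_vcf(p, "s")))
})

test_that("cohort assembly validates its manifest", {
  fx <- fx_small()
  co <- assemble_cohort(fx$file_manifest)
  expect_s3_class(co, "variant_cohort")
  expect_equal(nrow(co$samples), 4L)
  expect_equal(unique(co$samples$group), c("grpA", "grpB"))
  expect_identical(co$samples$sample, fx$file_manifest$sample)
  bad <- fx$file_manifest
  bad$sample <- rep(bad$sample[1], nrow(bad))
  expect_error(assemble_cohort(bad), "configuration error")
  expect_error(assemble_cohort(fx$file_manifest[0, ]), "configuration error")
})

test_that("INFO fields are preserved verbatim and extractable", {
  p <- write_test_vcf("chr1\t100\t.\tA\tG\t.\tPASS\tFunc.refGene=exonic;Gene.refGene=GENE01;DP=10")
  v <- read_vcf(p, "s1")
  expect_match(v$info, "Func.refGene=exonic", fixed = TRUE)
  expect_equal(info_field(v, "Gene.refGene"), "GENE01")
  expect_equal(info_field(v, "DP"), "10")
  expect_true(is.na(info_field(v, "ABSENT")))
})
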