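write_test_vcf <- function(path, records,
                           samples = c("S1", "S2", "S3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"tranche\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}

ann_line <- function(chrom, pos, ref, alt, gene = "CHEK2",
                     region = "exonic", func = "nonsense",
                     maf = ".", pph2 = ".", rs = ".") {
  paste(chrom, pos, ref, alt, gene, region, func, maf, pph2, rs,
        sep = "\t")
}

write_test_annotation <- function(path, lines) {
  writeLines(c(paste("chrom", "pos", "ref", "alt", "gene", "region",
                     "func", "maf", "pph2_hdiv", "dbsnp_id", sep = "\t"),
               lines), path)
}

test_that("one het genotype among three samples yields exactly one call", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf, paste(
    "chr22", "100", ".", "C", "T", "50", "PASS", ".", "GT:AD:DP",
    "0/1:30,20:50", "0/0:40,0:40", "0/0:35,0:35", sep = "\t"))
  write_test_annotation(ann, ann_line("chr22", 100, "C", "T"))
  gm <- c(S1 = "case", S2 = "control", S3 = "control")
  ct <- import_vcf(vcf, ann, gm)
  expect_equal(n_calls(ct), 1L)
  expect_equal(ct$calls$sample_id, "S1")
  expect_equal(ct$calls$depth, 50L)
  expect_equal(ct$calls$alt_reads, 20L)
  expect_true(ct$calls$vqslod_pass)
  expect_equal(ct$calls$gene, "CHEK2")
})

test_that("multiallelic genotypes split into one biallelic call per carried alt", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf, paste(
    "chr1", "500", ".", "A", "C,T", "50", "PASS", ".", "GT:AD:DP",
    "1/2:5,20,25:50", "0/1:30,20:50", "0|0:40,0,0:40", sep = "\t"))
  write_test_annotation(ann, c(ann_line("chr1", 500, "A", "C"),
                               ann_line("chr1", 500, "A", "T",
                                        func = "missense", pph2 = "0.99")))
  gm <- c(S1 = "case", S2 = "control", S3 = "control")
  ct <- import_vcf(vcf, ann, gm)
  expect_equal(n_calls(ct), 3L)
  s1 <- ct$calls[ct$calls$sample_id == "S1", ]
  expect_setequal(s1$alt, c("C", "T"))
  expect_equal(s1$alt_reads[s1$alt == "C"], 20L)
  expect_equal(s1$alt_reads[s1$alt == "T"], 25L)
  expect_equal(s1$pph2_hdiv[s1$alt == "T"], 0.99)
})

test_that("VQSR tranche FILTER labels fail the vqslod flag", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf, paste(
    "chr2", "300", ".", "G", "A", "50",
    "VQSRTrancheSNP99.90to100.00", ".", "GT:AD:DP",
    "0/1:25,25:50", "0/0:40,0:40", "0/0:30,0:30", sep = "\t"))
  write_test_annotation(ann, ann_line("chr2", 300, "G", "A"))
  gm <- c(S1 = "case", S2 = "control", S3 = "control")
  ct <- import_vcf(vcf, ann, gm)
  expect_false(ct$calls$vqslod_pass)
})

test_that("unannotated variants import as func=other with a warning", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf, paste(
    "chr3", "700", ".", "T", "G", "50", "PASS", ".", "GT:AD:DP",
    "0/1:20,20:40", "0/0:40,0:40", "0/0:30,0:30", sep = "\t"))
  write_test_annotation(ann, ann_line("chr9", 1, "A", "T"))
  gm <- c(S1 = "case", S2 = "control", S3 = "control")
  expect_warning(ct <- import_vcf(vcf, ann, gm), "no annotation")
  expect_equal(ct$calls$func, "other")
  expect_true(is.na(ct$calls$gene))
})

test_that("a sample missing from the group map is an error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf, paste(
    "chr3", "700", ".", "T", "G", "50", "PASS", ".", "GT:AD:DP",
    "0/1:20,20:40", "0/0:40,0:40", "0/0:30,0:30", sep = "\t"))
  write_test_annotation(ann, ann_line("chr3", 700, "T", "G"))
  expect_error(import_vcf(vcf, ann, c(S1 = "case", S2 = "control")),
               "S3")
})

test_that("import emits one call per non-reference genotype allele (recount oracle)", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  set.seed(13)
  gts <- c("0/0", "0/1", "1/1", "1/2", "0/2", "./.")
  recs <- character(10)
  anns <- character(0)
  expected <- 0L
  for (i in 1:10) {
    g <- sample(gts, 3, replace = TRUE)
    recs[i] <- paste("chr1", 1000 + i, ".", "A", "C,T", "50", "PASS",
                     ".", "GT:AD:DP",
                     paste0(g[1], ":10,10,10:30"),
                     paste0(g[2], ":10,10,10:30"),
                     paste0(g[3], ":10,10,10:30"), sep = "\t")
    anns <- c(anns, ann_line("chr1", 1000 + i, "A", "C"),
              ann_line("chr1", 1000 + i, "A", "T"))
    # brute-force: count distinct non-reference alleles per genotype
    expected <- expected + sum(vapply(g, function(s) {
      a <- suppressWarnings(as.integer(strsplit(s, "/")[[1]]))
      length(unique(a[!is.na(a) & a > 0]))
    }, integer(1)))
  }
  write_test_vcf(vcf, recs)
  write_test_annotation(ann, anns)
  gm <- c(S1 = "case", S2 = "control", S3 = "control")
  ct <- import_vcf(vcf, ann, gm)
  expect_equal(n_calls(ct), expected)
})
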