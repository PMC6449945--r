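test_that("locate_region classifies exon, splice window, intron, intergenic", {
  exons <- data.frame(chrom = "chr1",
                      start = c(99L, 299L), end = c(200L, 400L))
  # exon [99,200) covers 1-based 100..200
  expect_equal(locate_region("chr1", 100L, exons), "exonic")
  expect_equal(locate_region("chr1", 200L, exons), "exonic")
  expect_equal(locate_region("chr1", 202L, exons), "splice_site")
  expect_equal(locate_region("chr1", 203L, exons), "intronic")
  expect_equal(locate_region("chr1", 98L, exons), "splice_site")
  expect_equal(locate_region("chr1", 97L, exons), "intergenic")
  expect_equal(locate_region("chr2", 100L, exons), "intergenic")
  # window 0 removes the splice class entirely
  expect_equal(locate_region("chr1", 202L, exons, window = 0L),
               "intronic")
})

test_that("stage-1 thresholds reject at the published bounds", {
  cfg <- filter_config()
  reg <- two_group_registry()
  run1 <- function(call) stage1_filter(cohort_table(call, reg), cfg)

  r <- run1(clean_call(depth = 9L, alt_reads = 4L))
  expect_equal(r$report$rejections[["depth"]], 1L)
  expect_equal(r$report$retained, 0L)
  # boundary: 10 reads retained
  expect_equal(run1(clean_call(depth = 10L, alt_reads = 4L))$report$retained,
               1L)
  r <- run1(clean_call(depth = 100L, alt_reads = 15L))
  expect_equal(r$report$rejections[["vaf"]], 1L)
  # VAF bounds inclusive
  expect_equal(run1(clean_call(depth = 100L, alt_reads = 20L))$report$retained,
               1L)
  expect_equal(run1(clean_call(depth = 100L, alt_reads = 80L))$report$retained,
               1L)
  r <- run1(clean_call(maf = "exac:0.02"))
  expect_equal(r$report$rejections[["maf"]], 1L)
  # <= 1% in every database passes; any one above rejects
  expect_equal(run1(clean_call(maf = "exac:0.01;gonl:0.002"))$report$retained,
               1L)
  expect_equal(run1(clean_call(maf = "exac:0.002;gonl:0.02"))$report$rejections[["maf"]],
               1L)
  expect_equal(run1(clean_call())$report$retained, 1L)
  r <- run1(clean_call(vqslod_pass = FALSE))
  expect_equal(r$report$rejections[["vqslod"]], 1L)
  r <- run1(clean_call(region = "intronic"))
  expect_equal(r$report$rejections[["region"]], 1L)
})

test_that("rejections attribute to the first failing filter and conserve counts", {
  # fails vqslod AND depth AND maf -> attributed to vqslod only
  ct <- cohort_table(clean_call(vqslod_pass = FALSE, depth = 5L,
                                alt_reads = 2L, maf = "exac:0.3"),
                     two_group_registry())
  r <- stage1_filter(ct, filter_config())
  expect_equal(r$report$rejections[["vqslod"]], 1L)
  expect_equal(sum(r$report$rejections), 1L)

  for (seed in 1:3) {
    ct <- random_cohort(n_calls = 150, seed = seed)
    r <- stage1_filter(ct, filter_config())
    expect_equal(r$report$input,
                 r$report$retained + sum(r$report$rejections))
  }
})

test_that("stage-1 filter matches a brute-force retention oracle and is idempotent and monotone", {
  cfg <- filter_config()
  for (seed in 1:3) {
    ct <- random_cohort(n_calls = 200, seed = seed)
    r <- stage1_filter(ct, cfg)
    keep <- stage1_oracle_keep(ct$calls, cfg)
    expect_equal(r$retained$calls, ct$calls[keep, ],
                 ignore_attr = "row.names")
    # idempotent
    r2 <- stage1_filter(r$retained, cfg)
    expect_equal(r2$retained$calls, r$retained$calls)
    expect_equal(sum(r2$report$rejections), 0L)
    # tightening any threshold never enlarges the retained set
    tighter <- list(filter_config(min_depth = 20),
                    filter_config(min_alt_reads = 5),
                    filter_config(vaf_min = 0.3, vaf_max = 0.7),
                    filter_config(max_maf = 0.001))
    keys_base <- paste(r$retained$calls$sample_id, r$retained$calls$pos)
    for (tc in tighter) {
      kt <- stage1_filter(ct, tc)$retained$calls
      expect_true(all(paste(kt$sample_id, kt$pos) %in% keys_base))
    }
  }
})

test_that("cohort-recurrence removal needs both groups above threshold", {
  cases <- sprintf("BC%03d", 1:54)
  controls <- sprintf("CT%03d", 1:120)
  reg <- two_group_registry(cases, controls)
  shared_var <- function(carriers, pos)
    do.call(rbind, lapply(carriers, function(s)
      clean_call(sample_id = s, pos = pos)))
  # 7/54 cases (13.0%) and 13/120 controls (10.8%): removed
  # 11/54 cases (20.4%) and 6/120 controls (5.0%): retained
  calls <- rbind(shared_var(c(cases[1:7], controls[1:13]), 500L),
                 shared_var(c(cases[1:11], controls[1:6]), 900L))
  ct <- cohort_table(calls, reg)
  res <- cohort_recurrence_filter(ct, 0.10)
  expect_equal(res$removed$variant, "chr1:500:A:T")
  expect_equal(res$n_removed_calls, 20L)
  expect_equal(n_calls(res$retained), 17L)
  # threshold 1.0 removes nothing
  expect_equal(nrow(cohort_recurrence_filter(ct, 1.0)$removed), 0)
})

test_that("cohort-recurrence removal is symmetric under group-label swap", {
  ct <- random_cohort(n_calls = 300, n_cases = 10, n_controls = 10,
                      seed = 42)
  swapped <- ct
  swapped$samples$group <- ifelse(swapped$samples$group == "case",
                                  "control", "case")
  a <- cohort_recurrence_filter(ct, 0.10)
  b <- cohort_recurrence_filter(swapped, 0.10)
  expect_setequal(a$removed$variant, b$removed$variant)
})

test_that("missense triage follows the HDIV class boundaries", {
  cfg <- filter_config()
  expect_equal(classify_missense(0.957, cfg), "missense_probably")
  expect_equal(classify_missense(0.99, cfg), "missense_probably")
  expect_equal(classify_missense(0.40, cfg), "missense_benign")
  expect_equal(classify_missense(0.452, cfg), "missense_benign")
  expect_equal(classify_missense(0.453, cfg), "missense_possibly")
  expect_equal(classify_missense(0.956, cfg), "missense_possibly")
  # the printed class bounds leave open gaps -> middle class
  expect_equal(classify_missense(0.9565, cfg), "missense_possibly")
  expect_equal(classify_missense(0.4525, cfg), "missense_possibly")
  expect_equal(classify_missense(NA_real_, cfg), "missense_unscored")
  expect_error(classify_missense(1.2, cfg), "outside")
})

test_that("categorize applies severity precedence and is total", {
  reg <- two_group_registry()
  cat1 <- function(call)
    categorize(cohort_table(call, reg))$calls$category
  expect_equal(cat1(clean_call(func = "nonsense")), "nonsense")
  expect_equal(cat1(clean_call(func = "other", region = "splice_site")),
               "splice_site")
  # splice-site region never downgrades a truncating annotation
  expect_equal(cat1(clean_call(func = "frameshift_indel", ref = "AT",
                               region = "splice_site")),
               "frameshift_indel")
  expect_equal(cat1(clean_call(func = "missense", pph2_hdiv = 0.99)),
               "missense_probably")
  expect_equal(cat1(clean_call(func = "missense")), "missense_unscored")
  expect_equal(cat1(clean_call(func = "synonymous")), "synonymous")

  ct <- categorize(random_cohort(400, seed = 9))
  expect_true(all(ct$calls$category %in% CATEGORIES))
  # deterministic
  expect_identical(ct$calls$category,
                   categorize(random_cohort(400, seed = 9))$calls$category)
})

test_that("panel restriction keeps panel genes and coordinate hits only", {
  panel <- gene_panel(data.frame(gene = "CHEK2", chrom = "chr22",
                                 start = 100L, end = 200L,
                                 sources = "Wood"))
  reg <- two_group_registry()
  ct <- cohort_table(rbind(
    clean_call(gene = "CHEK2"),
    clean_call(gene = "OTHER", pos = 2000L),
    clean_call(gene = NA_character_, chrom = "chr22", pos = 150L),
    clean_call(gene = NA_character_, chrom = "chr22", pos = 5000L)), reg)
  kept <- restrict_to_panel(ct, panel)
  expect_equal(n_calls(kept), 2L)
  expect_setequal(kept$calls$pos, c(1000L, 150L))
})

test_that("extract_pdavs groups carriers per variant and flags novelty", {
  reg <- two_group_registry(cases = c("S1", "S3"), controls = "S2")
  ct <- categorize(cohort_table(rbind(
    clean_call(func = "nonsense", dbsnp_id = "rs1"),
    clean_call(sample_id = "S3", func = "frameshift_indel", ref = "AT",
               pos = 2000L),
    clean_call(sample_id = "S1", func = "frameshift_indel", ref = "AT",
               pos = 2000L),
    clean_call(sample_id = "S2", func = "frameshift_indel", ref = "AT",
               pos = 2000L),
    clean_call(sample_id = "S2", func = "synonymous", pos = 3000L),
    clean_call(sample_id = "S1", func = "stop_loss", pos = 4000L)), reg))
  pd <- extract_pdavs(ct)
  expect_equal(nrow(pd), 3)
  fs <- pd[pd$category == "frameshift_indel", ]
  expect_equal(fs$n_case_carriers, 2L)
  expect_equal(fs$n_control_carriers, 1L)
  expect_equal(fs$carriers_case, "S1;S3")
  expect_false(pd$is_novel[pd$category == "nonsense"])
  expect_true(pd$is_novel[pd$category == "frameshift_indel"])
  # stop-loss excluded under the strict definition
  expect_equal(nrow(extract_pdavs(ct, include_stop_loss = FALSE)), 2)
  expect_error(extract_pdavs(cohort_table(clean_call(), reg)),
               "categorise")
})
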