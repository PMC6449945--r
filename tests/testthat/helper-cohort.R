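# Fixture builders used across the suite. All randomness is locally
# seeded so every test is reproducible in isolation.

random_calls <- function(n, samples, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  func <- sample(FUNCS, n, replace = TRUE)
  region <- sample(REGIONS, n, replace = TRUE)
  depth <- sample(0:150, n, replace = TRUE)
  alt_reads <- vapply(depth, function(d) sample(0:d, 1), 0L)
  maf <- ifelse(runif(n) < 0.4,
                sprintf("exac:%.4f;gonl:%.4f", runif(n, 0, 0.05),
                        runif(n, 0, 0.05)),
                NA_character_)
  data.frame(sample_id = sample(samples, n, replace = TRUE),
             chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
             pos = sample.int(1e6, n),   # unique => unique tuples
             ref = ref, alt = alt,
             gene = ifelse(runif(n) < 0.9,
                           sample(c("CHEK2", "PALB2", "BRCA1", "XYZ1",
                                    "XYZ2"), n, replace = TRUE),
                           NA_character_),
             region = region, func = func,
             depth = depth, alt_reads = alt_reads,
             vqslod_pass = runif(n) < 0.9,
             maf = maf,
             pph2_hdiv = ifelse(func == "missense" & runif(n) < 0.8,
                                runif(n), NA_real_),
             dbsnp_id = ifelse(runif(n) < 0.5,
                               sprintf("rs%06d", sample.int(1e6, n)),
                               NA_character_),
             stringsAsFactors = FALSE)
}

random_cohort <- function(n_calls = 100, n_cases = 4, n_controls = 6,
                          seed = 1) {
  ids <- c(sprintf("CA%02d", seq_len(n_cases)),
           sprintf("CO%02d", seq_len(n_controls)))
  grp <- rep(c("case", "control"), c(n_cases, n_controls))
  cohort_table(random_calls(n_calls, ids, seed = seed),
               data.frame(sample_id = ids, group = grp))
}

# one fully passing call; fields overridable
clean_call <- function(...) {
  base <- list(sample_id = "S1", chrom = "chr1", pos = 1000L, ref = "A",
               alt = "T", gene = "CHEK2", region = "exonic",
               func = "nonsense", depth = 50L, alt_reads = 25L,
               vqslod_pass = TRUE, maf = NA_character_,
               pph2_hdiv = NA_real_, dbsnp_id = NA_character_)
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

two_group_registry <- function(cases = "S1", controls = "S2") {
  data.frame(sample_id = c(cases, controls),
             group = rep(c("case", "control"),
                         c(length(cases), length(controls))))
}

# literal re-evaluation of the stage-1 retention predicate, written
# independently of the package internals (per-call loop, scalar logic)
stage1_oracle_keep <- function(calls, cfg) {
  vapply(seq_len(nrow(calls)), function(i) {
    row <- calls[i, ]
    if (!row$vqslod_pass) return(FALSE)
    if (!(row$region == "exonic" || row$region == "splice_site"))
      return(FALSE)
    if (row$depth < cfg$min_depth) return(FALSE)
    if (row$alt_reads < cfg$min_alt_reads) return(FALSE)
    vaf <- row$alt_reads / row$depth
    if (!(vaf >= cfg$vaf_min && vaf <= cfg$vaf_max)) return(FALSE)
    m <- 0
    if (!is.na(row$maf)) {
      for (part in strsplit(row$maf, ";")[[1]])
        m <- max(m, as.numeric(strsplit(part, ":")[[1]][2]))
    }
    m <= cfg$max_maf
  }, logical(1))
}
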