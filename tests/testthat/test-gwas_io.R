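test_that("summary_table enforces record invariants with per-reason warnings", {
  df <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs1"),
    chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
    effect_allele = c("a", "C", "G", "AT", "A"),
    other_allele = c("g", "T", "G", "C", "G"),
    eaf = c(0.2, 1.4, 0.3, 0.3, 0.3),
    beta = 0.1, se = c(0.01, 0.01, 0.01, 0.01, 0.01),
    pval = c(1e-9, 1e-9, 1e-9, 1e-9, 1e-9), n = 1000)
  expect_warning(st <- summary_table(df), "dropped 4 invalid row")
  # rs1 survives (alleles upper-cased); rs2 bad eaf, rs3 identical alleles,
  # rs4 indel, duplicate rs1 dropped
  expect_equal(st$snp_id, "rs1")
  expect_equal(st$effect_allele, "A")
})

test_that("rows with se = 0 are dropped and the rest returned", {
  df <- data.frame(snp_id = c("a", "b", "c"), chrom = "1", pos = 1:3,
                   effect_allele = "A", other_allele = "G", eaf = 0.5,
                   beta = 0.1, se = c(0.01, 0, 0.02), pval = 0.5, n = 10)
  expect_warning(st <- summary_table(df), "se <= 0")
  expect_equal(nrow(st), 2L)
  expect_setequal(st$snp_id, c("a", "c"))
})

test_that("write/read round trip is the identity on valid tables", {
  st <- make_st(c("rs1", "rs2", "rs3"), pos = c(11L, 22L, 33L),
                beta = c(0.123456789012345, -1e-7, 3.3),
                se = c(0.01, 2e-8, 0.5),
                pval = c(1e-300, 0.5, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(st, path)
  back <- read_summary_tsv(path, trait_label = "LDL")
  expect_equal(as.data.frame(back), as.data.frame(st))

  empty <- st[0, , drop = FALSE]
  class(empty) <- class(st)
  write_summary_tsv(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
})

test_that("LD matrices round-trip through the tab-separated format", {
  ids <- c("rs1", "rs2", "rs3")
  ld <- diag(1, 3); dimnames(ld) <- list(ids, ids)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.25
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_tsv(ld, path)
  expect_equal(read_ld_tsv(path), ld)
  asym <- ld; asym["rs1", "rs3"] <- 0.5
  write_ld_tsv(asym, path)
  expect_error(read_ld_tsv(path), "symmetric")
})

test_that("cis windows export as 0-based half-open BED records", {
  tg <- make_target(start = 1000000L, end = 1050000L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_cis_bed(tg, path, window_bp = 100000L)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 900000 - 1)
  expect_equal(bed$V3, 1150000)
})

test_that("read_summary_tsv maps columns and reports missing ones", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = "rs1", chrom = "2", bp = 10L, A1 = "A", A2 = "G",
                   freq = 0.2, b = 0.3, SE = 0.05, p = 1e-9, N = 100)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_summary_tsv(path, column_map = c(
    snp_id = "rsid", pos = "bp", effect_allele = "A1", other_allele = "A2",
    eaf = "freq", beta = "b", se = "SE", pval = "p", n = "N"))
  expect_equal(st$snp_id, "rs1")
  expect_equal(st$beta, 0.3)
  expect_error(read_summary_tsv(path, column_map = c(snp_id = "nope")),
               "absent column")
  expect_error(read_summary_tsv(path), "missing required column")
})

test_that("harmonize aligns, flips, and drops per the stated rules", {
  ex <- make_st(c("s1", "s2", "s3", "s4", "s5"), pos = 1:5,
                beta = 0.1, se = 0.01, pval = 1e-9,
                effect_allele = c("A", "A", "A", "A", "A"),
                other_allele = c("G", "G", "T", "T", "G"),
                eaf = c(0.3, 0.3, 0.49, 0.2, 0.3))
  ou <- make_st(c("s1", "s2", "s3", "s4", "s5", "s6"), pos = 1:6,
                beta = 0.05, se = 0.01, pval = 0.5,
                effect_allele = c("A", "G", "A", "T", "A"),
                other_allele = c("G", "A", "T", "A", "C"),
                eaf = c(0.31, 0.72, 0.5, 0.81, 0.3))
  h <- harmonize(ex, ou, palindrome_eaf_window = 0.08)
  expect_equal(nrow(h), 5L)  # s6 absent from exposure -> omitted
  rownames(h) <- h$snp_id
  expect_equal(h["s1", "action"], "kept")
  expect_equal(h["s1", "beta_outcome"], 0.05)
  expect_equal(h["s2", "action"], "flipped")
  expect_equal(h["s2", "beta_outcome"], -0.05)
  expect_equal(h["s3", "action"], "dropped_palindromic")  # eaf 0.49 in window
  # s4: palindromic, eaf 0.2 vs outcome 0.81 -> opposite sides, flipped
  expect_equal(h["s4", "action"], "flipped")
  expect_equal(h["s4", "beta_outcome"], -0.05)
  expect_equal(h["s5", "action"], "dropped_mismatch")  # A/G vs A/C irreconcilable
})

test_that("strand complements are resolved before declaring a mismatch", {
  ex <- make_st("s1", pos = 1L, beta = 0.1, se = 0.01, pval = 1e-9,
                effect_allele = "A", other_allele = "G")
  # outcome stored on the other strand: T/C == complement of A/G
  ou <- make_st("s1", pos = 1L, beta = 0.05, se = 0.01, pval = 0.5,
                effect_allele = "T", other_allele = "C")
  h <- harmonize(ex, ou)
  expect_equal(h$action, "kept")
  expect_equal(h$beta_outcome, 0.05)
  # complement-swapped: C/T -> flipped
  ou2 <- make_st("s1", pos = 1L, beta = 0.05, se = 0.01, pval = 0.5,
                 effect_allele = "C", other_allele = "T")
  h2 <- harmonize(ex, ou2)
  expect_equal(h2$action, "flipped")
  expect_equal(h2$beta_outcome, -0.05)
  # truly irreconcilable allele set
  ou3 <- make_st("s1", pos = 1L, beta = 0.05, se = 0.01, pval = 0.5,
                 effect_allele = "A", other_allele = "C")
  expect_equal(harmonize(ex, ou3)$action, "dropped_mismatch")
})

test_that("harmonization is idempotent and downstream-invariant to outcome orientation", {
  set.seed(11)
  sim <- simulate_target(make_target(), sim_config(j_snps = 10L))
  h1 <- kept_pairs(harmonize(sim$exposure, sim$control))
  # rebuild an outcome table already in exposure orientation from h1
  ex <- as.data.frame(sim$exposure)
  idx <- match(h1$snp_id, ex$snp_id)
  aligned <- ex[idx, ]
  aligned$beta <- h1$beta_outcome
  aligned$se <- h1$se_outcome
  aligned$pval <- pmax(2 * pnorm(-abs(aligned$beta) / aligned$se),
                       .Machine$double.xmin)
  aligned_st <- summary_table(aligned)
  h2 <- harmonize(sim$exposure, aligned_st)
  h2 <- h2[match(h1$snp_id, h2$snp_id), ]
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)

  # flipping every outcome allele label (and beta, eaf) changes nothing kept
  flipped <- as.data.frame(sim$control)
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h3 <- kept_pairs(harmonize(sim$exposure, summary_table(flipped)))
  h3 <- h3[match(h1$snp_id, h3$snp_id), ]
  expect_equal(h3$beta_outcome, h1$beta_outcome)
  expect_equal(suppressWarnings(ivw(h3)$beta), suppressWarnings(ivw(h1)$beta))
})
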