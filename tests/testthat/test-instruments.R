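test_that("cis selection applies inclusive boundaries and a strict p threshold", {
  tg <- make_target(start = 1000000L, end = 1050000L)
  st <- make_st(c("edge_lo", "inside", "edge_hi", "out_lo", "out_hi",
                  "weak", "wrong_chr"),
                pos = c(900000L, 1020000L, 1150000L, 899999L, 1150001L,
                        1020001L, 1020000L),
                beta = 0.1, se = 0.01,
                pval = c(1e-12, 1e-12, 1e-12, 1e-12, 1e-12, 6e-8, 1e-12),
                chrom = c("1", "1", "1", "1", "1", "1", "2"))
  sel <- select_cis_snps(st, tg, window_bp = 100000L, p_threshold = 5e-8)
  expect_setequal(sel$snp_id, c("edge_lo", "inside", "edge_hi"))
  # monotone in window_bp, anti-monotone in p_threshold (nested sets)
  wider <- select_cis_snps(st, tg, window_bp = 200001L)
  expect_true(all(sel$snp_id %in% wider$snp_id))
  looser <- select_cis_snps(st, tg, p_threshold = 1e-7)
  expect_true(all(sel$snp_id %in% looser$snp_id))
  stricter <- select_cis_snps(st, tg, p_threshold = 1e-13)
  expect_true(all(stricter$snp_id %in% sel$snp_id))
  expect_equal(nrow(stricter), 0L)
})

test_that("greedy clumping keeps the best SNP per clump", {
  ids <- c("A", "B", "C")
  st <- make_st(ids, pos = c(10L, 20L, 30L), beta = 0.1, se = 0.01,
                pval = c(1e-10, 1e-9, 1e-8))
  ld <- diag(1, 3); dimnames(ld) <- list(ids, ids)
  ld["A", "B"] <- ld["B", "A"] <- 0.5
  expect_equal(ld_clump(st, ld, r2_threshold = 0.001)$snp_id, c("A", "C"))

  # all independent -> everything retained
  ld0 <- diag(1, 3); dimnames(ld0) <- list(ids, ids)
  expect_equal(nrow(ld_clump(st, ld0)), 3L)

  # perfect LD -> only the smaller-p SNP survives
  ld1 <- matrix(1, 2, 2); dimnames(ld1) <- list(ids[1:2], ids[1:2])
  st2 <- st[1:2, ]; class(st2) <- class(st)
  expect_equal(ld_clump(st2, ld1)$snp_id, "A")

  expect_error(ld_clump(st, ld0[1:2, 1:2]), "absent from LD matrix.*C")
})

test_that("clumping matches the independent oracle on random instances", {
  set.seed(202)
  for (rep in 1:100) {
    inst <- random_clump_instance(sample(2:12, 1))
    got <- ld_clump(inst$st, inst$ld, inst$thr)$snp_id
    expect_equal(got, clump_oracle(inst$st, inst$ld, inst$thr))
    # retained pairwise independent; every discarded SNP is linked to a
    # retained better-ranked SNP
    if (length(got) > 1) {
      expect_true(all(inst$ld[got, got][upper.tri(diag(length(got)))] <
                        inst$thr))
    }
    dropped <- setdiff(inst$st$snp_id, got)
    for (d in dropped) {
      expect_true(any(inst$ld[d, got] >= inst$thr))
    }
  }
})

test_that("F statistics use the squared Wald z and flag weak sets", {
  st <- make_st(c("a", "b"), pos = 1:2, beta = c(0.1, 0.03),
                se = c(0.02, 0.01), pval = 1e-9)
  fs <- f_statistics(st)
  expect_equal(fs$f_per_snp, c(25, 9))
  expect_equal(fs$mean_f, 17)
  expect_false(fs$weak_instruments)
  weak <- f_statistics(st[2, ])
  expect_equal(weak$mean_f, 9)
  expect_true(weak$weak_instruments)
  expect_error(f_statistics(st[0, ]), "no instruments")
  # any set with every per-SNP F > 10 has mean F > 10
  set.seed(5)
  for (i in 1:20) {
    z <- sqrt(runif(8, 10.01, 400))
    stz <- make_st(sprintf("s%d", 1:8), pos = 1:8, beta = z * 0.01,
                   se = 0.01, pval = 1e-9)
    expect_gt(f_statistics(stz)$mean_f, 10)
  }
})

test_that("r2-based F is available as an alternative", {
  st <- make_st("a", pos = 1L, beta = 0.1, se = 0.02, pval = 1e-9,
                eaf = 0.25, n = 50000)
  r2 <- 2 * 0.25 * 0.75 * 0.1^2
  expect_equal(f_statistics(st, method = "r2")$f_per_snp,
               r2 * (50000 - 2) / (1 - r2))
})

test_that("instrument building recovers planted counts through all stages", {
  tg <- make_target()
  cfg <- sim_config(j_snps = 12L)
  sim <- simulate_target(tg, cfg, seed = 99)
  is1 <- build_instrument_set(sim$exposure, sim$control, tg, sim$ld)
  expect_equal(is1$n_snps, 12L)
  expect_true(all(is1$pairs$snp_id %in% sim$truth$planted_ids))
  expect_equal(unname(is1$log["n_cis"]), 12L)
  expect_gt(is1$mean_f, 10)

  # two of the twelve in perfect LD -> one clumped away
  cfg2 <- sim_config(j_snps = 12L, n_ld_pairs = 1L, ld_pair_r2 = 1)
  sim2 <- simulate_target(tg, cfg2, seed = 99)
  is2 <- build_instrument_set(sim2$exposure, sim2$control, tg, sim2$ld)
  expect_equal(is2$n_snps, 11L)

  # no significant SNP near the target -> empty set, not an error
  cfg3 <- sim_config(j_snps = 0L, n_decoys = 10L)
  sim3 <- simulate_target(tg, cfg3, seed = 99)
  is3 <- build_instrument_set(sim3$exposure, sim3$control, tg, sim3$ld)
  expect_equal(is3$n_snps, 0L)
  expect_true(is.na(is3$mean_f))
})
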