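test_that("Cochran's Q matches the hand computation on the worked example", {
  q <- cochran_q(example_pairs_3snp())
  expect_equal(q$q, 2.0)
  expect_equal(q$df, 2L)
  expect_equal(q$pval, exp(-1))  # chi-square(2) survival at 2
  expect_equal(q$i2, 0)
})

test_that("Q is permutation-invariant, zero iff ratios equal, and i2 matches its closed form", {
  set.seed(44)
  p <- simulate_instruments(12, theta = 0.3)
  q1 <- cochran_q(p)
  q2 <- cochran_q(p[sample(12), ])
  expect_equal(q1$q, q2$q)

  same <- make_pairs(bx = c(0.1, 0.2, 0.4), by = 0.3 * c(0.1, 0.2, 0.4),
                     sy = c(0.01, 0.02, 0.03))
  qs <- cochran_q(same)
  expect_equal(qs$q, 0)
  expect_equal(qs$i2, 0)
  expect_equal(qs$pval, 1)

  for (i in 1:20) {
    pp <- simulate_instruments(sample(3:15, 1), theta = runif(1, -0.5, 0.5))
    qq <- cochran_q(pp)
    expect_equal(qq$i2,
                 if (qq$q > 0) max(0, (qq$q - qq$df) / qq$q) * 100 else 0)
    expect_true(qq$i2 >= 0 && qq$i2 <= 100)
  }
  expect_error(cochran_q(p[1, ]), "at least 2")
})

test_that("Egger intercept test recovers an exact intercept and flags significance", {
  p <- make_pairs(bx = c(0.1, 0.2, 0.4), by = 0.02 + 0.5 * c(0.1, 0.2, 0.4),
                  sy = rep(0.01, 3))
  r <- egger_intercept_test(p)
  expect_equal(r$beta, 0.02)
  expect_error(egger_intercept_test(p[1:2, ]), "at least 3")
})

test_that("MR-PRESSO enforces its minimum instrument count and is seed-reproducible", {
  p <- simulate_instruments(10, theta = 0.3, seed = 5)
  expect_error(mr_presso(p[1:3, ], n_sim = 100), "at least 4")
  expect_error(mr_presso(p, n_sim = 50), "at least 100")
  a <- mr_presso(p, n_sim = 200, seed = 9)
  b <- mr_presso(p, n_sim = 200, seed = 9)
  expect_identical(a, b)
  expect_gt(a$global_pval, 0.05)  # homogeneous set: no pleiotropy signal
  expect_equal(length(a$outliers), 0L)
  expect_true(is.na(a$beta_corrected))
})

test_that("MR-PRESSO localizes a planted outlier and corrects the estimate", {
  p <- simulate_instruments(20, theta = 0.3, n_outliers = 1,
                            outlier_offset = 10, seed = 314)
  truth <- attr(p, "truth")
  res <- mr_presso(p, n_sim = 500, seed = 314)
  expect_lt(res$global_pval, 0.05)
  expect_true(truth$outlier_ids %in% res$outliers)
  expect_false(is.na(res$beta_corrected))
  expect_lt(abs(res$beta_corrected - 0.3), abs(res$beta_raw - 0.3))
  expect_false(is.na(res$distortion_pval))
})

test_that("leave-one-out reduces to the other SNP's ratio at J = 2 and flags dominance", {
  p2 <- example_pairs_3snp()[1:2, ]
  loo2 <- leave_one_out(p2)
  wr <- wald_ratio(p2)
  expect_equal(loo2$loo$beta_without, rev(wr$theta))
  expect_equal(loo2$loo$se_without, rev(wr$se_theta))
  expect_error(leave_one_out(p2[1, ]), "at least 2")

  # homogeneous set: all estimates near the full estimate, robust
  set.seed(21)
  p <- simulate_instruments(15, theta = 0.3)
  loo <- leave_one_out(p)
  full <- ivw(p)
  expect_true(loo$robust)
  expect_true(all(abs(loo$loo$beta_without - full$beta) < 2 * full$se))

  # LOO estimates weighted by their leave-out precision average back to the
  # full IVW point estimate: sum_j (S_w - w_j) beta_(-j) = (J - 1) S_w beta
  w <- (p$beta_exposure / p$se_outcome)^2
  sw <- sum(w)
  expect_equal(sum((sw - w) * loo$loo$beta_without) / ((length(w) - 1) * sw),
               full$beta)

  # a dominant outlier moves the estimate most when removed
  pout <- simulate_instruments(20, theta = 0.3, n_outliers = 1,
                               outlier_offset = 10, seed = 314)
  truth <- attr(pout, "truth")
  looo <- leave_one_out(pout)
  shift <- abs(looo$loo$beta_without - looo$all_snp_beta)
  expect_equal(looo$loo$snp_id[which.max(shift)], truth$outlier_ids)
})

test_that("funnel data pair ratios with precisions and are IVW-consistent", {
  f <- funnel_data(example_pairs_3snp())
  expect_equal(f$theta, c(0.5, 0.4, 0.6))
  expect_equal(f$precision, rep(10, 3))
  expect_equal(sum(f$theta * f$precision^2) / sum(f$precision^2),
               ivw(example_pairs_3snp(), mode = "fixed")$beta)
  one <- funnel_data(example_pairs_3snp()[1, ])
  expect_equal(nrow(one), 1L)
})

test_that("sensitivity_report assembles the battery and degrades gracefully", {
  p <- simulate_instruments(10, theta = 0.3, seed = 62)
  rep <- sensitivity_report(p, n_sim = 200, seed = 2)
  s <- rep$summary
  expect_equal(s$n_snps, 10L)
  expect_false(is.na(s$q_pval))
  expect_false(is.na(s$egger_intercept_p))
  expect_false(is.na(s$presso_global_p))
  expect_true(s$loo_robust)

  small <- sensitivity_report(p[1:3, ], n_sim = 200, seed = 2)
  expect_true(is.na(small$summary$presso_global_p))  # J < 4
  expect_false(is.na(small$summary$egger_intercept))
})
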