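test_that("inverse-variance pooling matches hand-computed weighted means", {
  one <- ivw_meta(0.1, 0.05)
  expect_equal(one$beta, 0.1)
  expect_equal(one$se, 0.05)

  eq <- ivw_meta(c(0.2, 0.0), c(0.1, 0.1))
  expect_equal(eq$beta, 0.1)
  expect_equal(eq$se, 0.1 / sqrt(2))

  # w = (100, 25): beta = (0.3*100 + 0.1*25)/125 = 0.26, se = 1/sqrt(125)
  uneq <- ivw_meta(c(0.3, 0.1), c(0.1, 0.2))
  expect_equal(uneq$beta, 0.26)
  expect_equal(uneq$se, 1 / sqrt(125))

  expect_error(ivw_meta(numeric(0), numeric(0)), "no estimates")
  expect_error(ivw_meta(0.1, 0), "se")
})

test_that("genomic control follows the median rule and never deflates", {
  null_chi2 <- rep(qchisq(0.5, 1), 11)
  expect_equal(genomic_control(null_chi2)$lambda, 1.0)

  gc <- genomic_control(c(0.5, 1.0, 2.0))
  expect_equal(gc$lambda, 1.0 / qchisq(0.5, 1), tolerance = 1e-12)
  expect_equal(gc$lambda, 2.198, tolerance = 1e-3)

  se <- c(0.1, 0.2)
  expect_identical(gc_adjust_se(se, 0.95), se)          # lambda < 1: untouched
  expect_equal(gc_adjust_se(se, 1.21), se * 1.1)        # sqrt(1.21)
})

test_that("Cochran's Q matches the two-group closed form and the worked example", {
  same <- cochran_q(c(0.1, 0.1), c(0.05, 0.05))
  expect_equal(same$q, 0)
  expect_equal(same$p, 1)
  expect_equal(same$i2, 0)

  two <- cochran_q(c(0.1, 0.0), c(0.05, 0.05))
  expect_equal(two$q, 2.0)
  expect_equal(two$p, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(two$p, 0.157, tolerance = 1e-2)

  # the published female/male fasting-insulin estimates at the ZNF12 lead SNP
  z <- cochran_q(znf12$beta, znf12$se)
  expect_equal(z$q, 8.06, tolerance = 1e-3)
  expect_gt(z$p, 4.4e-3)
  expect_lt(z$p, 4.7e-3)
})

test_that("Cochran's Q agrees with an independent fixed-effect implementation", {
  set.seed(TEST_SEED)
  beta <- rnorm(6, 0.05, 0.02)
  se <- runif(6, 0.01, 0.05)
  mine <- cochran_q(beta, se)
  pooled <- ivw_meta(beta, se)
  ref <- metafor::rma(yi = beta, sei = se, method = "FE")
  expect_equal(pooled$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(pooled$se, ref$se, tolerance = 1e-10)
  expect_equal(mine$q, ref$QE, tolerance = 1e-10)
  expect_equal(mine$p, ref$QEp, tolerance = 1e-10)
})

test_that("the 2-df dimorphic test matches its closed form", {
  zero <- sex_dimorphic_test(0, 1, 0, 1)
  expect_equal(zero$t2, 0)
  expect_equal(zero$p, 1)

  z22 <- sex_dimorphic_test(2, 1, 2, 1)
  expect_equal(z22$t2, 8)
  expect_equal(z22$p, exp(-4))

  z <- sex_dimorphic_test(znf12$beta[1], znf12$se[1], znf12$beta[2], znf12$se[2])
  expect_gt(z$t2, 33); expect_lt(z$t2, 35)
  expect_gt(z$p, 3e-8); expect_lt(z$p, 6e-8)

  # closed form p = exp(-t2/2) matches the generic chi-square tail
  t2 <- seq(0.1, 60, length.out = 50)
  expect_equal(pchisq(t2, 2, lower.tail = FALSE), exp(-t2 / 2), tolerance = 1e-12)
})

test_that("I-squared follows its formula and is scale invariant", {
  expect_equal(i_squared(4, 1), 75)
  expect_equal(i_squared(1, 1), 0)
  expect_equal(i_squared(0, 1), 0)
  expect_equal(i_squared(0.5, 1), 0)  # floored at zero

  set.seed(TEST_SEED)
  beta <- rnorm(5); se <- runif(5, 0.1, 1)
  for (k in c(0.1, 3, 100)) {
    a <- cochran_q(beta, se)
    b <- cochran_q(beta * k, se * k)
    expect_equal(a$i2, b$i2, tolerance = 1e-10)
  }
})

test_that("decomposition identity z_f^2 + z_m^2 = z_pooled^2 + Q holds exactly", {
  set.seed(TEST_SEED)
  n <- 10000
  bf <- rnorm(n); bm <- rnorm(n)
  sf <- runif(n, 0.01, 1); sm <- runif(n, 0.01, 1)
  for (i in seq_len(50)) {
    pooled <- ivw_meta(c(bf[i], bm[i]), c(sf[i], sm[i]))
    q <- cochran_q(c(bf[i], bm[i]), c(sf[i], sm[i]))$q
    lhs <- (bf[i] / sf[i])^2 + (bm[i] / sm[i])^2
    expect_equal(lhs, (pooled$beta / pooled$se)^2 + q, tolerance = 1e-10)
  }
  # vectorized form over all pairs
  wf <- 1 / sf^2; wm <- 1 / sm^2
  z2p <- (wf * bf + wm * bm)^2 / (wf + wm)
  qv <- (bf - bm)^2 / (sf^2 + sm^2)
  expect_lt(max(abs((bf / sf)^2 + (bm / sm)^2 - z2p - qv)), 1e-10)
})

test_that("one study per sex passes estimates through the pipeline unchanged", {
  r <- toy_records(3)
  pf <- study_panel(r, "s1", "female")
  rm_ <- r; rm_$beta <- c(0.05, -0.02, 0.0)
  pm <- study_panel(rm_, "s1", "male")
  res <- meta_pipeline(list(pf, pm),
                       meta_config(study_gc = FALSE, second_stage_gc = FALSE))
  expect_equal(res$BETA_F, r$beta[match(res$MARKER, r$marker_id)])
  expect_equal(res$BETA_M, rm_$beta[match(res$MARKER, rm_$marker_id)])
  # decomposition identity on the output columns
  expect_equal(res$CHI2_2DF,
               (res$BETA_ALL / res$SE_ALL)^2 + res$Q, tolerance = 1e-10)
})

test_that("pooling a 6-study synthetic panel recovers the common effect", {
  sim <- generate_study_sumstats(cohort_spec(
    n_variants = 400, fraction_causal = 1, beta_f = 0.04, beta_m = 0.04,
    n_studies = 6, seed = TEST_SEED))
  res <- meta_pipeline(sim$panels, meta_config(second_stage_gc = FALSE))
  cover_f <- mean(abs(res$BETA_F - 0.04) < 2 * res$SE_F)
  cover_m <- mean(abs(res$BETA_M - 0.04) < 2 * res$SE_M)
  expect_gt(cover_f, 0.90)
  expect_gt(cover_m, 0.90)
})

test_that("injected study-level inflation is corrected by genomic control", {
  sim <- generate_study_sumstats(cohort_spec(
    n_variants = 10000, n_studies = 4, gc_lambda = 1.2, seed = TEST_SEED))
  res <- meta_pipeline(sim$panels, meta_config(second_stage_gc = FALSE))
  lam_study <- attr(res, "study_lambda")
  expect_true(all(lam_study > 1.1))   # inflation visible before correction
  # post-GC pooled statistics are calibrated; pool both sexes for stability
  chi2 <- c((res$BETA_F / res$SE_F)^2, (res$BETA_M / res$SE_M)^2)
  lam_post <- genomic_control(chi2)$lambda
  expect_gt(lam_post, 0.98)
  expect_lt(lam_post, 1.02)
})

test_that("a variant absent in one sex still gets a combined result", {
  r <- toy_records(3)
  pf <- study_panel(r, "s1", "female")
  pm <- study_panel(r[1:2, ], "s1", "male")
  res <- meta_pipeline(list(pf, pm),
                       meta_config(study_gc = FALSE, second_stage_gc = FALSE))
  only_f <- res[res$MARKER == "rs3", ]
  expect_true(is.finite(only_f$BETA_ALL))
  expect_true(is.na(only_f$P_DIMORPHIC))
  expect_true(is.na(only_f$Q))
})

test_that("combined-only family studies enter only the combined analysis", {
  r <- toy_records(3)
  pf <- study_panel(r, "s1", "female")
  pm <- study_panel(r, "s1", "male")
  fam <- r; fam$beta <- fam$beta + 0.5
  pc <- study_panel(fam, "fam", "combined")
  cfg <- meta_config(study_gc = FALSE, second_stage_gc = FALSE)
  with_fam <- meta_pipeline(list(pf, pm, pc), cfg)
  without <- meta_pipeline(list(pf, pm), cfg)
  expect_equal(with_fam$BETA_F, without$BETA_F)
  expect_equal(with_fam$BETA_M, without$BETA_M)
  expect_false(isTRUE(all.equal(with_fam$BETA_ALL, without$BETA_ALL)))
})

test_that("both combined-analysis modes are available and differ as documented", {
  set.seed(TEST_SEED)
  r <- toy_records(4)
  r$beta <- rnorm(4, 0, 0.05)
  pf <- study_panel(r, "s1", "female")
  rm_ <- r; rm_$beta <- rnorm(4, 0, 0.05); rm_$se <- r$se * 1.5
  pm <- study_panel(rm_, "s1", "male")
  joint <- meta_pipeline(list(pf, pm),
                         meta_config(study_gc = FALSE, second_stage_gc = FALSE,
                                     combined_mode = "joint"))
  two <- meta_pipeline(list(pf, pm),
                       meta_config(study_gc = FALSE, second_stage_gc = FALSE,
                                   combined_mode = "pooled_sexes"))
  # with one study per sex the two modes coincide
  expect_equal(joint$BETA_ALL, two$BETA_ALL, tolerance = 1e-12)
})
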