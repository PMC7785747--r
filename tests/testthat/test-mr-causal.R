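mk_gwas <- function(marker, chr, pos, p) {
  data.frame(MARKER = marker, CHR = chr, POS = pos, P_ALL = p,
             stringsAsFactors = FALSE)
}

test_that("instrument selection keeps mutually independent significant SNPs", {
  g <- mk_gwas(c("a", "b", "c"), 1:3, c(1e6, 2e6, 3e6), c(1e-10, 1e-9, 1e-12))
  ld0 <- data.frame(MARKER1 = c("a", "a", "b"), MARKER2 = c("b", "c", "c"),
                    R2 = c(0, 0, 0))
  kept <- select_instruments(g, ld = ld0)
  expect_equal(sort(kept$MARKER), c("a", "b", "c"))

  ld <- data.frame(MARKER1 = "a", MARKER2 = "b", R2 = 0.5)
  g2 <- mk_gwas(c("a", "b"), 1, c(1e6, 1.1e6), c(1e-10, 1e-9))
  kept2 <- select_instruments(g2, ld = ld)
  expect_equal(kept2$MARKER, "a")   # lowest p wins the pruning

  expect_error(select_instruments(mk_gwas("a", 1, 1, 0.5)), "threshold")
})

test_that("block-structured LD collapses to one instrument per block", {
  set.seed(TEST_SEED)
  n_blocks <- 10; per_block <- 5
  block <- rep(seq_len(n_blocks), each = per_block)
  marker <- sprintf("b%d_s%d", block, rep(seq_len(per_block), n_blocks))
  g <- mk_gwas(marker, chr = block, pos = rep(1:per_block * 1e4, n_blocks),
               p = runif(length(marker), 1e-12, 1e-9))
  same_block <- outer(block, block, "==") & outer(marker, marker, "!=")
  idx <- which(same_block & upper.tri(same_block), arr.ind = TRUE)
  ld <- data.frame(MARKER1 = marker[idx[, 1]], MARKER2 = marker[idx[, 2]],
                   R2 = 0.8)
  kept <- select_instruments(g, ld = ld)
  expect_equal(nrow(kept), n_blocks)
  expect_equal(length(unique(block[match(kept$MARKER, marker)])), n_blocks)
})

test_that("Wald ratios follow the delta method", {
  r <- ratio_estimate(0.2, 0.01, 0.04, 0.01)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.05)

  r0 <- ratio_estimate(0.2, 0.01, 0, 0.01)
  expect_equal(r0$beta, 0)
  expect_equal(r0$se, 0.05)

  flip <- ratio_estimate(-0.2, 0.01, -0.04, 0.01)
  expect_equal(flip$beta, r$beta)

  expect_error(ratio_estimate(0, 0.01, 0.1, 0.01), "beta_exposure")

  r2 <- ratio_estimate(0.2, 0.01, 0.04, 0.01, second_order = TRUE)
  expect_gt(r2$se, r$se)
})

test_that("IVW recovers an exact line through the origin with zero heterogeneity", {
  inst <- data.frame(beta_exposure = c(0.1, 0.2, 0.3),
                     se_exposure = 0.01,
                     beta_outcome = c(0.02, 0.04, 0.06),
                     se_outcome = 0.01)
  res <- mr_ivw(inst)
  expect_equal(res$beta_iv, 0.2, tolerance = 1e-12)
  expect_equal(res$q_ivw, 0, tolerance = 1e-20)
  expect_equal(res$k, 3L)
})

test_that("IVW slope is invariant to a common rescaling of outcome SEs", {
  set.seed(TEST_SEED)
  inst <- data.frame(beta_exposure = runif(20, 0.05, 0.3), se_exposure = 0.01,
                     beta_outcome = rnorm(20, 0.1, 0.02), se_outcome = 0.01)
  a <- mr_ivw(inst)
  inst2 <- inst; inst2$se_outcome <- inst$se_outcome * 7
  b <- mr_ivw(inst2)
  expect_equal(a$beta_iv, b$beta_iv, tolerance = 1e-12)
})

test_that("with homogeneous instruments random-effect IVW equals fixed-effect", {
  inst <- data.frame(beta_exposure = c(0.1, 0.2, 0.4), se_exposure = 0.01,
                     beta_outcome = c(0.05, 0.10, 0.20), se_outcome = 0.02)
  res <- mr_ivw(inst)
  se_fixed <- 1 / sqrt(sum(inst$beta_exposure^2 / inst$se_outcome^2))
  expect_equal(res$se_iv, se_fixed, tolerance = 1e-12)
})

test_that("Egger recovers exact affine structure and nests the IVW slope", {
  inst <- data.frame(beta_exposure = c(0.1, 0.2, 0.3, 0.4), se_exposure = 0.01,
                     beta_outcome = 0.05 + 0.2 * c(0.1, 0.2, 0.3, 0.4),
                     se_outcome = 0.01)
  res <- mr_egger(inst)
  expect_equal(res$beta_iv, 0.2, tolerance = 1e-10)
  expect_equal(res$intercept, 0.05, tolerance = 1e-10)

  # constraining the intercept to zero reproduces the IVW slope exactly
  w <- 1 / inst$se_outcome^2
  constrained <- coef(lm(beta_outcome ~ beta_exposure - 1, data = inst,
                         weights = w))
  expect_equal(unname(constrained), mr_ivw(inst)$beta_iv, tolerance = 1e-12)

  expect_error(mr_egger(inst[1:2, ]), "at least 3")
})

test_that("IVW and Egger recover planted slopes and pleiotropy", {
  hits_ivw <- hits_egger <- hits_int <- logical(200)
  for (s in seq_len(200)) {
    sim <- generate_mr_system(k = 50, true_slope = 1.0, seed = TEST_SEED + s)
    inst <- sim$instruments$female
    iv <- mr_ivw(inst)
    eg <- mr_egger(inst)
    hits_ivw[s] <- abs(iv$beta_iv - 1.0) < 2 * iv$se_iv
    hits_egger[s] <- abs(eg$beta_iv - 1.0) < 2 * eg$se_iv
    hits_int[s] <- abs(eg$intercept) < 2 * eg$se_intercept
  }
  expect_gte(mean(hits_ivw), 0.95)
  expect_gte(mean(hits_egger), 0.95)
  expect_gte(mean(hits_int), 0.95)
})

test_that("directional pleiotropy lands in the Egger intercept, not the slope", {
  slopes <- ints <- numeric(50)
  for (s in seq_len(50)) {
    sim <- generate_mr_system(k = 200, true_slope = 0.5,
                              pleiotropy_mean = 0.02, seed = TEST_SEED + s)
    eg <- mr_egger(sim$instruments$female)
    slopes[s] <- eg$beta_iv
    ints[s] <- eg$intercept
  }
  expect_lt(abs(median(slopes) - 0.5), 0.05 * 0.5)
  expect_lt(abs(median(ints) - 0.02), 0.005)
})

test_that("median bias is small across the slope/pleiotropy grid", {
  grid <- expand.grid(slope = c(0.5, 1.86), pleio = c(0, -0.002, 0.002))
  for (g in seq_len(nrow(grid))) {
    est <- numeric(30)
    for (s in seq_len(30)) {
      sim <- generate_mr_system(k = 200, true_slope = grid$slope[g],
                                pleiotropy_mean = grid$pleio[g],
                                seed = TEST_SEED + 1000 * g + s)
      inst <- sim$instruments$female
      # constant pleiotropy on signed exposures averages out for IVW;
      # Egger handles the directional (oriented) case
      est[s] <- if (grid$pleio[g] == 0) mr_ivw(inst)$beta_iv
                else mr_egger(inst)$beta_iv
    }
    expect_lt(abs(median(est) - grid$slope[g]), 0.05 * grid$slope[g])
  }
})

test_that("bidirectional orchestration finds a planted forward-women effect", {
  found <- matrix(0, 4, 2,
                  dimnames = list(c("forward.women", "reverse.women",
                                    "forward.men", "reverse.men"), NULL))
  n_seeds <- 20
  sig <- matrix(FALSE, n_seeds, 4)
  for (s in seq_len(n_seeds)) {
    fwd <- generate_mr_system(k = 100, true_slope = c(0.5, 0),
                              seed = TEST_SEED + s)
    rev <- generate_mr_system(k = 50, true_slope = c(0, 0),
                              seed = TEST_SEED + 500 + s)
    res <- mr_bidirectional(list(forward_women = fwd$instruments$female,
                                 reverse_women = rev$instruments$female,
                                 forward_men = fwd$instruments$male,
                                 reverse_men = rev$instruments$male))
    ivw <- res[res$METHOD == "ivw_random", ]
    sig[s, ] <- ivw$SIGNIFICANT
  }
  expect_gte(mean(sig[, 1]), 0.90)          # forward women: planted effect
  expect_lt(mean(sig[, 2]), 0.20)           # the other three cells are null
  expect_lt(mean(sig[, 3]), 0.20)
  expect_lt(mean(sig[, 4]), 0.20)
})

test_that("swapping exposure and outcome labels swaps the result table", {
  sim <- generate_mr_system(k = 60, true_slope = c(0.8, 0.1), seed = TEST_SEED)
  null_sim <- generate_mr_system(k = 60, true_slope = c(0, 0),
                                 seed = TEST_SEED + 1)
  tabs <- list(forward_women = sim$instruments$female,
               reverse_women = null_sim$instruments$female,
               forward_men = sim$instruments$male,
               reverse_men = null_sim$instruments$male)
  swapped <- list(forward_women = tabs$reverse_women,
                  reverse_women = tabs$forward_women,
                  forward_men = tabs$reverse_men,
                  reverse_men = tabs$forward_men)
  a <- mr_bidirectional(tabs)
  b <- mr_bidirectional(swapped)
  fwd_w <- a$DIRECTION == "forward" & a$SEX == "women"
  rev_w <- b$DIRECTION == "reverse" & b$SEX == "women"
  expect_equal(a$BETA_IV[fwd_w], b$BETA_IV[rev_w])
})

test_that("instrument harmonization aligns outcome alleles to the exposure", {
  exp_tab <- data.frame(MARKER = c("rs1", "rs2", "rs3"),
                        EA = c("A", "C", "A"), NEA = c("G", "T", "T"),
                        BETA = c(0.1, 0.2, 0.15), SE = 0.01,
                        EAF = c(0.3, 0.4, 0.2))
  out_tab <- data.frame(MARKER = c("rs1", "rs2", "rs3"),
                        EA = c("G", "C", "A"), NEA = c("A", "T", "T"),
                        BETA = c(-0.05, 0.08, 0.02), SE = 0.02,
                        EAF = c(0.7, 0.4, 0.49))
  h <- harmonize_instruments(exp_tab, out_tab)
  expect_equal(h$marker_id, c("rs1", "rs2"))
  expect_equal(h$beta_outcome, c(0.05, 0.08))  # rs1 swapped back
  dropped <- attr(h, "dropped")
  expect_equal(dropped$marker_id, "rs3")       # ambiguous palindromic
  expect_equal(dropped$reason, "palindromic_ambiguous")
})
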