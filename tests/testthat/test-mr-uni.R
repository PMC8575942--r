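# Univariable estimators: Wald ratio, IVW-MRE, weighted median, MR-Egger,
# MR-PRESSO, and the orchestration layer.

test_that("Wald ratio and its delta-method SEs are correct", {
  wr <- wald_ratio(0.05, 0.01, 0.10, 0.02)
  expect_equal(wr$estimate, 2.0)
  expect_equal(wr$se, 0.4)
  expect_equal(wald_ratio(0.05, 0.01, 0, 0.02)$estimate, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "bx = 0")
})

test_that("second-order Wald SE agrees with Monte-Carlo propagation within 2%", {
  bx <- 0.05; sx <- 0.002; by <- 0.10; sy <- 0.02
  so <- wald_ratio(bx, sx, by, sy, second_order = TRUE)$se
  set.seed(99)
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  expect_equal(so, sd(draws), tolerance = 0.02)
  # and it strictly exceeds the first-order SE
  expect_gt(so, wald_ratio(bx, sx, by, sy)$se)
})

test_that("IVW matches closed-form WLS, reduces to the Wald ratio, and handles exact fits", {
  hs <- fixture_hset5()
  res <- mr_ivw(hs)
  bx <- hs$exposure_betas[, 1]; by <- hs$outcome_beta; w <- 1 / hs$outcome_se^2
  fit <- lm(by ~ bx - 1, weights = w)
  expect_equal(res$estimate, unname(coef(fit)), tolerance = 1e-12)

  # two SNPs with equal bx and sigma_y, ratios 1 and 3 -> estimate 2
  two <- harmonised_set(c(0.1, 0.1), c(0.01, 0.01), c(0.1, 0.3), c(0.05, 0.05))
  expect_equal(mr_ivw(two)$estimate, 2)

  # single SNP reduces to the Wald ratio
  one <- harmonised_set(0.05, 0.01, 0.1, 0.02)
  r1 <- mr_ivw(one)
  expect_equal(r1$estimate, 2)
  expect_equal(r1$se, 0.4)

  # exact line through the origin: Q = 0, random-effects scale 1
  exact <- harmonised_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                          0.5 * c(0.1, 0.2, 0.3), rep(0.05, 3))
  re <- mr_ivw(exact)
  expect_equal(re$estimate, 0.5)
  expect_equal(re$q, 0, tolerance = 1e-15)
  expect_equal(re$re_scale, 1)
  expect_equal(re$se, re$se_fixed)
})

test_that("multiplicative random-effects SE is never below the fixed-effects SE", {
  for (s in 1:20) {
    set.seed(s)
    k <- 25
    hs <- harmonised_set(rnorm(k, 0.05, 0.02), rep(0.003, k),
                         rnorm(k, 0.02, 0.03), runif(k, 0.005, 0.02))
    res <- mr_ivw(hs)
    expect_gte(res$se, res$se_fixed)
    if (res$q <= k - 1) expect_equal(res$se, res$se_fixed)
  }
})

test_that("estimates are equivariant under rescaling of bx and by", {
  hs <- fixture_hset5()
  base <- list(ivw = mr_ivw(hs)$estimate, egger = mr_egger(hs)$estimate,
               med = mr_weighted_median(hs, n_bootstrap = 50, seed = 1)$estimate)

  cx <- hs
  cx$exposure_betas <- hs$exposure_betas * 2
  cx$exposure_ses <- hs$exposure_ses * 2
  expect_equal(mr_ivw(cx)$estimate, base$ivw / 2, tolerance = 1e-12)
  expect_equal(mr_egger(cx)$estimate, base$egger / 2, tolerance = 1e-12)
  expect_equal(mr_weighted_median(cx, n_bootstrap = 50, seed = 1)$estimate,
               base$med / 2, tolerance = 1e-12)

  cy <- hs
  cy$outcome_beta <- hs$outcome_beta * 3
  cy$outcome_se <- hs$outcome_se * 3
  expect_equal(mr_ivw(cy)$estimate, base$ivw * 3, tolerance = 1e-12)
  expect_equal(mr_egger(cy)$estimate, base$egger * 3, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative-weight-0.5 point", {
  const <- harmonised_set(c(0.1, 0.2, 0.4), rep(0.01, 3),
                          0.7 * c(0.1, 0.2, 0.4), rep(0.02, 3))
  expect_equal(mr_weighted_median(const, n_bootstrap = 50, seed = 1)$estimate, 0.7)

  # ratios {1, 2, 10} with equal ratio weights -> 2 (middle mass point)
  bx <- c(0.1, 0.1, 0.1); sy <- c(0.02, 0.02, 0.02)
  eq <- harmonised_set(bx, rep(0.001, 3), c(0.1, 0.2, 1.0), sy)
  expect_equal(mr_weighted_median(eq, n_bootstrap = 50, seed = 1)$estimate, 2)

  # unequal weights: check against the interpolation formula evaluated directly
  bx <- c(0.2, 0.1, 0.3); by <- c(0.1, 0.25, 0.9); sy <- c(0.02, 0.03, 0.05)
  hs <- harmonised_set(bx, rep(0.001, 3), by, sy)
  r <- by / bx; w <- bx^2 / sy^2
  ord <- order(r); r <- r[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  i <- max(which(s < 0.5))
  oracle <- r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
  expect_equal(mr_weighted_median(hs, n_bootstrap = 50, seed = 1)$estimate, oracle,
               tolerance = 1e-12)
})

test_that("weighted median resists sub-half-weight contamination that wrecks IVW", {
  # 10 valid SNPs (true effect 0.5) + 4 pleiotropic SNPs pulled to ratio 5,
  # carrying 45% of the weight
  med_bias <- ivw_bias <- numeric(40)
  for (r in 1:40) {
    set.seed(600 + r)
    bx <- c(rep(0.1, 10), rep(0.143, 4))
    sy <- rep(0.002, 14)
    by <- c(0.5 * bx[1:10], 5.0 * bx[11:14]) + rnorm(14, 0, sy)
    hs <- harmonised_set(bx, rep(0.002, 14), by, sy)
    w <- bx^2 / sy^2
    expect_lt(sum(w[11:14]) / sum(w), 0.5)
    med_bias[r] <- mr_weighted_median(hs, n_bootstrap = 100, seed = r)$estimate - 0.5
    ivw_bias[r] <- mr_ivw(hs)$estimate - 0.5
  }
  # the median stays inside the valid cluster; IVW is dragged toward 5
  expect_lt(max(abs(med_bias)), 0.1)
  expect_gt(min(abs(ivw_bias)), 1)
})

test_that("MR-Egger recovers slope and intercept from exactly generated data", {
  bx <- c(0.05, 0.08, 0.11, 0.15, 0.2)
  by <- 0.02 + 0.5 * bx
  hs <- harmonised_set(bx, rep(0.005, 5), by, rep(0.01, 5))
  res <- mr_egger(hs)
  expect_equal(res$estimate, 0.5, tolerance = 1e-10)
  expect_equal(res$intercept$estimate, 0.02, tolerance = 1e-10)
  expect_equal(res$q, 0, tolerance = 1e-15)

  # matches lm with weights on the oriented data
  hs2 <- fixture_hset5()
  fit <- lm(hs2$outcome_beta ~ hs2$exposure_betas[, 1],
            weights = 1 / hs2$outcome_se^2)
  res2 <- mr_egger(hs2)
  expect_equal(res2$estimate, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(res2$intercept$estimate, unname(coef(fit)[1]), tolerance = 1e-12)

  expect_error(mr_egger(harmonised_set(c(1, 2), c(0.1, 0.1), c(1, 2), c(0.1, 0.1))),
               "at least 3")
})

test_that("Egger slope equals IVW when the intercept is constrained to zero", {
  hs <- fixture_hset5()
  # refit with the intercept dropped: identical to the IVW normal equations
  bx <- hs$exposure_betas[, 1]; by <- hs$outcome_beta; w <- 1 / hs$outcome_se^2
  no_int <- sum(w * bx * by) / sum(w * bx^2)
  expect_equal(mr_ivw(hs)$estimate, no_int, tolerance = 1e-14)
})

test_that("balanced pleiotropy leaves the Egger intercept near-null, directional shifts it", {
  set.seed(42)
  ps <- replicate(60, {
    k <- 50
    bx <- abs(rnorm(k, 0.05, 0.02))
    by <- 0.4 * bx + rnorm(k, 0, 0.01) + rnorm(k, 0, 0.005)  # balanced pleiotropy
    mr_egger(harmonised_set(bx, rep(0.002, k), by, rep(0.01, k)))$intercept$pvalue
  })
  expect_lt(mean(ps < 0.05), 0.2)  # near-nominal type-I error

  set.seed(43)
  hits <- mean(replicate(60, {
    k <- 100
    bx <- abs(rnorm(k, 0.05, 0.02))
    by <- 0.4 * bx + 0.01 + rnorm(k, 0, 0.005) + rnorm(k, 0, 0.005)
    mr_egger(harmonised_set(bx, rep(0.002, k), by, rep(0.01, k)))$intercept$pvalue < 0.05
  }))
  expect_gt(hits, 0.8)
})

test_that("MR-PRESSO is null-calibrated on clean data and flags a planted outlier", {
  set.seed(7)
  k <- 20
  bx <- runif(k, 0.03, 0.12)
  sy <- rep(0.008, k)
  by <- 0.5 * bx + rnorm(k, 0, sy)
  clean <- harmonised_set(bx, rep(0.002, k), by, sy)
  res <- mr_presso(clean, n_sim = 500, seed = 1)
  expect_gt(res$global_pvalue, 0.05)
  expect_length(res$outliers, 0)
  expect_equal(res$estimate, res$raw$estimate)

  # plant a 10-sigma outlier
  by_out <- by
  by_out[5] <- by[5] + 10 * sy[5]
  dirty <- harmonised_set(bx, rep(0.002, k), by_out, sy)
  res2 <- mr_presso(dirty, n_sim = 500, seed = 1)
  expect_lt(res2$global_pvalue, 0.05)
  expect_true("snp5" %in% res2$outliers)
  expect_lt(abs(res2$estimate - 0.5), abs(res2$raw$estimate - 0.5))
  expect_false(is.na(res2$distortion_p))

  expect_error(mr_presso(harmonised_set(1:3 / 10, rep(0.01, 3), 1:3 / 10, rep(0.01, 3))),
               "at least 4")
})

test_that("the PRESSO global test p-value is approximately uniform under the null", {
  set.seed(11)
  ps <- replicate(120, {
    k <- 15
    bx <- runif(k, 0.03, 0.12)
    sy <- rep(0.008, k)
    by <- 0.5 * bx + rnorm(k, 0, sy)
    mr_presso(harmonised_set(bx, rep(0.002, k), by, sy),
              n_sim = 200, seed = sample.int(1e6, 1))$global_pvalue
  })
  # rejection rate near nominal at both tails
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.08)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.15)
})

test_that("the univariable suite produces the full method grid and self-regression is 1", {
  tr <- quick_truth(n_snps = 60, seed = 2)
  st <- generate_study(tr)
  res <- run_total_effects(st$exposures, st$outcomes, ld = st$ld,
                           n_bootstrap = 100, n_presso_sim = 200, seed = 1)
  expect_equal(nrow(res), 2 * 2 * 4)
  expect_setequal(unique(res$exposure), c("sbp", "dbp"))
  # binary outcomes carry OR columns, continuous do not
  expect_true(all(!is.na(res$or[res$outcome == "cvd"])))
  expect_true(all(is.na(res$or[res$outcome == "lifespan"])))

  # exposure regressed on itself: estimate 1 per SD
  self_out <- st$exposures$sbp
  self_out$trait_type <- "continuous"
  res_self <- run_total_effects(list(sbp = st$exposures$sbp), list(self = self_out),
                                ld = st$ld, n_bootstrap = 50, n_presso_sim = 100,
                                seed = 1, methods = "ivw")
  expect_equal(res_self$estimate, 1.0, tolerance = 1e-10)
})
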