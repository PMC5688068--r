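test_that("feature AUC equals exhaustive pairwise concordance", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n1 <- sample(3:6, 1)
      n2 <- sample(3:6, 1)
      # small integer support to force ties
      v <- sample(1:5, n1 + n2, replace = TRUE)
      g <- rep(c("NW", "OW/Ob"), c(n1, n2))
      res <- feature_auc(v, g)
      bf <- brute_auc(v, g == "OW/Ob")
      expect_equal(res$auc, max(bf, 1 - bf), tolerance = 1e-12)
    }
  })
})

test_that("feature AUC handles separation, ties and direction", {
  g <- rep(c("NW", "OW/Ob"), each = 3)
  sep <- feature_auc(c(1, 2, 3, 10, 11, 12), g)
  expect_equal(sep$auc, 1)
  expect_equal(sep$direction, "OW/Ob > NW")
  tied <- feature_auc(rep(2, 6), g)
  expect_equal(tied$auc, 0.5)
  rev <- feature_auc(c(10, 11, 12, 1, 2, 3), g)
  expect_equal(rev$auc, 1)
  expect_equal(rev$direction, "NW > OW/Ob")
  expect_error(feature_auc(1:3, rep("NW", 3)), class = "voclearn_error_input")
})

test_that("AUC confidence intervals are clipped, deterministic and sane", {
  g <- rep(c("NW", "OW/Ob"), each = 6)
  v_sep <- c(1:6, 11:16)
  ci <- auc_ci(v_sep, g)
  expect_equal(unname(ci["high"]), 1)
  expect_true(ci["low"] >= 0 && ci["low"] <= 1)
  withr::with_seed(300, v <- rnorm(12) + rep(c(0, 1), each = 6))
  b1 <- auc_ci(v, g, method = "bootstrap", n_boot = 200, seed = 9)
  b2 <- auc_ci(v, g, method = "bootstrap", n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  d <- auc_ci(v, g)
  expect_lt(d["low"], feature_auc(v, g)$auc)
  expect_gt(d["high"], feature_auc(v, g)$auc)
})

test_that("DeLong intervals achieve near-nominal coverage", {
  # binormal model with known AUC; 40 per group, where the asymptotic
  # DeLong variance is reliable (it is anti-conservative for very small n)
  true_auc <- pnorm(1 / sqrt(2))
  withr::with_seed(123, {
    cover <- vapply(1:200, function(i) {
      v <- c(rnorm(40), rnorm(40) + 1)
      g <- rep(c("NW", "OW/Ob"), each = 40)
      ci <- auc_ci(v, g)
      ci["low"] <= true_auc && true_auc <= ci["high"]
    }, logical(1))
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("Youden cutpoint maximises sens + spec - 1", {
  g <- rep(c("NW", "OW/Ob"), each = 3)
  sep <- sens_spec_at_youden(c(1, 2, 3, 10, 11, 12), g)
  expect_equal(sep$sens, 1)
  expect_equal(sep$spec, 1)
  # binary-valued feature: hand-built 2x2 table at the single real cut
  # pos values {1,1,0}, neg values {0,0,1}: cut at 1 -> sens 2/3, spec 2/3
  v <- c(0, 0, 1, 1, 1, 0)
  out <- sens_spec_at_youden(v, g)
  expect_equal(out$sens, 2 / 3)
  expect_equal(out$spec, 2 / 3)
  expect_equal(out$cutpoint, 1)
  # all tied: J = 0, tie broken toward specificity
  tied <- sens_spec_at_youden(rep(1, 6), g)
  expect_equal(tied$sens + tied$spec, 1)
  expect_equal(tied$spec, 1)
})

test_that("q-values match hand BH and stay monotone", {
  expect_equal(q_values(c(0.01, 0.02, 0.03, 0.04), method = "bh"),
               rep(0.04, 4))
  expect_equal(q_values(rep(1, 5), method = "storey"), rep(1, 5))
  withr::with_seed(17, p <- runif(200)^1.5)
  q <- q_values(p, method = "storey")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  # BH never declares more discoveries at q <= a than raw p <= a counting
  for (a in c(0.01, 0.05, 0.1)) {
    expect_lte(sum(q_values(p, method = "bh") <= a), sum(p <= a))
  }
  expect_error(q_values(c(0.5, 1.2)), class = "voclearn_error_parameter")
})

test_that("post-hoc t power matches a numerical-integration oracle", {
  # independent route: P(T' > t | ncp) integrated over the chi-square mixing
  noncentral_tail <- function(tcrit, df, ncp) {
    stats::integrate(function(w) {
      (1 - pnorm(tcrit * sqrt(w / df) - ncp)) * stats::dchisq(w, df)
    }, 0, Inf, rel.tol = 1e-10)$value
  }
  oracle_power <- function(d, n1, n2, alpha = 0.05) {
    v <- 1 / n1 + 1 / n2
    ncp <- d / sqrt(v)
    df <- (v)^2 / ((1 / n1)^2 / (n1 - 1) + (1 / n2)^2 / (n2 - 1))
    tcrit <- qt(1 - alpha / 2, df)
    noncentral_tail(tcrit, df, ncp) + noncentral_tail(tcrit, df, -ncp)
  }
  got <- power_t(0.5, 1, 28, 0, 1, 21)
  expect_equal(got, oracle_power(0.5, 28, 21), tolerance = 1e-6)
  # null effect: power equals the significance level
  expect_equal(power_t(1, 1, 20, 1, 1, 20), 0.05, tolerance = 1e-3)
  # saturation at a huge standardised effect
  expect_gt(power_t(5, 1, 20, 0, 1, 20), 0.999)
  expect_error(power_t(1, 0, 10, 1, 0, 10), class = "voclearn_error_parameter")
})

test_that("ROC power is calibrated against a binormal simulation", {
  expect_equal(power_roc(0.5 + 1e-12, 28, 21), 0.05, tolerance = 1e-2)
  expect_gt(power_roc(0.99, 28, 21), 0.99)
  # monotone in AUC and in group size
  expect_true(all(diff(vapply(c(0.6, 0.7, 0.8, 0.9), power_roc,
                              numeric(1), n1 = 28, n2 = 21)) > 0))
  expect_gt(power_roc(0.75, 56, 42), power_roc(0.75, 28, 21))
  expect_warning(p0 <- power_roc(0.4, 28, 21), "0.5")
  expect_equal(p0, 0.05)
  # simulation oracle at AUC 0.75, n = 28/21: the z-test with the
  # known-under-H0 variance, rejection rate over binormal draws
  mu <- sqrt(2) * qnorm(0.75)
  v0 <- (0.25 + (28 + 21 - 2) / 12) / (28 * 21)
  withr::with_seed(202, {
    rej <- vapply(1:2000, function(i) {
      v <- c(rnorm(28), rnorm(21) + mu)
      a <- brute_auc(v, rep(c(FALSE, TRUE), c(28, 21)))
      abs(a - 0.5) / sqrt(v0) > qnorm(0.975)
    }, logical(1))
  })
  expect_equal(power_roc(0.75, 28, 21), mean(rej), tolerance = 0.05)
})

test_that("the univariate battery assembles coherent per-feature rows", {
  d <- make_processed(n1 = 14, n2 = 11, p = 8, shift = 2, n_shift = 2,
                      seed = 140)
  uni <- univariate_stats(d)
  expect_equal(nrow(uni), 8)
  expect_true(all(uni$auc >= 0.5))
  expect_true(all(uni$auc_ci_low <= uni$auc & uni$auc <= uni$auc_ci_high))
  expect_true(all(uni$sens >= 0 & uni$sens <= 1))
  expect_true(all(uni$spec >= 0 & uni$spec <= 1))
  # the two shifted features dominate
  expect_setequal(uni$feature[order(uni$t_p)][1:2], c("V1", "V2"))
  expect_true(all(uni$direction[order(uni$t_p)][1:2] == "OW/Ob > NW"))
  # t is invariant to the global autoscaling (affine per feature)
  d_scaled <- d
  d_scaled[paste0("V", 1:8)] <-
    as.data.frame(scale(as.matrix(d[paste0("V", 1:8)])))
  uni2 <- univariate_stats(d_scaled)
  expect_equal(uni2$t_p, uni$t_p, tolerance = 1e-10)
  expect_equal(uni2$auc, uni$auc, tolerance = 1e-12)
})
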