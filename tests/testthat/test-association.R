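test_that("logistic fit recovers closed-form cases", {
  # intercept-only: beta0 = logit of the outcome mean
  y <- rep(c(1, 0), c(25, 75))
  f <- fit_logistic(y, cbind(intercept = rep(1, 100)))
  expect_equal(unname(f$beta), log(0.25 / 0.75), tolerance = 1e-8)

  # saturated 2x2: exp(beta) is the cross-product odds ratio
  x <- rep(c(1, 1, 0, 0), c(7, 13, 25, 312))
  y2 <- rep(c(1, 0, 1, 0), c(7, 13, 25, 312))
  f2 <- fit_logistic(y2, cbind(intercept = 1, carrier = x))
  expect_equal(unname(exp(f2$beta["carrier"])), (7 * 312) / (13 * 25),
               tolerance = 1e-7)
  expect_equal(unname(exp(f2$beta["carrier"])), crude_or(7, 13, 25, 312)$or_,
               tolerance = 1e-7)
})

test_that("logistic fit matches a reference IRLS implementation", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(80:200, 1)
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    colnames(X) <- c("b0", "x1", "x2", "x3")
    beta_true <- runif(4, -1, 1)
    y <- rbinom(n, 1, plogis(drop(X %*% beta_true)))
    if (sum(y) < 3 || sum(y) > n - 3) next
    f <- fit_logistic(y, X)
    if (f$method != "mle") next
    expect_equal(unname(f$beta), unname(irls_reference(y, X)),
                 tolerance = 1e-6)
  }
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  y <- rbinom(50, 1, 0.4)
  X <- cbind(intercept = 1, a = rnorm(50))
  X <- cbind(X, a_copy = X[, "a"])
  expect_error(fit_logistic(y, X), "rank deficient.*a_copy")
})

test_that("separation triggers the Firth refit and keeps estimates finite", {
  # complete separation: carrier status determines the outcome
  x <- rep(c(1, 0), c(20, 80))
  y <- rep(c(1, 0), c(20, 80))
  f <- fit_logistic(y, cbind(intercept = 1, carrier = x))
  expect_equal(f$method, "firth")
  expect_true(f$separation)
  expect_true(all(is.finite(f$beta)))
  expect_true(all(is.finite(f$se)))
  expect_lt(f$p["carrier"], 0.001)
})

test_that("segment logistic association reduces to the crude odds ratio", {
  # cohort mirroring a 2x2 layout, no covariate structure used
  n <- 357
  carrier_cn <- rep(c(1L, 2L, 1L, 2L), c(7, 25, 13, 312))
  cls <- rep(c("none", "none", "good", "good"), c(7, 25, 13, 312))
  labels <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       das28_baseline = 6, das28_month6 = 3,
                       delta_das28 = 3, cdai_baseline = 30, cdai_month6 = 10,
                       delta_cdai = 20, eular_class = cls,
                       is_responder = cls != "none")
  r <- assoc_segment_logistic(carrier_cn, labels, covariates = NULL,
                              segment_id = "tab1", adjusted = FALSE)
  expect_equal(r$or_, crude_or(7, 13, 25, 312)$or_, tolerance = 1e-6)
  expect_equal(r$coding, "deletion_carrier")
  expect_true(r$ci_low < r$or_ && r$or_ < r$ci_high)

  # degenerate predictor: no carriers at all
  expect_error(
    assoc_segment_logistic(rep(2L, n), labels, NULL, adjusted = FALSE),
    "degenerate predictor")
})

test_that("duplication carriers are coded with the reference class", {
  set.seed(5)
  n <- 300
  cn <- c(rep(1L, 20), rep(3L, 10), rep(2L, 270))
  cls <- sample(c("none", "moderate"), n, replace = TRUE, prob = c(0.3, 0.7))
  labels <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       das28_baseline = 6, das28_month6 = 4, delta_das28 = 2,
                       cdai_baseline = 30, cdai_month6 = 15, delta_cdai = 15,
                       eular_class = cls, is_responder = cls != "none")
  r <- assoc_segment_logistic(cn, labels, NULL, adjusted = FALSE)
  # identical to treating CN3 as CN2
  cn2 <- cn; cn2[cn2 == 3L] <- 2L
  r2 <- assoc_segment_logistic(cn2, labels, NULL, adjusted = FALSE)
  expect_equal(r$beta, r2$beta)
})

test_that("linear CDAI model recovers exact coefficients and flips sign", {
  set.seed(23)
  n <- 200
  carrier_cn <- c(rep(1L, 30), rep(2L, 170))
  carrier <- as.integer(carrier_cn <= 1L)
  cdai_b <- runif(n, 20, 45)
  delta <- 10 + 5 * carrier + 0.3 * cdai_b   # exactly linear, no noise
  labels <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       das28_baseline = 6, das28_month6 = 4, delta_das28 = 2,
                       cdai_baseline = cdai_b, cdai_month6 = cdai_b - delta,
                       delta_cdai = delta,
                       eular_class = "moderate", is_responder = TRUE)
  r <- assoc_segment_linear(carrier_cn, labels, NULL, adjusted = FALSE)
  # with baseline CDAI omitted the fit is only near-exact; include it
  r_adj <- {
    covs <- data.frame(sample_id = labels$sample_id,
                       bmi = rnorm(n, 23, 3), sex = rbinom(n, 1, 0.8),
                       drug = sample(c("etanercept", "adalimumab"), n, TRUE),
                       mtx = rbinom(n, 1, 0.8), pc1 = rnorm(n))
    assoc_segment_linear(carrier_cn, labels, covs, adjusted = TRUE)
  }
  expect_equal(r_adj$beta, 5, tolerance = 1e-8)
  expect_lt(r_adj$p_value, 1e-12)
  r_flip <- assoc_segment_linear(carrier_cn, labels, NULL,
                                 orientation = "worsening", adjusted = FALSE)
  expect_equal(r_flip$beta, -r$beta, tolerance = 1e-10)
  expect_equal(r_flip$p_value, r$p_value, tolerance = 1e-10)
})

test_that("permuted carrier labels give well-calibrated linear CIs", {
  set.seed(41)
  n <- 250
  cover <- 0
  reps <- 300
  cdai_b <- runif(n, 20, 45)
  delta <- rnorm(n, 12, 8)
  labels <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       das28_baseline = 6, das28_month6 = 4, delta_das28 = 2,
                       cdai_baseline = cdai_b, cdai_month6 = cdai_b - delta,
                       delta_cdai = delta,
                       eular_class = "moderate", is_responder = TRUE)
  for (r in 1:reps) {
    cn <- sample(c(rep(1L, 20), rep(2L, n - 20)))
    res <- assoc_segment_linear(cn, labels, NULL, adjusted = FALSE)
    cover <- cover + (res$ci_low <= 0 && 0 <= res$ci_high)
  }
  expect_gte(cover / reps, 0.91)
})

test_that("BH step-up matches hand evaluation and the brute-force definition", {
  r <- bh_fdr(rep(0.01, 10), q = 0.05)
  expect_true(all(r$significant))

  r2 <- bh_fdr(c(0.001, 0.01, 0.02, 0.9), q = 0.05)
  expect_equal(r2$significant, c(TRUE, TRUE, TRUE, FALSE))

  r3 <- bh_fdr(0.049, q = 0.05)
  expect_equal(r3$adjusted, 0.049)
  expect_true(r3$significant)

  expect_error(bh_fdr(c(0.5, 0)), "0, 1")

  set.seed(13)
  for (i in 1:40) {
    m <- sample(1:60, 1)
    p <- round(runif(m), 3)
    p[p == 0] <- 1e-4
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    got <- bh_fdr(p, q)
    want <- bh_brute(p, q)
    expect_equal(got$significant, want$significant)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
  }
})

test_that("crude odds ratios use Woolf intervals and zero-cell correction", {
  r <- crude_or(1, 1, 1, 1)
  expect_equal(r$or_, 1)
  expect_false(r$corrected)

  r2 <- crude_or(7, 13, 25, 312)
  expect_equal(r2$or_, 6.72, tolerance = 0.01)
  expect_equal(r2$ci_low, exp(log(6.72) - qnorm(0.975) *
                                sqrt(1 / 7 + 1 / 13 + 1 / 25 + 1 / 312)),
               tolerance = 1e-3)

  r3 <- crude_or(5, 0, 10, 100)
  expect_true(r3$corrected)
  expect_true(is.finite(r3$or_) && r3$or_ > 0)
})

test_that("SNP-CNV tagging r2 handles perfect, null and degenerate cases", {
  set.seed(29)
  n <- 357
  del <- rbinom(n, 2, 0.03)
  # a SNP identical to the deletion dosage tags it perfectly
  r <- snp_cnv_r2(cbind(tag = del), del)
  expect_equal(r$r2, 1)
  # monomorphic SNP: r2 = 0 with flag
  r2 <- snp_cnv_r2(cbind(mono = rep(1, n)), del)
  expect_equal(r2$r2, 0)
  expect_true(r2$monomorphic)
  # independent SNPs: E[r2] ~ 1/(n-1)
  snps <- matrix(rbinom(n * 400, 2, 0.3), n, 400)
  r3 <- snp_cnv_r2(snps, del)
  expect_equal(mean(r3$r2), 1 / (n - 1), tolerance = 0.35)
  # window restriction
  seg <- list(start = 5e6, end = 5.01e6)
  pos <- c(4.2e6, 5.005e6, 6.5e6)
  r4 <- snp_cnv_r2(matrix(rbinom(3 * n, 2, 0.3), n, 3), del,
                   snp_positions = pos, segment = seg, window = 1e6)
  expect_equal(nrow(r4), 2)
})
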