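test_that("the Wald ratio is the delta-method per-SNP estimate", {
  h <- make_hset(gamma = 0.1, Gamma = 0.05, se_Gamma = 0.02)
  w <- mr_wald_ratio(h)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(w$pval, 2 * pnorm(-2.5))

  h0 <- make_hset(gamma = 0.1, Gamma = 0)
  w0 <- mr_wald_ratio(h0)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pval, 1)

  # joint sign flip of gamma and Gamma leaves the ratio unchanged
  hf <- make_hset(gamma = -0.1, Gamma = -0.05, se_Gamma = 0.02)
  expect_equal(mr_wald_ratio(hf)$beta, 0.5)
  expect_error(mr_wald_ratio(make_hset(gamma = 0, Gamma = 0.1)), "zero")
})

test_that("IVW reduces to exact answers in degenerate configurations", {
  # identical Wald ratios: beta exact, zero residuals so no inflation
  h <- make_hset(gamma = c(0.1, 0.3), Gamma = c(0.05, 0.15),
                 se_Gamma = c(0.02, 0.05))
  f <- mr_ivw(h)
  expect_equal(f$beta, 0.5)
  expect_equal(f$se, sqrt(1 / sum(h$gamma^2 / h$se_Gamma^2)))
  # single SNP delegates to the Wald ratio
  h1 <- make_hset(gamma = 0.2, Gamma = 0.08, se_Gamma = 0.03)
  expect_equal(mr_ivw(h1)[c("beta", "se", "pval")],
               mr_wald_ratio(h1)[c("beta", "se", "pval")])
})

test_that("IVW and Egger match an independent weighted-least-squares oracle", {
  for (seed in 1:10) {
    h <- random_hset(J = sample(4:30, 1), seed = 1000 + seed)
    w <- 1 / h$se_Gamma^2
    ivw <- mr_ivw(h)
    o <- oracle_wls(h$gamma, h$Gamma, w, intercept = FALSE)
    expect_equal(ivw$beta, o$coef, tolerance = 1e-12)
    expect_equal(ivw$se, o$se_unscaled * max(1, o$sigma), tolerance = 1e-12)
    # fixed-effect variant drops the residual scale entirely
    expect_equal(mr_ivw(h, random_effects = FALSE)$se, o$se_unscaled,
                 tolerance = 1e-12)

    eg <- mr_egger(h)
    flip <- ifelse(h$gamma < 0, -1, 1)
    oe <- oracle_wls(h$gamma * flip, h$Gamma * flip, w, intercept = TRUE)
    J <- nrow(h)
    expect_equal(eg$beta, oe$coef[2], tolerance = 1e-12)
    expect_equal(eg$intercept, oe$coef[1], tolerance = 1e-12)
    expect_equal(eg$se, oe$se_unscaled[2] * max(1, oe$sigma), tolerance = 1e-12)
    expect_equal(eg$intercept_se, oe$se_unscaled[1] * max(1, oe$sigma),
                 tolerance = 1e-12)
    expect_equal(eg$pval,
                 2 * pt(-abs(eg$beta / eg$se), df = J - 2), tolerance = 1e-12)
  }
})

test_that("IVW is the weighted average of Wald ratios with weights gamma^2/se_Gamma^2", {
  h <- random_hset(15, seed = 77)
  theta <- h$Gamma / h$gamma
  w <- h$gamma^2 / h$se_Gamma^2
  expect_equal(mr_ivw(h)$beta, sum(w * theta) / sum(w))
})

test_that("Egger recovers an exact affine relation and rejects collinearity", {
  g <- c(0.1, 0.2, 0.3, 0.45)
  h <- make_hset(gamma = g, Gamma = 0.02 + 0.3 * g, se_Gamma = 0.01)
  f <- mr_egger(h)
  expect_equal(f$beta, 0.3)
  expect_equal(f$intercept, 0.02)
  expect_error(mr_egger(make_hset(gamma = rep(0.2, 5), Gamma = rnorm(5))),
               class = "mr_degenerate_design")
  expect_error(mr_egger(make_hset(gamma = c(0.1, 0.2), Gamma = c(0, 0))),
               class = "mr_insufficient_instruments")
})

test_that("the weighted median interpolates the weighted ratio quantile", {
  # equal weights, symmetric ratios: the middle one
  h <- make_hset(gamma = c(1, 1, 1), Gamma = c(0.1, 0.5, 0.9), se_Gamma = 1)
  wm <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.5)

  # identical ratios with tiny errors: estimate exact, bootstrap se ~ 0
  hc <- make_hset(gamma = c(0.1, 0.2, 0.4), Gamma = c(0.03, 0.06, 0.12),
                  se_gamma = 1e-8, se_Gamma = 1e-8)
  wmc <- mr_weighted_median(hc, n_boot = 200, seed = 2)
  expect_equal(wmc$beta, 0.3)
  expect_lt(wmc$se, 1e-5)

  # brute-force oracle and bit-for-bit seed reproducibility
  for (seed in 1:5) {
    h <- random_hset(11, seed = 500 + seed)
    wm1 <- mr_weighted_median(h, n_boot = 150, seed = 42)
    wm2 <- mr_weighted_median(h, n_boot = 150, seed = 42)
    expect_identical(wm1, wm2)
    expect_equal(wm1$beta,
                 oracle_weighted_median(h$Gamma / h$gamma,
                                        h$gamma^2 / h$se_Gamma^2))
  }
})

test_that("binary outcomes carry exact odds-ratio transforms", {
  h <- make_hset(gamma = c(0.1, 0.2, 0.3), Gamma = c(0.02, 0.05, 0.04),
                 outcome_type = "binary")
  f <- mr_fit(h, seed = 3, n_boot = 100)
  expect_equal(f$results$or, exp(f$results$beta))
  expect_equal(f$results$or_low, exp(f$results$ci_low))
  expect_equal(f$results$or_high, exp(f$results$ci_high))
  expect_true(all(f$results$ci_low < f$results$beta),
              all(f$results$beta < f$results$ci_high))
})

test_that("mr_fit returns a well-formed model object with working methods", {
  h <- make_hset(gamma = c(0.1, 0.25, 0.4, 0.5),
                 Gamma = c(0.021, 0.049, 0.083, 0.098), se_Gamma = 0.01)
  f <- mr_fit(h, seed = 11, n_boot = 100)
  expect_s3_class(f, "mr_fit")
  expect_named(coef(f), c("ivw", "egger", "weighted_median"))
  ci <- confint(f)
  expect_equal(dim(ci), c(3L, 2L))
  expect_equal(unname(ci["ivw", ]),
               unlist(f$results[f$results$method == "ivw",
                                c("ci_low", "ci_high")], use.names = FALSE))
  r <- residuals(f)
  expect_length(r, 4L)
  expect_equal(unname(predict(f, newdata = c(0, 1))),
               c(0, coef(f)[["ivw"]]))
  expect_output(print(f), "ivw")
  expect_output(print(summary(f)), "Cochran")
  expect_error(mr_fit(h, methods = "weighted_median"), "seed")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("Egger agrees with IVW when pleiotropy is absent", {
  diffs <- vapply(1:40, function(r) {
    s <- simulate_pair(sim_params(m_snps = 40, beta_causal = 0.1,
                                  seed = 6000 + r))
    h <- harmonize(s$exposure, s$outcome)
    mr_egger(h)$beta - mr_ivw(h)$beta
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.005)
})

test_that("the weighted median converges to the majority ratio", {
  # 60% of weight on ratio 0.3, 40% on a contaminated ratio, shrinking SEs
  g <- rep(0.3, 10)
  G <- c(rep(0.09, 6), rep(0.21, 4))
  h <- make_hset(gamma = g, Gamma = G, se_gamma = 1e-6, se_Gamma = 1e-6)
  wm <- mr_weighted_median(h, n_boot = 100, seed = 5)
  expect_equal(wm$beta, 0.3, tolerance = 1e-6)
})
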