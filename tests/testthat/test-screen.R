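test_that("the Bonferroni threshold is alpha over the number of tests", {
  expect_equal(signif(bonferroni_threshold(0.05, 1400), 4), 3.571e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 200), 5e-5)
})

test_that("classification applies the two-tier rule with all gates", {
  cfg <- screen_config(seed = 1, n_tests = 1400)
  # IVW p below 0.05/1400: first tier regardless of the other methods
  expect_equal(classify_pair(make_pair(1.45e-5, 0.2, 0.3), cfg),
               "bonferroni_significant")
  # direction inconsistency vetoes the nominal tier
  expect_equal(classify_pair(
    make_pair(0.01, 0.03, 0.04, betas = c(0.1, 0.1, -0.1)), cfg), "null")
  # all three nominal, consistent signs, clean diagnostics
  expect_equal(classify_pair(make_pair(0.01, 0.03, 0.04), cfg),
               "nominal_significant")
  # each diagnostic gate vetoes on its own
  expect_equal(classify_pair(make_pair(0.01, 0.03, 0.04, q_pval = 0.01), cfg),
               "null")
  expect_equal(classify_pair(
    make_pair(0.01, 0.03, 0.04, egger_intercept_p = 0.02), cfg), "null")
  expect_equal(classify_pair(
    make_pair(0.01, 0.03, 0.04, presso_global_p = 0.03), cfg), "null")
  # a diagnostic that could not run passes vacuously
  expect_equal(classify_pair(
    make_pair(0.01, 0.03, 0.04, presso_global_p = NA), cfg),
    "nominal_significant")
  # any method above alpha: null
  expect_equal(classify_pair(make_pair(0.01, 0.06, 0.04), cfg), "null")
})

test_that("run_pair skips cleanly when stages empty the instrument set", {
  s <- simulate_pair(sim_params(m_snps = 10, m_instruments = 0, seed = 5))
  cfg <- screen_config(seed = 2, n_sim = 100, n_boot = 100)
  pr <- run_pair(s$exposure, s$outcome, s$ld, cfg)
  expect_equal(pr$classification, "skipped")
  expect_equal(pr$skipped_stage, "pvalue_filter")
  expect_output(print(pr), "skipped")
})

test_that("a strong causal pair reaches the Bonferroni tier", {
  s <- simulate_pair(sim_params(m_snps = 35, m_instruments = 30,
                                beta_causal = 0.25, seed = 17))
  cfg <- screen_config(seed = 3, n_tests = 50, n_sim = 200, n_boot = 200)
  pr <- run_pair(s$exposure, s$outcome, s$ld, cfg)
  expect_equal(pr$classification, "bonferroni_significant")
  expect_equal(pr$n_snp_final, nrow(pr$fit$set))
  expect_gte(pr$n_snp_final, 25L)
  # classification is a pure function of the stored pieces
  expect_equal(classify_pair(pr, cfg), pr$classification)
})

test_that("run_pair honors the configured F-filter stage", {
  s <- simulate_pair(sim_params(m_snps = 30, m_instruments = 26,
                                beta_causal = 0.1,
                                gamma_range = c(0.03, 0.3), seed = 23))
  # a permissive p screen (0.01) admits SNPs weaker than F = 10, so the
  # weak-instrument stage has work to do in both configurations
  cfg_post <- screen_config(seed = 4, n_sim = 100, n_boot = 100, n_tests = 10,
                            pval_threshold = 0.01)
  cfg_pre <- screen_config(seed = 4, n_sim = 100, n_boot = 100, n_tests = 10,
                           pval_threshold = 0.01,
                           f_filter_stage = "pre_harmonize")
  pr_post <- run_pair(s$exposure, s$outcome, s$ld, cfg_post)
  pr_pre <- run_pair(s$exposure, s$outcome, s$ld, cfg_pre)
  # both orders drop the same weak SNPs here; survivors agree
  expect_setequal(pr_post$fit$set$snp_id, pr_pre$fit$set$snp_id)
  expect_gt(unname(pr_post$removal_log["weak_instruments"]), 0)
})

test_that("a screen has the right shape and its matrix tracks the IVW sign", {
  exposures <- list(); outcomes <- list()
  for (i in 1:3) {
    s <- simulate_pair(sim_params(m_snps = 25, m_instruments = 20,
                                  beta_causal = c(0.3, -0.3, 0)[i],
                                  seed = 100 + i),
                       exposure_id = paste0("met", i),
                       outcome_id = paste0("out", i))
    exposures[[i]] <- s$exposure
    if (i <= 2) outcomes[[i]] <- s$outcome
  }
  cfg <- screen_config(seed = 5, n_sim = 100, n_boot = 100)
  scr <- run_screen(exposures, outcomes, ld_table(), cfg)
  expect_s3_class(scr, "mr_screen")
  expect_length(scr$pairs, 6L)
  expect_equal(dim(scr$matrix), c(3L, 2L))
  expect_equal(rownames(scr$matrix), c("met1", "met2", "met3"))
  for (pr in scr$pairs) {
    i <- match(pr$exposure_id, rownames(scr$matrix))
    j <- match(pr$outcome_id, colnames(scr$matrix))
    cell <- scr$matrix[i, j]
    if (pr$classification %in% c("bonferroni_significant",
                                 "nominal_significant")) {
      ivw_beta <- pr$fit$results$beta[pr$fit$results$method == "ivw"]
      expect_equal(cell, sign(ivw_beta))
    } else {
      expect_equal(cell, 0L)
    }
    expect_equal(classify_pair(pr, scr$cfg), pr$classification)
  }
  # met1 truly causes out1: that cell must light up positive
  expect_equal(scr$matrix["met1", "out1"], 1L)
  expect_output(print(scr), "3 exposures x 2 outcomes")
})

test_that("screens re-run byte-identically and write stable outputs", {
  exposures <- lapply(1:4, function(i)
    simulate_pair(sim_params(m_snps = 20, m_instruments = 15,
                             beta_causal = 0.2 * (i %% 2), seed = 200 + i),
                  exposure_id = paste0("m", i))$exposure)
  o1 <- simulate_pair(sim_params(m_snps = 20, m_instruments = 15,
                                 beta_causal = 0.2, seed = 201),
                      outcome_id = "cont")$outcome
  o2 <- simulate_pair(sim_params(m_snps = 20, m_instruments = 15,
                                 outcome_type = "binary", seed = 300),
                      outcome_id = "bin")$outcome
  cfg <- screen_config(seed = 6, n_sim = 100, n_boot = 100)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_screen_results(run_screen(exposures, list(o1, o2), ld_table(), cfg), d1)
  write_screen_results(run_screen(exposures, list(o1, o2), ld_table(), cfg), d2)
  for (f in c("results_long.tsv", "matrix.tsv", "config.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  res <- utils::read.delim(file.path(d1, "results_long.tsv"))
  expect_true(all(c("exposure_id", "method", "beta", "classification")
                  %in% names(res)))
  expect_equal(sort(unique(res$outcome_id)), c("bin", "cont"))
})
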