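tab_pvals <- function(p) {
  make_sumstats(snp_id = sprintf("rs%d", seq_along(p)), chrom = "1",
                pos = seq_along(p) * 100000L, effect_allele = "A",
                other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                pval = p, n = 8299)
}

test_that("p-value screen uses a strict inequality and logs removals", {
  tab <- tab_pvals(c(1e-6, 1e-5, 1e-4))
  kept <- filter_by_pvalue(tab, 1e-5)
  expect_equal(kept$pval, 1e-6)
  expect_equal(unname(attr(kept, "selection_log")["pvalue_filter"]), 2L)
  expect_equal(attr(kept, "trait_id"), "trait")

  empty <- filter_by_pvalue(tab_pvals(0.5), 1e-5)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(filter_by_pvalue(empty, 1e-5)), 0L)

  set.seed(7)
  p <- runif(500)
  expect_equal(nrow(filter_by_pvalue(tab_pvals(p), 0.05)),
               sum(vapply(p, function(x) x < 0.05, logical(1))))
})

test_that("clumping keeps the best SNP of a correlated pair, never across chromosomes", {
  tab <- make_sumstats(snp_id = c("a", "b"), chrom = "1",
                       pos = c(100000L, 105000L), effect_allele = "A",
                       other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                       pval = c(1e-8, 1e-6), n = 8299)
  ld <- ld_table("a", "b", 0.9)
  expect_equal(clump(tab, ld)$snp_id, "a")

  tab2 <- tab
  tab2$chrom <- c("1", "2")
  expect_equal(sort(clump(tab2, ld)$snp_id), c("a", "b"))
})

test_that("clumping equals the brute-force greedy oracle on LD-block data", {
  s <- simulate_pair(sim_params(m_snps = 50, m_instruments = 10,
                                ld_blocks = list(block_size = 10, r2 = 0.8),
                                seed = 21))
  got <- clump(s$exposure, s$ld, r2_max = 0.001, window_kb = 10000)
  want <- oracle_clump(as.data.frame(s$exposure), as.data.frame(s$ld),
                       r2_max = 0.001, window_kb = 10000)
  expect_equal(sort(got$snp_id), want)
  # survivors are mutually below the LD threshold within the window
  if (nrow(got) > 1) {
    cmb <- combn(nrow(got), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      same_chrom <- got$chrom[i] == got$chrom[j]
      near <- same_chrom && abs(got$pos[i] - got$pos[j]) <= 1e7
      if (near)
        expect_lt(mrscreen:::ld_lookup(s$ld, got$snp_id[i], got$snp_id[j]),
                  0.001)
    }
  }
})

test_that("selection is invariant to input row order", {
  s <- simulate_pair(sim_params(m_snps = 40, m_instruments = 8,
                                ld_blocks = list(block_size = 5, r2 = 0.6),
                                seed = 3))
  tab <- s$exposure
  set.seed(1)
  shuf <- mrscreen:::restore_sumstats_attrs(tab[sample(nrow(tab)), ], tab)
  a <- select_instruments(tab, s$ld)
  b <- select_instruments(shuf, s$ld)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("dosage LD matches the textbook correlation formula", {
  g <- simulate_dosages(100, 3, maf = c(0.2, 0.3, 0.4), seed = 5)
  ld <- compute_ld_from_dosages(g)
  man_r2 <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    (sum((x - mx) * (y - my)) /
       sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
  }
  for (k in seq_len(nrow(ld))) {
    i <- ld$snp_a[k]; j <- ld$snp_b[k]
    expect_equal(ld$r2[k], man_r2(g[, i], g[, j]))
  }
  # identical columns: r2 exactly 1
  g2 <- cbind(x = g[, 1], y = g[, 1])
  expect_equal(compute_ld_from_dosages(g2)$r2, 1)
  # orthogonal by construction: r2 exactly 0
  g3 <- cbind(a = rep(c(0, 2), 50), b = rep(c(0, 0, 2, 2), 25))
  expect_equal(compute_ld_from_dosages(g3)$r2, 0)
  # zero-variance column omitted with a warning
  g4 <- cbind(g, const = rep(1, 100))
  expect_warning(ld4 <- compute_ld_from_dosages(g4), "zero-variance")
  expect_false("const" %in% c(ld4$snp_a, ld4$snp_b))
})

test_that("variance explained follows the EAF-weighted formula", {
  expect_equal(compute_r2(0, 0.3, 0.02, 8299), 0)
  num <- 2 * 0.1^2 * 0.5 * 0.5
  den <- num + 2 * 0.01^2 * 8299 * 0.5 * 0.5
  expect_equal(compute_r2(0.1, 0.5, 0.01, 8299), num / den)
  expect_equal(num / den, 0.011906, tolerance = 1e-4)
  # symmetric in eaf vs 1 - eaf
  set.seed(2)
  for (i in 1:20) {
    b <- rnorm(1); f <- runif(1, 0.01, 0.99); s <- runif(1, 0.01, 0.1)
    expect_equal(compute_r2(b, f, s, 5000), compute_r2(b, 1 - f, s, 5000))
  }
  expect_error(compute_r2(0.1, NA, 0.02, 8299), "eaf")
})

test_that("F statistic matches its formula and boundary conventions", {
  expect_equal(compute_f(0, 1000, 1), 0)
  expect_equal(compute_f(0.01, 1002, 1), 0.01 * 1000 / 0.99)
  expect_equal(compute_f(0.01, 1002, 1), 10.101, tolerance = 1e-4)
  r2 <- seq(0.001, 0.5, length.out = 50)
  expect_true(all(diff(compute_f(r2, 5000, 3)) > 0))  # monotone in r2
  expect_error(compute_f(0.1, 4, 3), "exceed")
})

test_that("weak-instrument removal keeps F exactly at the floor", {
  tab <- tab_pvals(rep(1e-8, 3))
  tab <- attach_instrument_metrics(tab)
  tab$f_stat <- c(9.9, 10, 21.2)
  kept <- drop_weak_instruments(tab, 10)
  expect_equal(kept$f_stat, c(10, 21.2))
  expect_equal(unname(attr(kept, "selection_log")["weak_instruments"]), 1L)
  expect_equal(nrow(drop_weak_instruments(kept[0, ], 10)), 0L)

  # enumeration oracle on simulated metrics
  s <- simulate_pair(sim_params(m_snps = 200, gamma_range = c(0.02, 0.12),
                                seed = 9))
  m <- attach_instrument_metrics(s$exposure)
  expect_equal(drop_weak_instruments(m, 10)$snp_id,
               m$snp_id[vapply(m$f_stat, function(f) f >= 10, logical(1))])
})

test_that("per-SNP F >= floor is equivalent to R2 >= floor/(N-2+floor)", {
  s <- simulate_pair(sim_params(m_snps = 200, gamma_range = c(0.02, 0.12),
                                seed = 13))
  m <- attach_instrument_metrics(s$exposure)
  f_min <- 10
  lhs <- m$f_stat >= f_min
  rhs <- m$r2 >= f_min / (m$n - 2 + f_min)
  expect_equal(lhs, rhs)
  # per-SNP F (k = 1) reduces to R2(N-2)/(1-R2)
  expect_equal(m$f_stat, m$r2 * (m$n - 2) / (1 - m$r2))
  expect_true(is.finite(attr(m, "joint_f")))
})
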