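# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (lm() fits, explicit loops) so they share no code with
# the package's closed-form estimators.

make_hset <- function(gamma, Gamma, se_gamma = 0.02, se_Gamma = 0.02,
                      outcome_type = "continuous", eaf = 0.3,
                      n_exp = 8299, n_out = 5e5,
                      snp_id = sprintf("rs%04d", seq_along(gamma))) {
  J <- length(gamma)
  df <- data.frame(
    snp_id = snp_id,
    effect_allele = rep("A", J), other_allele = rep("G", J),
    gamma = gamma, se_gamma = rep_len(se_gamma, J),
    Gamma = Gamma, se_Gamma = rep_len(se_Gamma, J),
    pval_exp = rep(1e-8, J), pval_out = rep(0.5, J),
    eaf_exp = rep_len(eaf, J), eaf_out = rep_len(eaf, J),
    n_exp = rep_len(n_exp, J), n_out = rep_len(n_out, J),
    stringsAsFactors = FALSE)
  mrscreen:::new_harmonized_set(df, "exposure", "outcome", outcome_type,
                                c(not_in_outcome = 0L, palindromic = 0L,
                                  mismatched = 0L, missing_values = 0L,
                                  steiger = 0L))
}

make_sumstats <- function(..., trait_id = "trait",
                          trait_type = "continuous") {
  sumstats(data.frame(..., stringsAsFactors = FALSE), trait_id = trait_id,
           trait_type = trait_type)
}

random_hset <- function(J, seed) {
  set.seed(seed)
  make_hset(gamma = runif(J, 0.05, 0.6) * sample(c(-1, 1), J, replace = TRUE),
            Gamma = rnorm(J, 0, 0.05),
            se_gamma = runif(J, 0.005, 0.05),
            se_Gamma = runif(J, 0.002, 0.05))
}

# weighted-least-squares oracle via lm(); returns coefficients, the
# unscaled (sigma = 1) SEs and the weighted residual scale sigma_hat
oracle_wls <- function(g, G, w, intercept) {
  fit <- if (intercept) lm(G ~ g, weights = w) else lm(G ~ 0 + g, weights = w)
  sm <- summary(fit)
  list(coef = unname(coef(fit)),
       se_unscaled = unname(sm$coefficients[, "Std. Error"] / sm$sigma),
       sigma = sm$sigma)
}

# brute-force weighted median: explicit sort, running weight loop, manual
# interpolation between the two bracketing order statistics
oracle_weighted_median <- function(theta, w) {
  w <- w / sum(w)
  ord <- order(theta)
  th <- theta[ord]; ww <- w[ord]
  s <- numeric(length(th))
  run <- 0
  for (i in seq_along(th)) {
    s[i] <- run + ww[i] / 2
    run <- run + ww[i]
  }
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  i <- max(which(s < 0.5))
  th[i] + (0.5 - s[i]) / (s[i + 1] - s[i]) * (th[i + 1] - th[i])
}

# brute-force greedy clumping over plain data frames
oracle_clump <- function(df, ld_df, r2_max, window_kb) {
  df <- df[order(df$pval, df$chrom, df$pos), ]
  kept <- character()
  repeat {
    if (nrow(df) == 0) break
    idx <- df[1, ]
    kept <- c(kept, idx$snp_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    drop <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$chrom[i] != idx$chrom) next
      if (abs(df$pos[i] - idx$pos) > window_kb * 1000) next
      hit <- ld_df[(ld_df$snp_a == idx$snp_id & ld_df$snp_b == df$snp_id[i]) |
                     (ld_df$snp_b == idx$snp_id & ld_df$snp_a == df$snp_id[i]), ]
      r2 <- if (nrow(hit) == 0) 0 else hit$r2[1]
      drop[i] <- r2 >= r2_max
    }
    df <- df[!drop, , drop = FALSE]
  }
  sort(kept)
}

# minimal hand-built pair result for classification tests
make_pair <- function(p_ivw, p_egger, p_wm, betas = c(0.1, 0.1, 0.1),
                      q_pval = 0.5, egger_intercept_p = 0.5,
                      presso_global_p = 0.5) {
  fit <- structure(list(results = data.frame(
    method = c("ivw", "egger", "weighted_median"),
    n_snp = 10L, beta = betas, se = 0.01,
    ci_low = betas - 0.02, ci_high = betas + 0.02,
    pval = c(p_ivw, p_egger, p_wm), stringsAsFactors = FALSE)),
    class = "mr_fit")
  sens <- list(q_pval = q_pval, egger_intercept_p = egger_intercept_p,
               presso_global_p = presso_global_p)
  structure(list(fit = fit, sensitivity = sens), class = "mr_pair_result")
}

write_sumstats_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

sumstats_header <- paste(c("snp_id", "chrom", "pos", "effect_allele",
                           "other_allele", "eaf", "beta", "se", "pval", "n"),
                         collapse = "\t")
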