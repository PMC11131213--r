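#' Cochran's Q heterogeneity test
#'
#' With per-SNP Wald ratios \eqn{\theta_j = \Gamma_j/\gamma_j} and weights
#' \eqn{w_j = \gamma_j^2/se_{\Gamma_j}^2}, the statistic is
#' \eqn{Q = \sum_j w_j(\theta_j - \hat\theta)^2} around the *fixed-effect*
#' IVW estimate \eqn{\hat\theta} (re-estimated from the set at hand, even
#' when the headline IVW uses random effects). Under homogeneity Q is
#' chi-square with J-1 degrees of freedom; the p-value is the upper tail.
#'
#' @param set a `harmonized_set` with at least 2 SNPs.
#' @return A list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  if (nrow(set) < 2L)
    mr_insufficient_error("Cochran's Q needs at least 2 SNPs")
  theta <- set$Gamma / set$gamma
  w <- set$gamma^2 / set$se_Gamma^2
  center <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - center)^2)
  df <- nrow(set) - 1L
  list(q_stat = q, q_df = df,
       q_pval = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept, its standard error and t-test p-value from the
#' [mr_egger()] fit; a nonzero intercept indicates average directional
#' pleiotropy across instruments (under InSIDE).
#'
#' @param set a `harmonized_set` with at least 3 SNPs.
#' @return A list with `intercept`, `intercept_se`, `intercept_p`.
#' @export
egger_intercept_test <- function(set) {
  fit <- mr_egger(set)
  list(intercept = fit$intercept, intercept_se = fit$intercept_se,
       intercept_p = fit$intercept_p)
}

#' Simulation-based global pleiotropy test (MR-PRESSO style)
#'
#' A residual-sum-of-squares global test for pleiotropic outliers. For each
#' SNP j the leave-one-out fixed-effect IVW slope \eqn{\beta_{(-j)}} gives
#' an out-of-sample residual \eqn{r_j = \Gamma_j - \beta_{(-j)}\gamma_j};
#' the observed statistic is \eqn{RSS = \sum_j r_j^2 / se_{\Gamma_j}^2}.
#' Its null distribution is built by parametric simulation: in each of
#' `n_sim` rounds, \eqn{\Gamma_j^* \sim N(\beta_{(-j)}\gamma_j,
#' se_{\Gamma_j})} and \eqn{\gamma_j^* \sim N(\gamma_j, se_{\gamma_j})} are
#' drawn and the statistic recomputed. The global p-value is
#' \eqn{(1 + \#\{RSS^* \ge RSS\})/(1 + n_{sim})} (never exactly zero).
#' Per-SNP outlier p-values compare each observed weighted squared residual
#' with its own simulated distribution and are Bonferroni-adjusted across
#' SNPs.
#'
#' @param set a `harmonized_set` with at least 4 SNPs.
#' @param n_sim simulation rounds (default 1000, minimum 100).
#' @param seed integer seed; mandatory for reproducibility.
#' @return A list with `rss_obs`, `pval`, `n_sim`, and `outlier_p` (named,
#'   Bonferroni-adjusted).
#' @export
presso_global <- function(set, n_sim = 1000, seed) {
  stopifnot(inherits(set, "harmonized_set"))
  if (nrow(set) < 4L)
    mr_insufficient_error("the global pleiotropy test needs at least 4 SNPs")
  stopifnot(n_sim >= 100)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  # canonical SNP order: the simulated null draws then do not depend on the
  # row order of the input, making the p-value permutation-invariant
  ord <- order(set$snp_id)
  g <- set$gamma[ord]; G <- set$Gamma[ord]
  sg <- set$se_gamma[ord]; sG <- set$se_Gamma[ord]
  w <- 1 / sG^2
  J <- length(g)

  loo_slopes <- function(g, G) {
    s1 <- sum(w * g * G); s2 <- sum(w * g^2)
    (s1 - w * g * G) / (s2 - w * g^2)
  }
  b_loo <- loo_slopes(g, G)
  r_obs <- G - b_loo * g
  rss_obs <- sum(w * r_obs^2)
  r2w_obs <- w * r_obs^2

  sims <- with_seed(seed, {
    gs <- matrix(stats::rnorm(J * n_sim, mean = g, sd = sg), nrow = J)
    Gs <- matrix(stats::rnorm(J * n_sim, mean = b_loo * g, sd = sG), nrow = J)
    # vectorized leave-one-out slopes per simulation round
    s1 <- colSums(w * gs * Gs); s2 <- colSums(w * gs^2)
    b_star <- (rep(s1, each = J) - w * gs * Gs) /
      (rep(s2, each = J) - w * gs^2)
    dim(b_star) <- c(J, n_sim)
    r_star <- Gs - b_star * gs
    w * r_star^2
  })
  rss_star <- colSums(sims)
  pval <- (1 + sum(rss_star >= rss_obs)) / (1 + n_sim)
  outlier_p <- (1 + rowSums(sims >= r2w_obs)) / (1 + n_sim)
  outlier_p <- pmin(outlier_p * J, 1)
  names(outlier_p) <- set$snp_id[ord]
  # report in the input's row order
  outlier_p <- outlier_p[set$snp_id]
  list(rss_obs = rss_obs, pval = pval, n_sim = as.integer(n_sim),
       outlier_p = outlier_p)
}

#' Leave-one-out analysis
#'
#' Refits the IVW estimator J times, excluding one SNP at a time. A SNP is
#' flagged influential when its exclusion flips the sign of the estimate or
#' moves the p-value across `alpha`.
#'
#' @param set a `harmonized_set` with at least 3 SNPs.
#' @param random_effects IVW variant, as in [mr_fit()].
#' @param alpha significance threshold used for the influence flag.
#' @return A data frame with one row per excluded SNP: `snp_id`, `beta`,
#'   `se`, `pval`, `influential`.
#' @export
leave_one_out <- function(set, random_effects = TRUE, alpha = 0.05) {
  stopifnot(inherits(set, "harmonized_set"))
  if (nrow(set) < 3L)
    mr_insufficient_error("leave-one-out needs at least 3 SNPs")
  full <- mr_ivw(set, random_effects = random_effects)
  rows <- lapply(seq_len(nrow(set)), function(j) {
    sub <- new_harmonized_set(set[-j, , drop = FALSE],
                              exposure_id = attr(set, "exposure_id"),
                              outcome_id = attr(set, "outcome_id"),
                              outcome_type = attr(set, "outcome_type"),
                              removal_log = attr(set, "removal_log"))
    fit <- mr_ivw(sub, random_effects = random_effects)
    data.frame(snp_id = set$snp_id[j], beta = fit$beta, se = fit$se,
               pval = fit$pval,
               influential = sign(fit$beta) != sign(full$beta) ||
                 (fit$pval < alpha) != (full$pval < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run all sensitivity diagnostics
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, the simulation-based
#' global pleiotropy test and leave-one-out into one report. Diagnostics
#' whose minimum SNP count is not met are recorded as not run (`NA`), not
#' errors. Flags are evaluated at `alpha`: heterogeneity when the Q p-value
#' is below it, pleiotropy when the Egger-intercept or global-test p-value
#' is.
#'
#' @param set a `harmonized_set`.
#' @param n_sim simulation rounds for the global test.
#' @param seed integer seed (mandatory).
#' @param alpha flag threshold (default 0.05).
#' @param random_effects IVW variant for leave-one-out.
#' @return An object of class `mr_sensitivity`: list with `q_stat`, `q_df`,
#'   `q_pval`, `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `presso_global_rss`, `presso_global_p`, `presso_n_sim`, `presso_outlier_p`,
#'   `loo`, `heterogeneity_detected`, `pleiotropy_detected`, `not_run`.
#' @export
mr_sensitivity <- function(set, n_sim = 1000, seed, alpha = 0.05,
                           random_effects = TRUE) {
  stopifnot(inherits(set, "harmonized_set"))
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  not_run <- character()
  rep <- list(q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
              egger_intercept = NA_real_, egger_intercept_se = NA_real_,
              egger_intercept_p = NA_real_,
              presso_global_rss = NA_real_, presso_global_p = NA_real_,
              presso_n_sim = NA_integer_, presso_outlier_p = NULL,
              loo = NULL)
  if (nrow(set) >= 2) {
    q <- cochran_q(set)
    rep[c("q_stat", "q_df", "q_pval")] <- q
  } else not_run <- c(not_run, "cochran_q")
  if (nrow(set) >= 3) {
    eg <- egger_intercept_test(set)
    rep[c("egger_intercept", "egger_intercept_se", "egger_intercept_p")] <- eg
    rep$loo <- leave_one_out(set, random_effects = random_effects,
                             alpha = alpha)
  } else not_run <- c(not_run, "egger_intercept", "leave_one_out")
  if (nrow(set) >= 4) {
    pr <- presso_global(set, n_sim = n_sim, seed = seed)
    rep$presso_global_rss <- pr$rss_obs
    rep$presso_global_p <- pr$pval
    rep$presso_n_sim <- pr$n_sim
    rep$presso_outlier_p <- pr$outlier_p
  } else not_run <- c(not_run, "presso_global")
  rep$heterogeneity_detected <- isTRUE(rep$q_pval < alpha)
  rep$pleiotropy_detected <- isTRUE(rep$egger_intercept_p < alpha) ||
    isTRUE(rep$presso_global_p < alpha)
  rep$alpha <- alpha
  rep$not_run <- not_run
  class(rep) <- "mr_sensitivity"
  rep
}

#' @export
print.mr_sensitivity <- function(x, digits = 4, ...) {
  cat("MR sensitivity diagnostics\n")
  cat(sprintf("  Cochran's Q:        %.*g on %s df, p = %.*g\n",
              digits, x$q_stat, format(x$q_df), digits, x$q_pval))
  cat(sprintf("  Egger intercept:    %.*g (SE %.*g), p = %.*g\n",
              digits, x$egger_intercept, digits, x$egger_intercept_se,
              digits, x$egger_intercept_p))
  cat(sprintf("  Global RSS test:    RSS = %.*g, p = %.*g (%s simulations)\n",
              digits, x$presso_global_rss, digits, x$presso_global_p,
              format(x$presso_n_sim)))
  cat(sprintf("  heterogeneity: %s; pleiotropy: %s (alpha = %g)\n",
              x$heterogeneity_detected, x$pleiotropy_detected, x$alpha))
  if (length(x$not_run))
    cat("  not run:", paste(x$not_run, collapse = ", "), "\n")
  invisible(x)
}
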