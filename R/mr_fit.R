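#' Fit two-sample Mendelian randomization models
#'
#' Fits the requested causal estimators to a harmonized set of per-SNP
#' effect pairs \eqn{(\gamma_j, \Gamma_j)}:
#'
#' * **IVW** — inverse-variance weighted: weighted least squares of
#'   \eqn{\Gamma} on \eqn{\gamma} through the origin with weights
#'   \eqn{1/se_{\Gamma_j}^2}; equivalently the inverse-variance weighted
#'   average of per-SNP Wald ratios. By default a multiplicative
#'   random-effects standard error is used: the fixed-effect SE is scaled
#'   by \eqn{\max(1, \hat\phi)} where \eqn{\hat\phi^2} is the weighted
#'   residual mean square on J-1 degrees of freedom. Single-SNP sets reduce
#'   to the Wald ratio.
#' * **MR-Egger** — each SNP is oriented so \eqn{\gamma_j > 0}, then
#'   weighted least squares of \eqn{\Gamma} on \eqn{\gamma} *with*
#'   intercept; the slope is the pleiotropy-robust causal estimate and the
#'   intercept estimates average directional pleiotropy. SEs carry the same
#'   \eqn{\max(1,\hat\phi)} scale on J-2 df; p-values and confidence
#'   intervals use the t distribution with J-2 df.
#' * **Weighted median** — per-SNP ratios \eqn{\theta_j = \Gamma_j/\gamma_j}
#'   with weights \eqn{\gamma_j^2/se_{\Gamma_j}^2} normalized to sum one;
#'   the estimate interpolates the weighted empirical quantile function at
#'   probability 0.5 (cumulative midpoint weights). Its SE is the standard
#'   deviation over `n_boot` parametric resamples of
#'   \eqn{(\gamma_j^*, \Gamma_j^*)}; a seed is therefore mandatory when
#'   this method is requested. Consistent when at least half the weight
#'   comes from valid instruments.
#'
#' For binary outcomes all estimates are on the log odds-ratio scale and
#' exponentiated `or` columns are added.
#'
#' @param set a `harmonized_set` from [harmonize()]/[steiger_filter()].
#' @param methods any of `"ivw"`, `"egger"`, `"weighted_median"`.
#' @param n_boot bootstrap replicates for the weighted-median SE
#'   (default 1000).
#' @param seed integer seed for the weighted-median bootstrap; mandatory if
#'   `"weighted_median"` is requested.
#' @param random_effects use the multiplicative random-effects IVW SE
#'   (default `TRUE`); `FALSE` gives the fixed-effect SE.
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#'
#' @return An object of class `mr_fit`: a list with `results` (one row per
#'   method: `method`, `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`,
#'   plus `or`, `or_low`, `or_high` for binary outcomes and
#'   `intercept`, `intercept_se`, `intercept_p` for MR-Egger), the input
#'   `set`, and fit metadata. Methods: [print.mr_fit()], [summary.mr_fit()],
#'   [coef.mr_fit()], [confint.mr_fit()], [plot.mr_fit()],
#'   [residuals.mr_fit()], [predict.mr_fit()].
#' @seealso [mr_ivw()], [mr_egger()], [mr_weighted_median()],
#'   [mr_wald_ratio()], [mr_sensitivity()]
#' @export
mr_fit <- function(set, methods = c("ivw", "egger", "weighted_median"),
                   n_boot = 1000, seed = NULL, random_effects = TRUE,
                   alpha = 0.05) {
  stopifnot(inherits(set, "harmonized_set"))
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median"),
                       several.ok = TRUE)
  if ("weighted_median" %in% methods && is.null(seed))
    stop("a seed is mandatory for the weighted-median bootstrap")
  rows <- list()
  for (m in methods) {
    rows[[m]] <- switch(m,
      ivw = mr_ivw(set, random_effects = random_effects, alpha = alpha),
      egger = mr_egger(set, alpha = alpha),
      weighted_median = mr_weighted_median(set, n_boot = n_boot, seed = seed,
                                           alpha = alpha))
  }
  results <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(results) <- NULL
  structure(list(results = results, set = set,
                 exposure_id = attr(set, "exposure_id"),
                 outcome_id = attr(set, "outcome_id"),
                 outcome_type = attr(set, "outcome_type"),
                 alpha = alpha, random_effects = random_effects,
                 n_boot = n_boot, seed = seed),
            class = "mr_fit")
}

mr_result_row <- function(method, n_snp, beta, se, crit, pdist, df = NA_real_,
                          outcome_type = "continuous",
                          intercept = NULL) {
  z <- beta / se
  pval <- if (pdist == "t") {
    pmax(2 * stats::pt(-abs(z), df = df), .Machine$double.xmin)
  } else two_sided_p(z)
  row <- list(method = method, n_snp = n_snp, beta = beta, se = se,
              ci_low = beta - crit * se, ci_high = beta + crit * se,
              pval = pval)
  if (identical(outcome_type, "binary")) {
    row$or <- exp(row$beta)
    row$or_low <- exp(row$ci_low)
    row$or_high <- exp(row$ci_high)
  } else {
    row$or <- NA_real_; row$or_low <- NA_real_; row$or_high <- NA_real_
  }
  if (!is.null(intercept)) {
    row$intercept <- intercept[["est"]]
    row$intercept_se <- intercept[["se"]]
    row$intercept_p <- intercept[["p"]]
  } else {
    row$intercept <- NA_real_; row$intercept_se <- NA_real_
    row$intercept_p <- NA_real_
  }
  row
}

check_nonempty <- function(set) {
  if (nrow(set) == 0L)
    mr_empty_set_error("harmonized set contains no SNPs")
}

#' Wald ratio for a single SNP
#'
#' The per-SNP causal estimate \eqn{\Gamma/\gamma} with first-order
#' delta-method standard error \eqn{se_\Gamma/|\gamma|} and a two-sided
#' normal p-value.
#'
#' @param set a `harmonized_set` with exactly one SNP (or `gamma`, `Gamma`,
#'   `se_Gamma` given directly via the other arguments).
#' @param alpha one minus the confidence level.
#' @return A list with the `mr_fit` result-row fields.
#' @export
mr_wald_ratio <- function(set, alpha = 0.05) {
  check_nonempty(set)
  stopifnot(nrow(set) == 1L)
  if (set$gamma == 0) stop("Wald ratio undefined: exposure effect is zero")
  beta <- set$Gamma / set$gamma
  se <- set$se_Gamma / abs(set$gamma)
  mr_result_row("wald", 1L, beta, se, crit = stats::qnorm(1 - alpha / 2),
                pdist = "normal", outcome_type = attr(set, "outcome_type"))
}

#' Inverse-variance weighted estimator
#'
#' @inheritParams mr_fit
#' @return A list with the `mr_fit` result-row fields.
#' @rdname mr_fit
#' @export
mr_ivw <- function(set, random_effects = TRUE, alpha = 0.05) {
  check_nonempty(set)
  if (nrow(set) == 1L) return(mr_wald_ratio(set, alpha = alpha))
  g <- set$gamma; G <- set$Gamma; w <- 1 / set$se_Gamma^2
  s2 <- sum(w * g^2)
  beta <- sum(w * g * G) / s2
  se_fixed <- sqrt(1 / s2)
  J <- length(g)
  phi2 <- sum(w * (G - beta * g)^2) / (J - 1)
  scale <- if (random_effects) max(1, sqrt(phi2)) else 1
  mr_result_row("ivw", J, beta, se_fixed * scale,
                crit = stats::qnorm(1 - alpha / 2), pdist = "normal",
                outcome_type = attr(set, "outcome_type"))
}

#' MR-Egger regression
#'
#' @rdname mr_fit
#' @export
mr_egger <- function(set, alpha = 0.05) {
  check_nonempty(set)
  if (nrow(set) < 3L)
    mr_insufficient_error("MR-Egger needs at least 3 SNPs")
  flip <- sign(set$gamma)
  flip[flip == 0] <- 1
  g <- set$gamma * flip; G <- set$Gamma * flip
  w <- 1 / set$se_Gamma^2
  if (stats::var(g) < .Machine$double.eps * max(1, mean(g)^2))
    mr_degenerate_error("MR-Egger design is collinear: all |gamma| equal")
  J <- length(g)
  sw <- sum(w); swx <- sum(w * g); swx2 <- sum(w * g^2)
  swy <- sum(w * G); swxy <- sum(w * g * G)
  det <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swx2 * swy - swx * swxy) / det
  resid <- G - inter - slope * g
  phi2 <- sum(w * resid^2) / (J - 2)
  scale <- max(1, sqrt(phi2))
  se_slope <- sqrt(sw / det) * scale
  se_inter <- sqrt(swx2 / det) * scale
  crit <- stats::qt(1 - alpha / 2, df = J - 2)
  p_inter <- pmax(2 * stats::pt(-abs(inter / se_inter), df = J - 2),
                  .Machine$double.xmin)
  mr_result_row("egger", J, slope, se_slope, crit = crit, pdist = "t",
                df = J - 2, outcome_type = attr(set, "outcome_type"),
                intercept = list(est = inter, se = se_inter, p = p_inter))
}

# Weighted empirical quantile at probability 0.5 with midpoint cumulative
# weights; linear interpolation between order statistics.
weighted_median_estimate <- function(theta, w) {
  w <- w / sum(w)
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  i <- max(which(s < 0.5))
  theta[i] + (0.5 - s[i]) / (s[i + 1] - s[i]) * (theta[i + 1] - theta[i])
}

#' Weighted-median estimator
#'
#' @rdname mr_fit
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = NULL, alpha = 0.05) {
  check_nonempty(set)
  if (nrow(set) < 3L)
    mr_insufficient_error("weighted median needs at least 3 SNPs")
  stopifnot(n_boot >= 100)
  if (is.null(seed)) stop("a seed is mandatory for the weighted-median bootstrap")
  use <- set$gamma != 0
  if (any(!use))
    warning(sum(!use), " SNP(s) with zero exposure effect excluded from weighted median")
  g <- set$gamma[use]; G <- set$Gamma[use]
  sg <- set$se_gamma[use]; sG <- set$se_Gamma[use]
  J <- length(g)
  theta <- G / g
  w <- g^2 / sG^2
  est <- weighted_median_estimate(theta, w)
  boot <- with_seed(seed, {
    gs <- matrix(stats::rnorm(J * n_boot, mean = g, sd = sg), nrow = J)
    Gs <- matrix(stats::rnorm(J * n_boot, mean = G, sd = sG), nrow = J)
    vapply(seq_len(n_boot), function(b) {
      gb <- gs[, b]
      ok <- gb != 0
      weighted_median_estimate(Gs[ok, b] / gb[ok], gb[ok]^2 / sG[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_result_row("weighted_median", J, est, se,
                crit = stats::qnorm(1 - alpha / 2), pdist = "normal",
                outcome_type = attr(set, "outcome_type"))
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%s outcome), %d SNP(s)\n\n",
              x$exposure_id %||% "?", x$outcome_id %||% "?",
              x$outcome_type, nrow(x$set)))
  res <- x$results
  show <- res[c("method", "n_snp", "beta", "se", "ci_low", "ci_high", "pval")]
  if (identical(x$outcome_type, "binary"))
    show <- cbind(show, res[c("or", "or_low", "or_high")])
  print(format(show, digits = digits), row.names = FALSE)
  eg <- res[res$method == "egger", ]
  if (nrow(eg) == 1L && !is.na(eg$intercept))
    cat(sprintf("\nMR-Egger intercept: %.*g (SE %.*g, p = %.*g)\n",
                digits, eg$intercept, digits, eg$intercept_se,
                digits, eg$intercept_p))
  invisible(x)
}

#' @export
#' @method summary mr_fit
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit, ...)
  set <- x$fit$set
  if (nrow(set) >= 2) {
    q <- cochran_q(set)
    cat(sprintf("\nCochran's Q = %.4g on %d df, p = %.4g\n",
                q$q_stat, q$q_df, q$q_pval))
  }
  invisible(x)
}

#' @export
#' @method coef mr_fit
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
#' @method confint mr_fit
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  res <- object$results
  if (abs(level - (1 - object$alpha)) > 1e-12)
    warning("intervals were computed at level ", 1 - object$alpha)
  out <- as.matrix(res[c("ci_low", "ci_high")])
  rownames(out) <- res$method
  colnames(out) <- sprintf("%g %%", c(object$alpha / 2, 1 - object$alpha / 2) * 100)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
#' @method residuals mr_fit
residuals.mr_fit <- function(object, method = "ivw", ...) {
  res <- object$results
  if (!method %in% res$method) stop("no fitted method '", method, "'")
  b <- res$beta[res$method == method]
  a <- if (method == "egger") res$intercept[res$method == method] else 0
  set <- object$set
  flip <- if (method == "egger") ifelse(set$gamma < 0, -1, 1) else 1
  stats::setNames(set$Gamma * flip - a - b * set$gamma * flip, set$snp_id)
}

#' @export
#' @method predict mr_fit
predict.mr_fit <- function(object, newdata = NULL, method = "ivw", ...) {
  res <- object$results
  if (!method %in% res$method) stop("no fitted method '", method, "'")
  b <- res$beta[res$method == method]
  a <- if (method == "egger") res$intercept[res$method == method] else 0
  g <- if (is.null(newdata)) object$set$gamma
  else if (is.list(newdata)) newdata$gamma
  else newdata
  a + b * g
}

#' @export
#' @method plot mr_fit
plot.mr_fit <- function(x, ...) {
  set <- x$set
  graphics::plot(set$gamma, set$Gamma,
                 xlab = "SNP effect on exposure (gamma)",
                 ylab = "SNP effect on outcome (Gamma)",
                 pch = 19, ...)
  graphics::segments(set$gamma, set$Gamma - 1.96 * set$se_Gamma,
                     set$gamma, set$Gamma + 1.96 * set$se_Gamma,
                     col = "grey60")
  res <- x$results
  cols <- c(ivw = "firebrick", egger = "steelblue",
            weighted_median = "darkgreen", wald = "firebrick")
  for (i in seq_len(nrow(res))) {
    a <- if (res$method[i] == "egger") res$intercept[i] else 0
    graphics::abline(a = a, b = res$beta[i], col = cols[[res$method[i]]],
                     lwd = 2, lty = i)
  }
  graphics::legend("topleft", legend = res$method, col = cols[res$method],
                   lty = seq_len(nrow(res)), lwd = 2, bty = "n")
  invisible(x)
}
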