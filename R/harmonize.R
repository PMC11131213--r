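#' Align exposure and outcome effect alleles
#'
#' Produces the analysis-ready per-SNP effect pairs (exposure effect
#' \eqn{\gamma_j} and outcome effect \eqn{\Gamma_j}, with standard errors)
#' for every selected instrument found in the outcome table, in the
#' exposure's allele orientation:
#'
#' * outcome alleles equal to the exposure's: kept as-is;
#' * outcome alleles swapped (effect/other exchanged): outcome beta negated,
#'   outcome `eaf` complemented;
#' * alleles matching only after strand complement (A<->T, C<->G): the
#'   complement is applied first, then the two rules above (disable with
#'   `strand_flip = FALSE`);
#' * palindromic SNPs (A/T or C/G pairs) are removed unconditionally —
#'   their strand cannot be resolved from alleles alone;
#' * allele sets irreconcilable after the above are removed as mismatched;
#' * records with missing beta/se/p-value on either side are removed;
#' * instruments absent from the outcome are dropped (no proxy-SNP search).
#'
#' @param exposure_ivs instrument-selected exposure [sumstats()].
#' @param outcome outcome [sumstats()].
#' @param strand_flip attempt strand-complement reconciliation before
#'   declaring a mismatch (default `TRUE`).
#'
#' @return A `harmonized_set`: a data frame with columns `snp_id`,
#'   `effect_allele`, `other_allele` (exposure orientation), `gamma`,
#'   `se_gamma`, `Gamma`, `se_Gamma`, `pval_exp`, `pval_out`, `eaf_exp`,
#'   `eaf_out`, `n_exp`, `n_out`, and attributes `exposure_id`,
#'   `outcome_id`, `outcome_type` and `removal_log` (counts by reason:
#'   `not_in_outcome`, `palindromic`, `mismatched`, `missing_values`,
#'   `steiger`). An empty set is returned, not an error; estimators raise a
#'   typed condition on it.
#' @export
harmonize <- function(exposure_ivs, outcome, strand_flip = TRUE) {
  stopifnot(inherits(exposure_ivs, "sumstats"), inherits(outcome, "sumstats"))
  log <- c(not_in_outcome = 0L, palindromic = 0L, mismatched = 0L,
           missing_values = 0L, steiger = 0L)
  exp <- exposure_ivs
  idx <- match(exp$snp_id, outcome$snp_id)
  log["not_in_outcome"] <- sum(is.na(idx))
  keep <- !is.na(idx)
  exp <- exp[keep, , drop = FALSE]
  out <- outcome[idx[keep], , drop = FALSE]

  n <- nrow(exp)
  gamma <- exp$beta; se_gamma <- exp$se
  Gamma <- rep(NA_real_, n); se_Gamma <- out$se
  eaf_out <- rep(NA_real_, n)
  status <- rep("ok", n)

  pal <- is_palindromic(exp$effect_allele, exp$other_allele) |
    is_palindromic(out$effect_allele, out$other_allele)
  status[pal] <- "palindromic"

  for (i in seq_len(n)) {
    if (status[i] != "ok") next
    ea_x <- exp$effect_allele[i]; oa_x <- exp$other_allele[i]
    ea_y <- out$effect_allele[i]; oa_y <- out$other_allele[i]
    b <- out$beta[i]; f <- out$eaf[i]
    matched <- FALSE
    for (flip in c(FALSE, if (strand_flip) TRUE)) {
      a1 <- if (flip) complement_allele(ea_y) else ea_y
      a2 <- if (flip) complement_allele(oa_y) else oa_y
      if (identical(a1, ea_x) && identical(a2, oa_x)) {
        Gamma[i] <- b; eaf_out[i] <- f
        matched <- TRUE; break
      }
      if (identical(a1, oa_x) && identical(a2, ea_x)) {
        Gamma[i] <- -b
        eaf_out[i] <- if (is.na(f)) NA_real_ else 1 - f
        matched <- TRUE; break
      }
    }
    if (!matched) status[i] <- "mismatched"
  }

  miss <- status == "ok" &
    (is.na(gamma) | is.na(se_gamma) | is.na(exp$pval) |
       is.na(Gamma) | is.na(se_Gamma) | is.na(out$pval))
  status[miss] <- "missing_values"

  log["palindromic"] <- sum(status == "palindromic")
  log["mismatched"] <- sum(status == "mismatched")
  log["missing_values"] <- sum(status == "missing_values")

  ok <- status == "ok"
  df <- data.frame(
    snp_id = exp$snp_id[ok],
    effect_allele = exp$effect_allele[ok], other_allele = exp$other_allele[ok],
    gamma = gamma[ok], se_gamma = se_gamma[ok],
    Gamma = Gamma[ok], se_Gamma = se_Gamma[ok],
    pval_exp = exp$pval[ok], pval_out = out$pval[ok],
    eaf_exp = exp$eaf[ok], eaf_out = eaf_out[ok],
    n_exp = exp$n[ok], n_out = out$n[ok],
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new_harmonized_set(df,
                     exposure_id = attr(exposure_ivs, "trait_id"),
                     outcome_id = attr(outcome, "trait_id"),
                     outcome_type = attr(outcome, "trait_type"),
                     removal_log = log)
}

new_harmonized_set <- function(df, exposure_id, outcome_id, outcome_type,
                               removal_log) {
  structure(df,
            exposure_id = exposure_id, outcome_id = outcome_id,
            outcome_type = outcome_type, removal_log = removal_log,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  log <- attr(x, "removal_log")
  cat(sprintf("Harmonized set: %s -> %s (%s outcome), %d SNPs\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              attr(x, "outcome_type"), nrow(x)))
  cat("  removed:", paste(sprintf("%s=%d", names(log), log), collapse = ", "),
      "\n")
  NextMethod()
  invisible(x)
}

#' Steiger directionality filtering
#'
#' Guards against reverse causation by removing SNPs that explain more
#' variance in the outcome than in the exposure: per SNP the variance
#' explained ([compute_r2()]) is evaluated on both sides from the
#' harmonized effects, and SNPs with `r2_out > r2_exp` are removed. The
#' comparison is deterministic (no significance test). For binary outcomes
#' the outcome-side quantity is a pseudo-R² on the log-odds scale; see the
#' vignette for this limitation. SNPs lacking `eaf` or `n` on either side
#' cannot be assessed and are removed as `missing_values`.
#'
#' @param set a `harmonized_set` from [harmonize()].
#' @return The filtered `harmonized_set`, with `r2_exp` and `r2_out` columns
#'   attached and `removal_log` updated.
#' @export
steiger_filter <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  log <- attr(set, "removal_log")
  if (nrow(set) == 0L) return(set)
  miss <- is.na(set$eaf_exp) | is.na(set$eaf_out) |
    is.na(set$n_exp) | is.na(set$n_out)
  r2_exp <- rep(NA_real_, nrow(set)); r2_out <- rep(NA_real_, nrow(set))
  if (any(!miss)) {
    r2_exp[!miss] <- compute_r2(set$gamma[!miss], set$eaf_exp[!miss],
                                set$se_gamma[!miss], set$n_exp[!miss])
    r2_out[!miss] <- compute_r2(set$Gamma[!miss], set$eaf_out[!miss],
                                set$se_Gamma[!miss], set$n_out[!miss])
  }
  set$r2_exp <- r2_exp
  set$r2_out <- r2_out
  reverse <- !miss & r2_out > r2_exp
  log["missing_values"] <- log["missing_values"] + sum(miss)
  log["steiger"] <- log["steiger"] + sum(reverse)
  out <- set[!(miss | reverse), , drop = FALSE]
  rownames(out) <- NULL
  new_harmonized_set(out,
                     exposure_id = attr(set, "exposure_id"),
                     outcome_id = attr(set, "outcome_id"),
                     outcome_type = attr(set, "outcome_type"),
                     removal_log = log)
}
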