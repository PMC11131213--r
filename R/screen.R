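#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`; with the conventional `alpha = 0.05` and 1400
#' exposures this is 3.571e-5.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests corrected for (>= 1).
#' @return The per-test p-value threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Screen configuration
#'
#' Bundles every tunable of the exposure-by-outcome screen. Defaults follow
#' standard two-sample MR practice for molecular exposures: instrument
#' p-value screen at 1e-5, LD clumping at r² < 0.001 within 10,000 kb,
#' weak-instrument floor F >= 10, gates at alpha = 0.05.
#'
#' @param pval_threshold instrument p-value screen.
#' @param clump_r2,clump_window_kb LD clumping parameters.
#' @param f_min weak-instrument F floor.
#' @param alpha significance level for gates and nominal tests.
#' @param n_tests number of tests for the Bonferroni tier; `NULL` (default)
#'   means "number of exposures in the screen", the per-outcome correction
#'   used when screening many exposures.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim global-pleiotropy-test simulation rounds.
#' @param seed integer seed (mandatory); per-pair sub-seeds are derived
#'   from it deterministically, so results do not depend on evaluation
#'   order.
#' @param f_filter_stage `"post_steiger"` (default; p-filter, clump,
#'   harmonize, Steiger, then the F filter) or `"pre_harmonize"`.
#' @param strand_flip attempt strand-complement reconciliation in
#'   harmonization.
#' @param random_effects IVW variant (see [mr_fit()]).
#' @return A `screen_config` list.
#' @export
screen_config <- function(pval_threshold = 1e-5, clump_r2 = 0.001,
                          clump_window_kb = 10000, f_min = 10, alpha = 0.05,
                          n_tests = NULL, n_boot = 1000, n_sim = 1000, seed,
                          f_filter_stage = c("post_steiger", "pre_harmonize"),
                          strand_flip = TRUE, random_effects = TRUE) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  f_filter_stage <- match.arg(f_filter_stage)
  stopifnot(pval_threshold > 0, pval_threshold < 1, clump_r2 > 0,
            clump_window_kb > 0, f_min >= 0, alpha > 0, alpha < 1,
            n_boot >= 100, n_sim >= 100)
  structure(list(pval_threshold = pval_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 alpha = alpha, n_tests = n_tests, n_boot = n_boot,
                 n_sim = n_sim, seed = as.integer(seed),
                 f_filter_stage = f_filter_stage, strand_flip = strand_flip,
                 random_effects = random_effects),
            class = "screen_config")
}

#' Two-tier significance classification
#'
#' Applies the screen's decision rule to one analysed pair:
#'
#' 1. `bonferroni_significant` — IVW p below `alpha / n_tests`;
#' 2. else `nominal_significant` — IVW, MR-Egger and weighted-median p all
#'    below `alpha`, all three estimates sharing a sign, and no
#'    heterogeneity or pleiotropy detected (Q, Egger-intercept and
#'    global-test p-values all above `alpha`; a diagnostic that could not
#'    run passes vacuously but is recorded);
#' 3. else `null`; pairs with no surviving instruments are `skipped`.
#'
#' @param pair an `mr_pair_result` from [run_pair()].
#' @param cfg a [screen_config()]; `cfg$n_tests` must be set here.
#' @return `"bonferroni_significant"`, `"nominal_significant"`, `"null"` or
#'   `"skipped"`.
#' @export
classify_pair <- function(pair, cfg) {
  stopifnot(inherits(pair, "mr_pair_result"), inherits(cfg, "screen_config"))
  if (is.null(pair$fit)) return("skipped")
  res <- pair$fit$results
  ivw <- res[res$method %in% c("ivw", "wald"), ]
  if (nrow(ivw) == 0L) return("skipped")
  n_tests <- cfg$n_tests %||% 1
  if (ivw$pval[1] < bonferroni_threshold(cfg$alpha, n_tests))
    return("bonferroni_significant")
  three <- res[res$method %in% c("ivw", "egger", "weighted_median"), ]
  if (nrow(three) < 3L) return("null")
  sens <- pair$sensitivity
  gates <- c(is.na(sens$q_pval) || sens$q_pval > cfg$alpha,
             is.na(sens$egger_intercept_p) ||
               sens$egger_intercept_p > cfg$alpha,
             is.na(sens$presso_global_p) ||
               sens$presso_global_p > cfg$alpha)
  if (all(three$pval < cfg$alpha) &&
      length(unique(sign(three$beta))) == 1L &&
      all(gates)) return("nominal_significant")
  "null"
}

#' Analyse one exposure-outcome pair end to end
#'
#' Runs the full pipeline in order: p-value screen, LD clumping,
#' harmonization, Steiger filtering, weak-instrument removal (stage
#' configurable), the three estimators, sensitivity diagnostics, and the
#' two-tier classification. Any stage that empties the instrument set
#' downgrades the pair to `skipped` with the stage recorded — never an
#' error.
#'
#' @param exposure exposure [sumstats()].
#' @param outcome outcome [sumstats()].
#' @param ld an [ld_table()].
#' @param cfg a [screen_config()].
#' @param seed optional override of `cfg$seed` (used by [run_screen()] for
#'   per-pair sub-seeds).
#' @return An `mr_pair_result`: list with `exposure_id`, `outcome_id`,
#'   `outcome_type`, `fit` ([mr_fit()] or `NULL`), `sensitivity`,
#'   `n_snp_final`, `classification`, `skipped_stage`, `selection_log`,
#'   `removal_log`.
#' @export
run_pair <- function(exposure, outcome, ld, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "screen_config"))
  seed <- seed %||% cfg$seed
  skipped <- function(stage, sel_log = NULL, rem_log = NULL) {
    structure(list(exposure_id = attr(exposure, "trait_id"),
                   outcome_id = attr(outcome, "trait_id"),
                   outcome_type = attr(outcome, "trait_type"),
                   fit = NULL, sensitivity = NULL, n_snp_final = 0L,
                   classification = "skipped", skipped_stage = stage,
                   selection_log = sel_log, removal_log = rem_log),
              class = "mr_pair_result")
  }

  sel <- filter_by_pvalue(exposure, cfg$pval_threshold)
  if (nrow(sel) == 0L) return(skipped("pvalue_filter",
                                      attr(sel, "selection_log")))
  sel <- clump(sel, ld, r2_max = cfg$clump_r2,
               window_kb = cfg$clump_window_kb)
  if (cfg$f_filter_stage == "pre_harmonize") {
    sel <- drop_weak_instruments(attach_instrument_metrics(sel), cfg$f_min)
    if (nrow(sel) == 0L) return(skipped("weak_instruments",
                                        attr(sel, "selection_log")))
  }
  sel_log <- attr(sel, "selection_log")

  h <- harmonize(sel, outcome, strand_flip = cfg$strand_flip)
  if (nrow(h) == 0L) return(skipped("harmonize", sel_log,
                                    attr(h, "removal_log")))
  h <- steiger_filter(h)
  if (nrow(h) == 0L) return(skipped("steiger", sel_log,
                                    attr(h, "removal_log")))
  if (cfg$f_filter_stage == "post_steiger") {
    f <- compute_f(h$r2_exp, h$n_exp, k = 1)
    keep <- f >= cfg$f_min
    rem_log <- attr(h, "removal_log")
    rem_log["weak_instruments"] <- sum(!keep)
    h <- new_harmonized_set(h[keep, , drop = FALSE],
                            exposure_id = attr(h, "exposure_id"),
                            outcome_id = attr(h, "outcome_id"),
                            outcome_type = attr(h, "outcome_type"),
                            removal_log = rem_log)
    if (nrow(h) == 0L) return(skipped("weak_instruments", sel_log,
                                      rem_log))
  }

  methods <- c("ivw",
               if (nrow(h) >= 3) c("egger", "weighted_median"))
  fit <- mr_fit(h, methods = methods, n_boot = cfg$n_boot, seed = seed,
                random_effects = cfg$random_effects, alpha = cfg$alpha)
  sens <- mr_sensitivity(h, n_sim = cfg$n_sim, seed = seed,
                         alpha = cfg$alpha,
                         random_effects = cfg$random_effects)
  pair <- structure(list(exposure_id = attr(h, "exposure_id"),
                         outcome_id = attr(h, "outcome_id"),
                         outcome_type = attr(h, "outcome_type"),
                         fit = fit, sensitivity = sens,
                         n_snp_final = nrow(h),
                         classification = NA_character_,
                         skipped_stage = NA_character_,
                         selection_log = sel_log,
                         removal_log = attr(h, "removal_log")),
                    class = "mr_pair_result")
  pair$classification <- classify_pair(pair, cfg)
  pair
}

#' @export
print.mr_pair_result <- function(x, ...) {
  cat(sprintf("MR pair: %s -> %s [%s]\n", x$exposure_id, x$outcome_id,
              x$classification))
  if (!is.null(x$fit)) print(x$fit, ...)
  else cat("  skipped at stage:", x$skipped_stage, "\n")
  invisible(x)
}

# deterministic sub-seed for pair index i (1-based), independent of
# evaluation order; kept within 32-bit integer range
pair_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 48271 + idx * 7919) %% 2147483647L) + 1L
}

#' Run a full exposure-by-outcome screen
#'
#' Evaluates every exposure against every outcome with [run_pair()], using
#' deterministic per-pair sub-seeds derived from `cfg$seed`, and assembles
#' a long-format results table plus an exposures-by-outcomes matrix of
#' signed significance (the sign of the IVW estimate for significant
#' pairs, 0 otherwise).
#'
#' Unless `cfg$n_tests` is set, the Bonferroni tier corrects for the
#' number of exposures (per outcome).
#'
#' @param exposures named list of exposure [sumstats()] objects.
#' @param outcomes named list of outcome [sumstats()] objects.
#' @param ld an [ld_table()].
#' @param cfg a [screen_config()].
#' @return An `mr_screen` object: list with `pairs` (list of
#'   `mr_pair_result`), `results` (long-format data frame, one row per pair
#'   and method), `matrix` (signed significance), and `cfg`.
#' @export
run_screen <- function(exposures, outcomes, ld, cfg) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            inherits(cfg, "screen_config"))
  if (is.null(cfg$n_tests)) cfg$n_tests <- length(exposures)
  exp_ids <- vapply(exposures, function(x) attr(x, "trait_id"), character(1))
  out_ids <- vapply(outcomes, function(x) attr(x, "trait_id"), character(1))
  pairs <- vector("list", length(exposures) * length(outcomes))
  mat <- matrix(0L, nrow = length(exposures), ncol = length(outcomes),
                dimnames = list(exp_ids, out_ids))
  idx <- 0L
  rows <- list()
  for (i in seq_along(exposures)) {
    for (j in seq_along(outcomes)) {
      idx <- idx + 1L
      pr <- run_pair(exposures[[i]], outcomes[[j]], ld, cfg,
                     seed = pair_seed(cfg$seed, idx))
      pairs[[idx]] <- pr
      if (pr$classification %in% c("bonferroni_significant",
                                   "nominal_significant")) {
        ivw_beta <- pr$fit$results$beta[pr$fit$results$method %in%
                                          c("ivw", "wald")][1]
        mat[i, j] <- as.integer(sign(ivw_beta))
      }
      rows[[idx]] <- pair_long_rows(pr)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(pairs = pairs, results = results, matrix = mat, cfg = cfg),
            class = "mr_screen")
}

pair_long_rows <- function(pr) {
  base <- data.frame(exposure_id = pr$exposure_id,
                     outcome_id = pr$outcome_id,
                     outcome_type = pr$outcome_type,
                     classification = pr$classification,
                     skipped_stage = pr$skipped_stage,
                     n_snp = pr$n_snp_final, stringsAsFactors = FALSE)
  if (is.null(pr$fit)) {
    return(cbind(base, data.frame(method = NA_character_, beta = NA_real_,
                                  se = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_, pval = NA_real_,
                                  or = NA_real_, or_low = NA_real_,
                                  or_high = NA_real_,
                                  q_pval = NA_real_,
                                  egger_intercept_p = NA_real_,
                                  presso_global_p = NA_real_,
                                  stringsAsFactors = FALSE)))
  }
  res <- pr$fit$results
  sens <- pr$sensitivity
  cbind(base[rep(1L, nrow(res)), , drop = FALSE],
        res[c("method", "beta", "se", "ci_low", "ci_high", "pval",
              "or", "or_low", "or_high")],
        data.frame(q_pval = sens$q_pval,
                   egger_intercept_p = sens$egger_intercept_p,
                   presso_global_p = sens$presso_global_p,
                   stringsAsFactors = FALSE))
}

#' @export
print.mr_screen <- function(x, ...) {
  cls <- vapply(x$pairs, function(p) p$classification, character(1))
  cat(sprintf("MR screen: %d exposures x %d outcomes (%d pairs)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$pairs)))
  print(table(classification = cls))
  invisible(x)
}

#' Write screen outputs
#'
#' Emits `results_long.tsv` (one row per pair and method),
#' `matrix.tsv` (signed-significance matrix) and `config.json` into `dir`.
#' Output is byte-identical across re-runs with the same configuration.
#'
#' @param screen an `mr_screen` from [run_screen()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(screen, dir) {
  stopifnot(inherits(screen, "mr_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- screen$results
  num <- vapply(res, is.numeric, logical(1)) &
    !names(res) %in% c("n_snp")
  out <- res
  for (cn in names(res)[num]) out[[cn]] <- format_full(res[[cn]])
  write_tsv_raw(out, file.path(dir, "results_long.tsv"))
  mat <- data.frame(exposure_id = rownames(screen$matrix),
                    screen$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_raw(mat, file.path(dir, "matrix.tsv"))
  cfg <- screen$cfg
  class(cfg) <- NULL
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                              digits = NA),
             file.path(dir, "config.json"))
  invisible(dir)
}

# byte-stable TSV writer (LF endings, NA for missing)
write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "NA"
      x
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
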