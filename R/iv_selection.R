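#' Genome-wide p-value screen for candidate instruments
#'
#' Retains exactly the rows with `pval < threshold` (strict inequality). An
#' empty result is valid: some exposures yield no instruments at the chosen
#' threshold.
#'
#' @param table a [sumstats()] object.
#' @param threshold p-value threshold in (0,1); the default 1e-5 is the
#'   customary relaxed threshold for exposures with few genome-wide
#'   significant hits.
#' @return A [sumstats()] object; the `selection_log` attribute records the
#'   number of rows removed.
#' @export
filter_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "sumstats"), threshold > 0, threshold < 1)
  keep <- table$pval < threshold
  out <- restore_sumstats_attrs(table[keep, , drop = FALSE], table)
  rownames(out) <- NULL
  log <- attr(table, "selection_log") %||% integer()
  log["pvalue_filter"] <- sum(!keep)
  attr(out, "selection_log") <- log
  out
}

#' Greedy LD clumping
#'
#' Prunes correlated SNPs so that retained index SNPs are approximately
#' independent: repeatedly takes the remaining SNP with the smallest p-value
#' as an index (ties broken by chromosome then position) and removes all
#' remaining SNPs on the same chromosome within `window_kb` of it whose LD
#' with it is `r2 >= r2_max`. SNP pairs absent from the LD table are treated
#' as independent. The window never spans chromosomes and is interpreted as
#' +/- `window_kb` around the index position.
#'
#' @param table a [sumstats()] object with positions.
#' @param ld an [ld_table()].
#' @param r2_max LD threshold; SNPs at or above it are removed (default
#'   0.001).
#' @param window_kb half-window in kilobases (default 10000).
#' @return The index SNPs as a [sumstats()] object ordered by (chrom, pos).
#' @export
clump <- function(table, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "sumstats"), inherits(ld, "ld_table"),
            r2_max > 0, r2_max < 1, window_kb > 0)
  if (nrow(table) == 0L) return(table)
  ord <- order(table$pval, table$chrom, table$pos)
  df <- restore_sumstats_attrs(table[ord, , drop = FALSE], table)
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(df))
  index <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    index[i] <- TRUE
    later <- which(alive & seq_len(nrow(df)) > i)
    if (length(later) == 0L) next
    near <- later[df$chrom[later] == df$chrom[i] &
                    abs(df$pos[later] - df$pos[i]) <= window_bp]
    if (length(near) == 0L) next
    r2 <- ld_lookup(ld, df$snp_id[i], df$snp_id[near])
    alive[near[r2 >= r2_max]] <- FALSE
  }
  out <- df[index, , drop = FALSE]
  out <- restore_sumstats_attrs(out[order(out$chrom, out$pos), , drop = FALSE],
                                table)
  rownames(out) <- NULL
  log <- attr(table, "selection_log") %||% integer()
  log["clump"] <- nrow(table) - nrow(out)
  attr(out, "selection_log") <- log
  out
}

#' LD from a genotype-dosage matrix
#'
#' Computes pairwise LD as the squared Pearson correlation of dosage columns
#' (dosages in `[0, 2]`). Zero-variance columns cannot contribute and their
#' pairs are omitted (with a warning).
#'
#' @param genotypes numeric matrix, samples x SNPs.
#' @param snp_ids SNP identifiers, one per column.
#' @return An [ld_table()] over all retained pairs.
#' @export
compute_ld_from_dosages <- function(genotypes, snp_ids = colnames(genotypes)) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 2)
  if (is.null(snp_ids)) stop("snp_ids required")
  stopifnot(length(snp_ids) == ncol(genotypes))
  v <- apply(genotypes, 2, stats::var)
  keep <- v > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance dosage column(s) omitted from LD")
  g <- genotypes[, keep, drop = FALSE]
  ids <- snp_ids[keep]
  if (ncol(g) < 2) return(ld_table())
  r2 <- stats::cor(g)^2
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  ld_table(ids[idx[, 1]], ids[idx[, 2]], r2[idx])
}

#' Variance in the exposure explained by one SNP
#'
#' The per-SNP proportion of trait variance explained,
#' \deqn{R^2 = \frac{2\beta^2 EAF(1-EAF)}
#'  {2\beta^2 EAF(1-EAF) + 2\,SE^2 N\, EAF(1-EAF)},}
#' where the numerator is the variance attributable to the SNP and the
#' denominator adds the residual variance implied by the standard error at
#' sample size N. Symmetric in `eaf` vs `1 - eaf`.
#'
#' @param beta per-allele effect estimate.
#' @param eaf effect-allele frequency in (0,1); required — a missing
#'   frequency is a hard error because the formula needs it.
#' @param se standard error of `beta` (> 0).
#' @param n GWAS sample size (> 0).
#' @return R² in `[0, 1)`; vectorized.
#' @export
compute_r2 <- function(beta, eaf, se, n) {
  if (any(is.na(eaf))) stop("eaf is required to compute variance explained")
  stopifnot(all(eaf > 0 & eaf < 1), all(se > 0), all(n > 0))
  num <- 2 * beta^2 * eaf * (1 - eaf)
  den <- num + 2 * se^2 * n * eaf * (1 - eaf)
  num / den
}

#' Instrument-strength F statistic
#'
#' \deqn{F = \frac{R^2 (N - k - 1)}{k (1 - R^2)}}
#' with `k` the number of instruments sharing the R² (use `k = 1` for a
#' per-SNP F) and `N` the sample size.
#'
#' @param r2 variance explained in `[0, 1)`.
#' @param n sample size; must exceed `k + 1`.
#' @param k number of instruments (default 1).
#' @return F statistic (>= 0); vectorized over `r2`.
#' @export
compute_f <- function(r2, n, k = 1) {
  stopifnot(all(r2 >= 0 & r2 < 1), k >= 1)
  if (any(n <= k + 1)) stop("sample size must exceed k + 1")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Attach per-SNP instrument-strength metrics
#'
#' Adds `r2` (variance explained) and `f_stat` (per-SNP F, `k = 1`) columns,
#' and records the joint F of the whole set (R² summed over SNPs, `k` =
#' number of SNPs) in the `joint_f` attribute.
#'
#' @param table a [sumstats()] object with no missing `eaf`.
#' @return `table` with `r2` and `f_stat` columns and a `joint_f` attribute.
#' @export
attach_instrument_metrics <- function(table) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) == 0L) {
    table$r2 <- numeric(0); table$f_stat <- numeric(0)
    attr(table, "joint_f") <- NA_real_
    return(table)
  }
  table$r2 <- compute_r2(table$beta, table$eaf, table$se, table$n)
  table$f_stat <- compute_f(table$r2, table$n, k = 1)
  k <- nrow(table)
  r2_joint <- min(sum(table$r2), 1 - 1e-12)
  n_min <- min(table$n)
  attr(table, "joint_f") <-
    if (n_min > k + 1) compute_f(r2_joint, n_min, k = k) else NA_real_
  table
}

#' Remove weak instruments
#'
#' Drops SNPs with per-SNP F statistic strictly below `f_min`; an F equal to
#' the floor is retained (the convention "eliminate F < 10").
#'
#' @param table output of [attach_instrument_metrics()].
#' @param f_min weak-instrument floor (default 10).
#' @return Filtered table; `selection_log` updated.
#' @export
drop_weak_instruments <- function(table, f_min = 10) {
  stopifnot(inherits(table, "sumstats"), !is.null(table$f_stat))
  keep <- table$f_stat >= f_min
  out <- restore_sumstats_attrs(table[keep, , drop = FALSE], table)
  rownames(out) <- NULL
  log <- attr(table, "selection_log") %||% integer()
  log["weak_instruments"] <- sum(!keep)
  attr(out, "selection_log") <- log
  attr(out, "joint_f") <- attr(table, "joint_f")
  out
}

#' Select instruments for one exposure
#'
#' Composes the selection stages in order: p-value screen, greedy LD
#' clumping, per-SNP strength metrics, weak-instrument removal. The
#' `selection_log` attribute of the result counts removals per stage.
#'
#' @param table exposure [sumstats()].
#' @param ld an [ld_table()] for clumping.
#' @param pval_threshold,clump_r2,clump_window_kb,f_min stage parameters;
#'   defaults 1e-5, 0.001, 10000 kb, 10.
#' @return A [sumstats()] object with `r2`/`f_stat` columns.
#' @export
select_instruments <- function(table, ld, pval_threshold = 1e-5,
                               clump_r2 = 0.001, clump_window_kb = 10000,
                               f_min = 10) {
  out <- filter_by_pvalue(table, pval_threshold)
  out <- clump(out, ld, r2_max = clump_r2, window_kb = clump_window_kb)
  out <- attach_instrument_metrics(out)
  drop_weak_instruments(out, f_min)
}
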