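#' GWAS summary-statistics tables
#'
#' A `sumstats` object is a data frame of per-SNP association records for one
#' trait, with the canonical columns `snp_id`, `chrom`, `pos` (1-based),
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` and the
#' attributes `trait_id` and `trait_type` (`"binary"` or `"continuous"`;
#' `beta` is a log odds ratio for binary traits and an effect in SD units for
#' standardized continuous traits). Rows are unique on `snp_id`; alleles are
#' single upper-case nucleotides. Missing effect-allele frequency (`eaf`) is
#' tolerated at construction but makes variance-explained and F statistics
#' unavailable downstream.
#'
#' @param records data frame holding the canonical columns above.
#' @param trait_id character scalar identifying the trait.
#' @param trait_type `"binary"` or `"continuous"`; never inferred from data.
#' @param drop_invalid drop (and count) rows violating the per-record
#'   invariants instead of erroring.
#'
#' @return A `sumstats` data frame. The attribute `read_log` counts rows
#'   dropped at construction, by reason.
#' @export
sumstats <- function(records, trait_id, trait_type = c("continuous", "binary"),
                     drop_invalid = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  req <- SUMSTATS_COLUMNS
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(records)[req]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.numeric(df$n)

  log <- c(bad_alleles = 0L, bad_numeric = 0L, duplicate = 0L)
  bad_allele <- !is_nucleotide(df$effect_allele) | !is_nucleotide(df$other_allele) |
    df$effect_allele == df$other_allele
  bad_num <- is.na(df$beta) | is.na(df$se) | df$se <= 0 |
    is.na(df$pval) | df$pval <= 0 | df$pval > 1 |
    is.na(df$n) | df$n <= 0 | is.na(df$pos) |
    (!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1))
  bad <- bad_allele | bad_num
  if (any(bad)) {
    if (!drop_invalid)
      stop(sum(bad), " record(s) violate summary-statistics invariants")
    log["bad_alleles"] <- sum(bad_allele)
    log["bad_numeric"] <- sum(bad_num & !bad_allele)
    df <- df[!bad, , drop = FALSE]
  }
  # duplicate marker ids: keep the smallest p-value (deterministic, mirrors
  # the "most significant record" convention); order-invariant.
  if (anyDuplicated(df$snp_id)) {
    ord <- order(df$pval, df$chrom, df$pos)
    df <- df[ord, , drop = FALSE]
    dup <- duplicated(df$snp_id)
    log["duplicate"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
  }
  # canonical row order: the table is a set of records, so construction is
  # invariant to input permutation
  df <- df[order(df$chrom, df$pos, df$snp_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            trait_id = trait_id, trait_type = trait_type, read_log = log,
            class = c("sumstats", "data.frame"))
}

SUMSTATS_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pval", "n")

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: trait '%s' (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  NextMethod()
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table with a header into a [sumstats()] object.
#' Canonical column names are `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`; dialects are supported
#' through `column_map`. Alleles are upper-cased; rows failing type coercion
#' or the record invariants (non-positive `se`, p-values outside (0,1],
#' multi-character or equal alleles, indels) are dropped and counted in the
#' `read_log` attribute. Duplicate `snp_id`s are resolved by keeping the
#' record with the smallest p-value. Files are UTF-8 with `NA` for missing.
#'
#' @param path path to a tab-separated file with header.
#' @param trait_type `"binary"` or `"continuous"` (mandatory; never guessed).
#' @param trait_id trait identifier; defaults to the file name without
#'   extension.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(snp_id = "rsid", pval = "p")`. Unmapped
#'   canonical names are looked up verbatim.
#'
#' @return A [sumstats()] object.
#' @export
read_sumstats <- function(path, trait_type = c("continuous", "binary"),
                          trait_id = NULL, column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "NA",
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  cmap <- stats::setNames(SUMSTATS_COLUMNS, SUMSTATS_COLUMNS)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_cols <- cmap[!cmap %in% names(raw)]
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- stats::setNames(raw[unname(cmap)], names(cmap))
  suppressWarnings({
    df$pos <- as.numeric(df$pos)
    for (col in c("eaf", "beta", "se", "pval", "n"))
      df[[col]] <- as.numeric(df[[col]])
  })
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  sumstats(df, trait_id = trait_id, trait_type = trait_type)
}

#' Write a GWAS summary-statistics table
#'
#' Writes the canonical tab-separated representation (UTF-8, `NA` for
#' missing, full numeric precision). `read_sumstats(write_sumstats(x))`
#' reproduces `x` on all fields, and the output is byte-identical across
#' repeated writes of the same table.
#'
#' @param table a [sumstats()] object with at least one row.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) == 0L) stop("refusing to write an empty summary-statistics table")
  out <- data.frame(
    snp_id = table$snp_id, chrom = table$chrom, pos = as.integer(table$pos),
    effect_allele = table$effect_allele, other_allele = table$other_allele,
    eaf = format_full(table$eaf), beta = format_full(table$beta),
    se = format_full(table$se), pval = format_full(table$pval),
    n = format_full(table$n),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(SUMSTATS_COLUMNS, collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Validate a summary-statistics table
#'
#' Report-only checks: counts of missing effect-allele frequencies, allele
#' violations (non-ACGT characters, indels, identical alleles) and — under
#' `strict` — records whose stored p-value disagrees with the two-sided
#' normal p-value implied by `beta`/`se` by more than `p_tol`.
#'
#' @param table a [sumstats()] object.
#' @param strict also check p-value/z-score consistency.
#' @param p_tol absolute tolerance on `|pval - 2*pnorm(-|beta/se|)|` in
#'   strict mode. The default 0.01 accommodates p-values rounded for
#'   publication while catching transcription errors.
#' @return A list of class `sumstats_validation` with counts
#'   `missing_eaf`, `allele_violations`, `p_inconsistent` (strict only,
#'   otherwise `NA`) and `n_records`.
#' @export
validate_sumstats <- function(table, strict = FALSE, p_tol = 0.01) {
  stopifnot(inherits(table, "sumstats"))
  bad_allele <- !is_nucleotide(table$effect_allele) |
    !is_nucleotide(table$other_allele) |
    table$effect_allele == table$other_allele
  p_bad <- NA_integer_
  if (strict) {
    p_implied <- two_sided_p(table$beta / table$se)
    p_bad <- sum(abs(table$pval - p_implied) > p_tol, na.rm = TRUE)
  }
  structure(list(n_records = nrow(table),
                 missing_eaf = sum(is.na(table$eaf)),
                 allele_violations = sum(bad_allele),
                 p_inconsistent = p_bad,
                 p_tol = if (strict) p_tol else NA_real_),
            class = "sumstats_validation")
}

#' @export
print.sumstats_validation <- function(x, ...) {
  cat("Summary-statistics validation report\n")
  cat(sprintf("  records:            %d\n", x$n_records))
  cat(sprintf("  missing eaf:        %d\n", x$missing_eaf))
  cat(sprintf("  allele violations:  %d\n", x$allele_violations))
  if (!is.na(x$p_inconsistent))
    cat(sprintf("  p/z inconsistent:   %d (|dp| > %g)\n",
                x$p_inconsistent, x$p_tol))
  invisible(x)
}

#' Pairwise LD tables
#'
#' An `ld_table` stores squared-correlation LD between SNP pairs as a
#' three-column data frame (`snp_a`, `snp_b`, `r2` in `[0,1]`). Pairs are
#' stored once in canonical (sorted-id) orientation; lookups are symmetric
#' and a pair absent from the table is treated as independent (r² = 0).
#'
#' @param snp_a,snp_b character vectors of SNP ids.
#' @param r2 numeric vector of squared correlations in `[0,1]`.
#' @return An `ld_table` data frame.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(), r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_a) == length(r2))
  if (any(!is.na(r2) & (r2 < 0 | r2 > 1))) stop("LD r2 must lie in [0, 1]")
  a <- as.character(snp_a); b <- as.character(snp_b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(snp_a = a, snp_b = b, r2 = as.numeric(r2),
                   stringsAsFactors = FALSE)
  key <- paste(df$snp_a, df$snp_b, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(df$r2, key, function(v) {
      if (max(v) - min(v) > 1e-12)
        stop("conflicting r2 values stored for the same SNP pair")
      v[1]
    })
    df <- df[!duplicated(key), , drop = FALSE]
    df$r2 <- as.numeric(agg[paste(df$snp_a, df$snp_b, sep = "\r")])
  }
  df <- df[order(df$snp_a, df$snp_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ld_table", "data.frame"))
}

#' @rdname ld_table
#' @param path path to a three-column tab-separated file (`snp_a`, `snp_b`,
#'   `r2`) with header.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = "NA", check.names = FALSE,
                           fileEncoding = "UTF-8",
                           colClasses = c("character", "character", "numeric"))
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(raw)))
    stop("LD table must have columns snp_a, snp_b, r2")
  ld_table(raw$snp_a, raw$snp_b, raw$r2)
}

#' @rdname ld_table
#' @param ld an `ld_table`.
#' @export
write_ld_table <- function(ld, path) {
  stopifnot(inherits(ld, "ld_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("snp_a\tsnp_b\tr2", con)
  if (nrow(ld) > 0L)
    writeLines(paste(ld$snp_a, ld$snp_b, format_full(ld$r2), sep = "\t"), con)
  invisible(path)
}

# Symmetric r2 lookup; missing pair => 0 (independent).
ld_lookup <- function(ld, a, b) {
  if (length(a) == 0L) return(numeric(0))
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  tab <- stats::setNames(ld$r2, paste(ld$snp_a, ld$snp_b, sep = "\r"))
  out <- unname(tab[key])
  out[is.na(out)] <- 0
  out
}
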