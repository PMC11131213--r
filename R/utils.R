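# Internal helpers shared across the package.

# Typed error conditions so callers (notably run_pair) can distinguish
# "no usable instruments" from genuine failures.
mr_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mrscreen_error"), call = call))
}

mr_empty_set_error <- function(msg) mr_error(msg, "mr_empty_set")
mr_insufficient_error <- function(msg) mr_error(msg, "mr_insufficient_instruments")
mr_degenerate_error <- function(msg) mr_error(msg, "mr_degenerate_design")

# Run expr with a private RNG stream seeded at `seed`, restoring the caller's
# .Random.seed afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Two-sided normal p-value with underflow guard (p must stay in (0, 1]).
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_nucleotide <- function(x) {
  !is.na(x) & x %in% c("A", "C", "G", "T")
}

# A/T and C/G allele pairs: strand orientation cannot be resolved.
is_palindromic <- function(ea, oa) {
  ok <- is_nucleotide(ea) & is_nucleotide(oa)
  ok & unname(DNA_COMPLEMENT[ifelse(ok, ea, "A")]) == oa
}

complement_allele <- function(x) unname(DNA_COMPLEMENT[x])

# Full-precision numeric formatting for on-disk tables: 17 significant digits
# guarantees exact double round-trip.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# [.data.frame drops custom attributes; copy the sumstats ones back after a
# row subset.
restore_sumstats_attrs <- function(out, from) {
  for (a in c("trait_id", "trait_type", "read_log", "selection_log", "joint_f"))
    attr(out, a) <- attr(from, a)
  class(out) <- class(from)
  out
}
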