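#' Parameters for the paired-GWAS generator
#'
#' Describes one synthetic exposure/outcome pair. The generator works
#' directly on the summary-statistic level: per SNP a minor-allele
#' frequency, a true exposure effect \eqn{\gamma_j} (instruments only), a
#' direct (pleiotropic) outcome effect \eqn{\alpha_j} and the implied true
#' outcome effect \eqn{\Gamma_j = \beta \gamma_j + \alpha_j} are drawn;
#' observed estimates are the truth plus normal noise at the standard error
#' implied by the sample size, \eqn{se_j = 1/\sqrt{2 N p_j(1-p_j)}} for a
#' standardized continuous trait, additionally scaled by
#' \eqn{1/\sqrt{cf(1-cf)}} on the log-odds scale for a binary outcome with
#' case fraction `cf`. Exposure and outcome samples are non-overlapping by
#' construction, so estimate errors are independent across the two tables.
#'
#' Instrument effects are drawn uniformly from `gamma_range` on the
#' exposure-increasing allele (all positive). The default range (0.1, 0.6)
#' in SD units per allele corresponds, at an exposure GWAS of ~8,300
#' samples, to per-SNP F statistics of roughly 20-1000 — the strength range
#' typical of metabolite GWAS instruments.
#'
#' @param m_snps total SNPs in the tables.
#' @param m_instruments SNPs with a nonzero exposure effect (first
#'   `m_instruments` SNPs); remaining SNPs are pure null.
#' @param n_exp exposure GWAS sample size (default 8299).
#' @param n_out outcome GWAS sample size (default 5e5).
#' @param beta_causal true causal effect of exposure on outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects with mean
#'   zero) or `"directional"` (nonzero mean, violating balanced
#'   pleiotropy but preserving InSIDE).
#' @param pleio_mean,pleio_sd mean and SD of the instruments' direct
#'   effects \eqn{\alpha_j}; `pleio_mean` must be 0 unless mode is
#'   `"directional"`.
#' @param gamma_range range of true instrument effects (SD units/allele).
#' @param maf_range allele-frequency range, default (0.05, 0.5).
#' @param ld_blocks `NULL` for mutually independent SNPs, or
#'   `list(block_size =, r2 =)` to group SNPs into LD blocks: SNPs within a
#'   block are co-located (kb apart), share the block's true effects and
#'   are listed in the LD table at the given r²; blocks are distant and
#'   independent.
#' @param outcome_type `"continuous"` or `"binary"` (log-odds effects).
#' @param case_fraction case fraction for binary outcomes (default 0.5).
#' @param outlier_shift displacement, in units of the outcome SE, added to
#'   the first instrument's true outcome effect (default 0; used to plant a
#'   single gross pleiotropic outlier).
#' @param seed integer seed; mandatory, all draws derive from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(m_snps = 26, m_instruments = m_snps, n_exp = 8299,
                       n_out = 5e5, beta_causal = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleio_mean = 0, pleio_sd = 0,
                       gamma_range = c(0.1, 0.6), maf_range = c(0.05, 0.5),
                       ld_blocks = NULL,
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 0.5, outlier_shift = 0, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(m_instruments <= m_snps, n_exp > 2, n_out > 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            case_fraction > 0, case_fraction < 1)
  if (pleiotropy_mode == "balanced" && pleio_mean != 0)
    stop("balanced pleiotropy requires pleio_mean = 0")
  structure(list(m_snps = m_snps, m_instruments = m_instruments,
                 n_exp = n_exp, n_out = n_out, beta_causal = beta_causal,
                 pleiotropy_mode = pleiotropy_mode, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, gamma_range = gamma_range,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 outlier_shift = outlier_shift, seed = as.integer(seed)),
            class = "sim_params")
}

# non-palindromic ordered allele pairs
NONPAL_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulate a paired exposure/outcome GWAS
#'
#' Generates one exposure and one outcome summary-statistics table, the LD
#' table, and the generating truth, per the model described in
#' [sim_params()]. Fully deterministic given `params$seed`. Outcome records
#' have their effect/other alleles swapped (with beta negated and frequency
#' complemented) for a random half of SNPs, exercising harmonization the
#' way independently processed GWAS do.
#'
#' @param params a [sim_params()] object.
#' @param exposure_id,outcome_id trait identifiers for the two tables.
#' @return A list with elements `exposure` and `outcome` ([sumstats()]
#'   objects), `ld` ([ld_table()]), and `truth` — a `sim_truth` list with
#'   `beta_causal`, per-SNP `gamma_true` and `alpha_true`,
#'   `instrument_ids`, and the `params`.
#' @export
simulate_pair <- function(params, exposure_id = "exposure",
                          outcome_id = "outcome") {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  if (p$m_instruments == 0 && p$beta_causal != 0)
    warning("beta_causal is nonzero but no instruments exist; ",
            "the causal effect is unidentifiable from this pair")
  with_seed(p$seed, {
    m <- p$m_snps
    snp_id <- sprintf("rs%07d", seq_len(m))

    # genomic layout: independent SNPs far apart; LD blocks co-located
    if (is.null(p$ld_blocks)) {
      block_of <- seq_len(m)
      offset_in_block <- rep(0L, m)
      block_r2 <- NULL
    } else {
      bs <- p$ld_blocks$block_size
      block_of <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
      offset_in_block <- (seq_len(m) - 1L) %% bs
      block_r2 <- p$ld_blocks$r2
    }
    n_blocks <- max(block_of)
    chrom <- as.character(((block_of - 1L) %% 22L) + 1L)
    pos <- 1e6L + ((block_of - 1L) %/% 22L) * 2e7L + offset_in_block * 5000L

    maf <- stats::runif(m, p$maf_range[1], p$maf_range[2])
    # instruments: the first m_instruments blocks carry a shared effect
    # (without LD blocks every SNP is its own block)
    iv_block <- seq_len(n_blocks) <= p$m_instruments
    gamma_block <- ifelse(iv_block,
                          stats::runif(n_blocks, p$gamma_range[1],
                                       p$gamma_range[2]), 0)
    alpha_block <- rep(0, n_blocks)
    if (p$pleiotropy_mode != "none")
      alpha_block[iv_block] <- stats::rnorm(sum(iv_block),
                                            mean = p$pleio_mean,
                                            sd = p$pleio_sd)
    gamma_true <- gamma_block[block_of]
    alpha_true <- alpha_block[block_of]

    se_exp <- 1 / sqrt(2 * p$n_exp * maf * (1 - maf))
    se_out <- 1 / sqrt(2 * p$n_out * maf * (1 - maf))
    if (p$outcome_type == "binary")
      se_out <- se_out / sqrt(p$case_fraction * (1 - p$case_fraction))

    Gamma_true <- p$beta_causal * gamma_true + alpha_true
    if (p$outlier_shift != 0 && p$m_instruments >= 1)
      Gamma_true[match(1L, block_of)] <-
        Gamma_true[match(1L, block_of)] + p$outlier_shift * se_out[match(1L, block_of)]

    beta_exp <- stats::rnorm(m, gamma_true, se_exp)
    beta_out <- stats::rnorm(m, Gamma_true, se_out)

    pair_idx <- sample.int(nrow(NONPAL_PAIRS), m, replace = TRUE)
    ea <- NONPAL_PAIRS[pair_idx, 1]; oa <- NONPAL_PAIRS[pair_idx, 2]

    exposure <- sumstats(data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_exp, se = se_exp,
      pval = two_sided_p(beta_exp / se_exp), n = p$n_exp,
      stringsAsFactors = FALSE), trait_id = exposure_id,
      trait_type = "continuous")

    swap <- stats::runif(m) < 0.5
    out_ea <- ifelse(swap, oa, ea)
    out_oa <- ifelse(swap, ea, oa)
    outcome <- sumstats(data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = out_ea, other_allele = out_oa,
      eaf = ifelse(swap, 1 - maf, maf),
      beta = ifelse(swap, -beta_out, beta_out), se = se_out,
      pval = two_sided_p(beta_out / se_out), n = p$n_out,
      stringsAsFactors = FALSE), trait_id = outcome_id,
      trait_type = p$outcome_type)

    ld <- if (is.null(block_r2)) ld_table() else {
      pairs <- do.call(rbind, lapply(split(seq_len(m), block_of), function(ix) {
        if (length(ix) < 2) return(NULL)
        cmb <- utils::combn(ix, 2)
        data.frame(a = snp_id[cmb[1, ]], b = snp_id[cmb[2, ]])
      }))
      if (is.null(pairs)) ld_table()
      else ld_table(pairs$a, pairs$b, rep(block_r2, nrow(pairs)))
    }

    truth <- structure(list(
      beta_causal = p$beta_causal,
      gamma_true = stats::setNames(gamma_true, snp_id),
      alpha_true = stats::setNames(alpha_true, snp_id),
      instrument_ids = snp_id[gamma_true != 0],
      params = p), class = "sim_truth")

    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

#' Named simulation presets
#'
#' Ready-made [sim_params()] describing the scenarios the estimators and
#' diagnostics are validated against:
#'
#' * `null` — no causal effect, no pleiotropy; type-I-error calibration.
#' * `causal` — beta = 0.2 with 50 strong instruments and a large outcome
#'   GWAS (n = 5e5); parameter recovery and CI coverage.
#' * `balanced_pleiotropy` — direct effects with mean zero (InSIDE holds):
#'   IVW remains unbiased, Egger intercept centered on zero.
#' * `directional_pleiotropy` — direct effects with mean 0.02: IVW biased,
#'   Egger intercept centered on 0.02.
#' * `weak_instruments` — instrument effects straddling the F = 10 floor.
#' * `one_outlier` — one instrument's outcome effect displaced by 10 SEs, a
#'   gross pleiotropic outlier for the global RSS test.
#'
#' @param seed integer seed stored in every preset.
#' @return Named list of [sim_params()].
#' @export
scenario_suite <- function(seed = 1) {
  list(
    null = sim_params(m_snps = 26, beta_causal = 0, seed = seed),
    causal = sim_params(m_snps = 50, beta_causal = 0.2, n_out = 5e5,
                        seed = seed),
    balanced_pleiotropy = sim_params(m_snps = 26, beta_causal = 0,
                                     pleiotropy_mode = "balanced",
                                     pleio_sd = 0.01, seed = seed),
    directional_pleiotropy = sim_params(m_snps = 26, beta_causal = 0,
                                        pleiotropy_mode = "directional",
                                        pleio_mean = 0.02, pleio_sd = 0.01,
                                        seed = seed),
    weak_instruments = sim_params(m_snps = 26, beta_causal = 0,
                                  gamma_range = c(0.02, 0.12), seed = seed),
    one_outlier = sim_params(m_snps = 26, beta_causal = 0.1,
                             outlier_shift = 10, seed = seed)
  )
}

#' Simulate a genotype-dosage matrix
#'
#' Small Hardy-Weinberg dosage generator (values 0/1/2 plus optional
#' within-block correlation) used to exercise [compute_ld_from_dosages()].
#'
#' @param n_samples,n_snps matrix dimensions.
#' @param maf allele frequency (scalar or per-SNP).
#' @param seed integer seed.
#' @return Numeric matrix `n_samples x n_snps` with `rs`-style column names.
#' @export
simulate_dosages <- function(n_samples, n_snps, maf = 0.3, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  maf <- rep_len(maf, n_snps)
  with_seed(seed, {
    g <- vapply(seq_len(n_snps), function(j)
      stats::rbinom(n_samples, 2L, maf[j]), numeric(n_samples))
    colnames(g) <- sprintf("rs%07d", seq_len(n_snps))
    g
  })
}
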