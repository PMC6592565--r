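#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator: genotype panel
#' dimensions and LD structure, the causal architecture shared across three
#' disease subtypes, phenome composition, the discovery-cohort GWAS, and the
#' corruption rates used to exercise summary-statistic quality control.
#'
#' Defaults describe the study conditions the rest of the package is tested
#' under: six causal loci shared by all three subtypes (mirroring the number
#' of shared skin-cancer risk loci the analysis design targets), ten loci
#' unique to each subtype, block-LD genotypes, subtype prevalences of a few
#' percent, two genetically correlated secondary traits, one secondary trait
#' mediated purely by the primary disease, and a bed of independent null
#' diagnosis codes.
#'
#' @param n_subjects Number of target-cohort subjects.
#' @param n_variants Number of variants on the panel.
#' @param block_size Variants per LD block.
#' @param within_block_r Target pairwise dosage correlation within a block,
#'   in `[0, 1)`.
#' @param maf_range Interval in `(0, 0.5]` from which each block's minor
#'   allele frequency is drawn (constant within a block; see Details).
#' @param n_shared_causal Causal loci shared by all three subtypes.
#' @param n_unique_causal_per_subtype Causal loci unique to each subtype.
#' @param effect_sd Standard deviation of causal per-allele log odds ratios.
#' @param base_prevalence Named numeric of length 3: target marginal
#'   prevalence per subtype, each in `(0, 1)`.
#' @param n_secondary_traits Secondary traits generated from the shared
#'   genetic score (genetically correlated with the subtypes).
#' @param n_mediated_traits Secondary traits caused by the primary disease
#'   itself rather than by genotype (exercise the exclusion scan).
#' @param n_null_codes Independent null diagnosis codes.
#' @param discovery_n Sample size of the independent discovery cohort used
#'   for the simulated GWAS.
#' @param qc_injection_rates Named numeric with elements `strand_flip`,
#'   `raf_error`, `ambiguous`, each in `[0, 1]`: per-row corruption
#'   probabilities applied to the discovery summary statistics.
#' @param seed Integer seed; a fixed config reproduces byte-identical output.
#'
#' @details Each LD block occupies under 1 Mb; consecutive blocks are placed
#'   more than 1 Mb apart so that clumping windows separate them. Minor
#'   allele frequency is drawn once per block because the haplotype-copy LD
#'   model that delivers an exact target correlation requires a common
#'   allele frequency within the block.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 5000,
                       n_variants = 400,
                       block_size = 10,
                       within_block_r = 0.5,
                       maf_range = c(0.05, 0.5),
                       n_shared_causal = 6,
                       n_unique_causal_per_subtype = 10,
                       effect_sd = 0.3,
                       base_prevalence = c(melanoma = 0.05,
                                           bcc = 0.06,
                                           scc = 0.04),
                       n_secondary_traits = 2,
                       n_mediated_traits = 1,
                       n_null_codes = 20,
                       discovery_n = 20000,
                       qc_injection_rates = c(strand_flip = 0.05,
                                              raf_error = 0.02,
                                              ambiguous = 0.05),
                       seed = 42L) {
  stopifnot_count(n_subjects, "n_subjects")
  stopifnot_count(n_variants, "n_variants")
  stopifnot_count(block_size, "block_size")
  stopifnot_count(discovery_n, "discovery_n")
  if (!is.numeric(within_block_r) || within_block_r < 0 || within_block_r >= 1)
    stop("'within_block_r' must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be an interval within (0, 0.5]")
  if (length(base_prevalence) != 3 || is.null(names(base_prevalence)) ||
      any(base_prevalence <= 0) || any(base_prevalence >= 1))
    stop("'base_prevalence' must be 3 named probabilities in (0, 1)")
  need <- c("strand_flip", "raf_error", "ambiguous")
  if (!all(need %in% names(qc_injection_rates)) ||
      any(qc_injection_rates[need] < 0) || any(qc_injection_rates[need] > 1))
    stop("'qc_injection_rates' needs strand_flip/raf_error/ambiguous in [0, 1]")
  if (n_shared_causal + 3 * n_unique_causal_per_subtype > n_variants)
    stop("causal loci exceed n_variants: need n_shared_causal + ",
         "3 * n_unique_causal_per_subtype <= n_variants")
  n_blocks <- ceiling(n_variants / block_size)
  if (n_shared_causal + 3 * n_unique_causal_per_subtype > n_blocks)
    stop("causal loci must come from distinct LD blocks: increase n_variants ",
         "or decrease block_size")
  if (effect_sd <= 0) stop("'effect_sd' must be positive")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_variants = as.integer(n_variants),
    block_size = as.integer(block_size),
    within_block_r = within_block_r,
    maf_range = maf_range,
    n_shared_causal = as.integer(n_shared_causal),
    n_unique_causal_per_subtype = as.integer(n_unique_causal_per_subtype),
    effect_sd = effect_sd,
    base_prevalence = base_prevalence,
    n_secondary_traits = as.integer(n_secondary_traits),
    n_mediated_traits = as.integer(n_mediated_traits),
    n_null_codes = as.integer(n_null_codes),
    discovery_n = as.integer(discovery_n),
    qc_injection_rates = qc_injection_rates[need],
    seed = as.integer(seed)
  ), class = "sim_config")
}

subtype_names <- function(config) names(config$base_prevalence)
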