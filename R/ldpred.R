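# Point-normal posterior reweighting of marginal GWAS effects under
# windowed LD: the infinitesimal closed form and a Gibbs sampler.
#
# Internally effects live on the standardized-genotype scale
# (beta_std = beta_allele * sqrt(2 p q)); output weights are
# back-transformed to the per-allele scale.

#' LDpred configuration
#'
#' @param causal_fractions Prior proportions of causal variants (the six
#'   fractions 100%, 10%, 1%, 0.1%, 0.01%, 0.001% by default).
#' @param radius_snps LD radius in SNPs to each side (default 2,800,
#'   matching an average 1 Mb window at genome-wide density).
#' @param n_gwas GWAS sample size (`NULL`: taken from the effects table).
#' @param h2 Trait heritability on the observed scale, or `"auto"` to
#'   estimate it with [estimate_h2_aggregate()].
#' @param burn_in Discarded Gibbs sweeps (default 100).
#' @param iterations Post-burn-in Gibbs sweeps averaged into the posterior
#'   mean (default 1,000).
#' @param seed RNG seed for the sampler.
#' @return List of class `ldpred_config`.
#' @export
ldpred_config <- function(causal_fractions = c(1, 0.1, 0.01, 1e-3, 1e-4, 1e-5),
                          radius_snps = 2800, n_gwas = NULL, h2 = "auto",
                          burn_in = 100, iterations = 1000, seed = 1L) {
  if (any(causal_fractions <= 0) || any(causal_fractions > 1))
    stop("causal fractions must lie in (0, 1]")
  if (radius_snps < 1) stop("radius_snps must be >= 1")
  structure(list(causal_fractions = causal_fractions,
                 radius_snps = as.integer(radius_snps), n_gwas = n_gwas,
                 h2 = h2, burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "ldpred_config")
}

#' LDpred default input filters
#'
#' Keeps SNPs (single-base alleles) present in the summary statistics, the
#' LD reference panel and the target panel, with MAF > 1% and non-ambiguous
#' allele combinations, and computes standardized marginal effects.
#'
#' @param stats `summary_stats` data.frame.
#' @param ld_variants Variant table of the LD reference panel.
#' @param target_variants Variant table of the target panel (default: same
#'   as the LD reference).
#' @return data.frame of class `marginal_effects`: `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `n`, `beta` (per-allele),
#'   `beta_std`, `se`, `p`, coordinate-sorted.
#' @export
filter_ldpred_input <- function(stats, ld_variants,
                                target_variants = ld_variants) {
  snp <- is_snp_allele(stats$EFFECT_ALLELE) & is_snp_allele(stats$OTHER_ALLELE)
  amb <- snp & is_ambiguous_pair(stats$EFFECT_ALLELE, stats$OTHER_ALLELE)
  maf <- pmin(stats$EAF, 1 - stats$EAF)
  keep <- snp & !amb & maf > 0.01 &
    stats$ID %in% ld_variants$id & stats$ID %in% target_variants$id
  s <- stats[keep, , drop = FALSE]
  if (!nrow(s)) stop("no variants survive the LDpred input filters")
  s <- s[order(s$CHROM, s$POS), , drop = FALSE]
  # standardized effect via z / sqrt(N): equals beta * sd(G) for a unit-
  # variance trait, and makes the sampling noise variance exactly 1/N for
  # binary-trait log odds ratios as well
  structure(data.frame(
    id = s$ID, chrom = s$CHROM, pos = s$POS,
    effect_allele = s$EFFECT_ALLELE, other_allele = s$OTHER_ALLELE,
    eaf = s$EAF, n = s$N, beta = s$BETA,
    beta_std = (s$BETA / s$SE) / sqrt(s$N),
    se = s$SE, p = s$P, stringsAsFactors = FALSE
  ), class = c("marginal_effects", "data.frame"))
}

#' Aggregate heritability estimate from summary statistics
#'
#' LD-score-style moment estimator: `h2 = M (mean chi2 - 1) / (N mean l)`
#' where `l` is the within-window LD score. Clamped to `[0.01, 0.99]` with a
#' warning outside that range.
#'
#' @param effects A `marginal_effects` table (or any data.frame with
#'   `beta`, `se`).
#' @param ld An `ld_panel` aligned to `effects`.
#' @param n GWAS sample size.
#' @return Scalar heritability estimate.
#' @export
estimate_h2_aggregate <- function(effects, ld, n) {
  if (nrow(effects) < 100) stop("need at least 100 variants")
  idx <- match(effects$id, ld$ids)
  if (anyNA(idx)) stop("effects and LD panel are misaligned")
  chi2 <- (effects$beta / effects$se)^2
  lsc <- rowSums(ld$r[idx, idx, drop = FALSE]^2)
  if (mean(lsc) <= 0) stop("degenerate LD panel")
  h2 <- nrow(effects) * (mean(chi2) - 1) / (n * mean(lsc))
  if (is.na(h2)) stop("heritability estimate undefined")
  if (h2 < 0.01 || h2 > 0.99) {
    warning(sprintf("aggregate h2 estimate %.3f outside [0.01, 0.99]; clamped",
                    h2))
    h2 <- min(max(h2, 0.01), 0.99)
  }
  h2
}

# Banded LD matrix (radius in SNPs) aligned to `effects`.
banded_ld <- function(effects, ld, radius) {
  idx <- match(effects$id, ld$ids)
  if (anyNA(idx)) stop("effects and LD panel are misaligned")
  D <- ld$r[idx, idx, drop = FALSE]
  m <- nrow(D)
  if (radius < m - 1) {
    off <- abs(outer(seq_len(m), seq_len(m), "-"))
    D[off > radius] <- 0
  }
  diag(D) <- 1
  D
}

#' Infinitesimal-prior posterior mean weights
#'
#' Closed-form posterior under the infinitesimal model: the standardized
#' weights solve `(M / (N h2) I + D) w = beta_std`, with `D` the banded LD
#' matrix within the radius. With identity LD this is the scalar shrinkage
#' `N h2 / (N h2 + M)`.
#'
#' @param effects A `marginal_effects` table.
#' @param ld An `ld_panel`.
#' @param h2 Heritability (scalar).
#' @param n GWAS sample size (default: from `effects`).
#' @param radius_snps LD radius in SNPs (default 2,800).
#' @return `effects` with columns `weight_std` (standardized scale) and
#'   `weight` (per-allele scale) appended.
#' @export
ldpred_inf <- function(effects, ld, h2, n = NULL, radius_snps = 2800) {
  n <- n %||% effects$n[1]
  m <- nrow(effects)
  D <- banded_ld(effects, ld, radius_snps)
  A <- D + diag(m / (n * h2), m)
  w <- tryCatch(solve(A, effects$beta_std), error = function(e) {
    message("near-singular LD system; adding ridge jitter 1e-6")
    solve(A + diag(1e-6, m), effects$beta_std)
  })
  effects$weight_std <- drop(w)
  effects$weight <- effects$weight_std * effects$se * sqrt(effects$n)
  effects
}

#' Point-normal Gibbs posterior mean weights
#'
#' Markov-chain sweep over variants: each variant's marginal effect is
#' residualized against the current effects of its neighbors within the LD
#' radius; under a point-normal prior with the given causal fraction the
#' inclusion indicator and effect are sampled, and post-burn-in samples are
#' averaged. Deterministic given `cfg$seed`.
#'
#' @param effects A `marginal_effects` table.
#' @param ld An `ld_panel`.
#' @param cfg An [ldpred_config()]; `cfg$h2 = "auto"` triggers
#'   [estimate_h2_aggregate()].
#' @param fraction Causal fraction to use (must be one of
#'   `cfg$causal_fractions`).
#' @return `effects` with `weight_std`, `weight` and `weight_mcse` (per-
#'   variant Monte-Carlo standard error from the chain) appended; attribute
#'   `h2` records the heritability used.
#' @export
ldpred_gibbs <- function(effects, ld, cfg = ldpred_config(), fraction = 1) {
  stopifnot(inherits(cfg, "ldpred_config"))
  if (!any(abs(fraction - cfg$causal_fractions) < 1e-12))
    stop("'fraction' must be one of cfg$causal_fractions")
  n <- cfg$n_gwas %||% effects$n[1]
  h2 <- cfg$h2
  if (identical(h2, "auto")) h2 <- estimate_h2_aggregate(effects, ld, n)
  m <- nrow(effects)
  D <- banded_ld(effects, ld, cfg$radius_snps)
  res <- with_seed(cfg$seed, {
    gibbs_point_normal(D, effects$beta_std, as.numeric(n), as.numeric(h2),
                       as.numeric(fraction), cfg$burn_in, cfg$iterations)
  })
  if (res$diverged)
    stop("Gibbs sampler diverged: running h2 of sampled effects exceeded ",
         "1.5x the prior h2 (", format(res$max_h2, digits = 3),
         "); check N, h2 and LD inputs")
  effects$weight_std <- res$mean
  effects$weight_mcse <- res$mcse
  effects$weight <- effects$weight_std * effects$se * sqrt(effects$n)
  attr(effects, "h2") <- h2
  effects
}

#' Package LDpred weights as a PRS model
#'
#' @param effects Output of [ldpred_inf()] or [ldpred_gibbs()].
#' @param method_tag Tag stored on the model (e.g. `"ldpred@0.01"`).
#' @param trait_label Trait label.
#' @return A [prs_model()] using the per-allele `weight` column.
#' @export
ldpred_prs_model <- function(effects, method_tag = "ldpred@1",
                             trait_label = "trait") {
  prs_model(data.frame(
    variant_id = effects$id, chrom = effects$chrom, pos = effects$pos,
    effect_allele = effects$effect_allele, other_allele = effects$other_allele,
    weight = effects$weight, p_value = effects$p, stringsAsFactors = FALSE
  ), method_tag = method_tag, trait_label = trait_label)
}
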