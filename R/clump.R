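# Windowed LD panel and greedy clumping with p-value thresholding.

#' Clumping configuration
#'
#' @param p_entry Entry threshold for clumping (strict `<`, default 5e-4).
#' @param r2_threshold LD threshold above which neighbors are removed
#'   (default 0.1).
#' @param window_bp Maximum distance at which LD is considered (default
#'   1 Mb).
#' @param maf_min Minimum minor allele frequency (default 0.5%).
#' @param thresholds p-value thresholds for the nested model subsets.
#' @return List of class `clump_config`.
#' @export
clump_config <- function(p_entry = 5e-4, r2_threshold = 0.1,
                         window_bp = 1e6, maf_min = 0.005,
                         thresholds = c(5e-9, 5e-8, 5e-7, 5e-6, 5e-5, 5e-4)) {
  if (any(thresholds <= 0) || any(thresholds > p_entry))
    stop("thresholds must lie in (0, p_entry]")
  structure(list(p_entry = p_entry, r2_threshold = r2_threshold,
                 window_bp = window_bp, maf_min = maf_min,
                 thresholds = sort(thresholds)), class = "clump_config")
}

#' Windowed pairwise LD from dosages
#'
#' Signed Pearson correlation between dosage vectors for variant pairs on
#' the same chromosome within `window_bp`; everything else is treated as
#' r = 0. Zero-variance (monomorphic) variants get r = 0 with a warning.
#'
#' @param geno A `dosage_data` object (the LD reference).
#' @param window_bp Distance window (default 1 Mb).
#' @param subject_ids Reference subject subset (default: all subjects).
#' @param variant_ids Restrict the panel to these variants (default: all).
#' @return Object of class `ld_panel`: list with `ids`, `chrom`, `pos`, and
#'   the windowed signed correlation matrix `r`.
#' @export
compute_ld <- function(geno, window_bp = 1e6, subject_ids = NULL,
                       variant_ids = NULL) {
  v <- geno$variants
  if (!is.null(variant_ids)) {
    idx <- match(variant_ids, v$id)
    if (anyNA(idx)) stop("unknown variant(s) in 'variant_ids'")
    v <- v[idx, , drop = FALSE]
  }
  rows <- subject_ids %||% rownames(geno$dosages)
  if (length(rows) < 2) stop("need at least 2 reference subjects")
  d <- geno$dosages[rows, v$id, drop = FALSE]
  sds <- apply(d, 2, sd)
  mono <- sds == 0
  if (any(mono))
    warning(sum(mono), " zero-variance variant(s); their LD recorded as 0")
  r <- suppressWarnings(cor(d))
  r[is.na(r)] <- 0
  diag(r) <- 1
  same_chr <- outer(v$chrom, v$chrom, "==")
  near <- abs(outer(v$pos, v$pos, "-")) <= window_bp
  r[!(same_chr & near)] <- 0
  diag(r) <- 1
  structure(list(ids = v$id, chrom = v$chrom, pos = v$pos, r = r),
            class = "ld_panel")
}

# r^2 between two variants by ID (0 when either is absent from the panel).
ld_r2 <- function(ld, id1, id2) {
  i <- match(id1, ld$ids); j <- match(id2, ld$ids)
  if (is.na(i) || is.na(j)) return(0)
  ld$r[i, j]^2
}

#' Greedy LD clumping of summary statistics
#'
#' Restricts to variants with minor allele frequency above `cfg$maf_min`,
#' p below `cfg$p_entry` (strict) and present on the LD panel, then greedily
#' takes the smallest-p remaining variant (ties broken by chromosome then
#' position) and removes all others with r^2 above `cfg$r2_threshold`
#' within `cfg$window_bp` on the same chromosome.
#'
#' @param stats `summary_stats` data.frame.
#' @param ld An `ld_panel` covering (at least) the candidate variants.
#' @param cfg A [clump_config()].
#' @return Character vector of retained index-variant IDs, coordinate-
#'   sorted; attribute `report` is a data.frame with the number of removed
#'   neighbors and the strongest removed r^2 per index variant.
#' @export
ld_clump <- function(stats, ld, cfg = clump_config()) {
  maf <- pmin(stats$EAF, 1 - stats$EAF)
  cand <- stats[maf > cfg$maf_min & stats$P < cfg$p_entry &
                  stats$ID %in% ld$ids, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no variants pass the MAF/p-entry filters")
    out <- character(0)
    attr(out, "report") <- data.frame(index = character(0),
                                      n_removed = integer(0),
                                      max_removed_r2 = numeric(0))
    return(out)
  }
  ord <- order(cand$P, cand$CHROM, cand$POS)
  cand <- cand[ord, , drop = FALSE]
  li <- match(cand$ID, ld$ids)
  active <- rep(TRUE, nrow(cand))
  kept <- integer(0)
  rep_rows <- list()
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    kept <- c(kept, i)
    active[i] <- FALSE
    nb <- which(active)
    if (length(nb)) {
      r2 <- ld$r[li[i], li[nb]]^2
      same <- ld$chrom[li[nb]] == ld$chrom[li[i]] &
        abs(ld$pos[li[nb]] - ld$pos[li[i]]) <= cfg$window_bp
      drop <- nb[same & r2 > cfg$r2_threshold]
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        index = cand$ID[i], n_removed = length(drop),
        max_removed_r2 = if (length(drop)) max(ld$r[li[i], li[drop]]^2) else 0,
        stringsAsFactors = FALSE)
      active[drop] <- FALSE
    } else {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        index = cand$ID[i], n_removed = 0L, max_removed_r2 = 0,
        stringsAsFactors = FALSE)
    }
  }
  kept_df <- cand[kept, , drop = FALSE]
  out <- kept_df$ID[order(kept_df$CHROM, kept_df$POS)]
  attr(out, "report") <- do.call(rbind, rep_rows)
  out
}

#' Nested p-value threshold subsets of clumped variants
#'
#' @param clumped Index-variant IDs from [ld_clump()].
#' @param stats The summary statistics the clumping ran on.
#' @param cfg A [clump_config()]; one model per `cfg$thresholds` entry.
#' @param trait_label Label stored on the returned models.
#' @return Named list of [prs_model()]s (names like `"5e-08"`), nested:
#'   the model at a smaller threshold is a subset of any larger one.
#'   Weights are the summary-statistic log odds ratios.
#' @export
threshold_subsets <- function(clumped, stats, cfg = clump_config(),
                              trait_label = "trait") {
  s <- stats[match(clumped, stats$ID), , drop = FALSE]
  out <- list()
  for (t in cfg$thresholds) {
    sub <- s[s$P < t, , drop = FALSE]
    out[[format(t)]] <- prs_model(data.frame(
      variant_id = sub$ID, chrom = sub$CHROM, pos = sub$POS,
      effect_allele = sub$EFFECT_ALLELE, other_allele = sub$OTHER_ALLELE,
      weight = sub$BETA, p_value = sub$P, stringsAsFactors = FALSE
    ), method_tag = sprintf("clump_threshold@%s", format(t)),
    trait_label = trait_label)
  }
  out
}
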