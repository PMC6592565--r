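# Harmonization and QC of external association sources.
#
# Strand logic: panel alleles are forward-strand.  If the reported risk
# allele matches a panel allele it is kept as-is.  If the panel variant is
# non-ambiguous (not A/T or C/G) and the complement of the risk allele
# matches, minus-strand reporting is assumed and the effect allele is
# corrected to the complementary base.  Ambiguous panel variants whose
# alleles do not match the report cannot be resolved and are excluded.

EXCLUSION_REASONS <- c("missing_fields", "ambiguous_mismatch",
                       "no_allele_match", "raf_deviation", "non_european",
                       "not_in_panel")

#' Harmonize one catalog entry against a panel variant
#'
#' @param entry A list/one-row data.frame with `variant_id`, `risk_allele`,
#'   `raf`, `odds_ratio`, `p_value`, `pub_date`, and optionally
#'   `ancestry_label`.
#' @param variant A one-row variant record with forward-strand alleles `a1`,
#'   `a2` (and `chrom`, `pos`).
#' @return A one-row data.frame: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight` (log odds ratio), `p_value`,
#'   `pub_date`, `exclusion_reason` (NA when kept).
#' @export
harmonize_alleles <- function(entry, variant) {
  reason <- NA_character_
  eff <- NA_character_
  oth <- NA_character_
  risk <- toupper(entry$risk_allele %||% NA_character_)
  if (is.na(risk) || is.na(entry$raf %||% NA) ||
      is.na(entry$odds_ratio %||% NA)) {
    reason <- "missing_fields"
  } else if (!is.null(entry$ancestry_label) && !is.na(entry$ancestry_label) &&
             !grepl("European", entry$ancestry_label, ignore.case = TRUE)) {
    reason <- "non_european"
  } else {
    if (!risk %in% BASES) stop("malformed risk allele: ", risk)
    a1 <- toupper(variant$a1); a2 <- toupper(variant$a2)
    if (!all(c(a1, a2) %in% BASES))
      stop("malformed panel alleles for ", variant$id %||% entry$variant_id)
    ambiguous <- is_ambiguous_pair(a1, a2)
    if (risk == a1) { eff <- a1; oth <- a2 }
    else if (risk == a2) { eff <- a2; oth <- a1 }
    else if (!ambiguous && complement_base(risk) == a1) { eff <- a1; oth <- a2 }
    else if (!ambiguous && complement_base(risk) == a2) { eff <- a2; oth <- a1 }
    else if (ambiguous) reason <- "ambiguous_mismatch"
    else reason <- "no_allele_match"
  }
  data.frame(
    variant_id = entry$variant_id,
    chrom = variant$chrom %||% NA_character_,
    pos = variant$pos %||% NA_integer_,
    effect_allele = eff,
    other_allele = oth,
    weight = if (is.na(reason)) log(entry$odds_ratio) else NA_real_,
    raf = entry$raf %||% NA_real_,
    p_value = entry$p_value %||% NA_real_,
    pub_date = as.Date(entry$pub_date %||% NA),
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Harmonize a catalog table against a variant panel
#'
#' Vectorised driver for [harmonize_alleles()]; entries whose variant is not
#' on the panel are excluded with reason `not_in_panel`. The result carries
#' one row per input entry (the harmonization audit).
#'
#' @param entries data.frame of catalog entries (see [harmonize_alleles()]).
#' @param variants Panel variant table (`id`, `chrom`, `pos`, `a1`, `a2`).
#' @return data.frame, one row per entry, with `exclusion_reason` NA for
#'   kept rows.
#' @export
harmonize_catalog <- function(entries, variants) {
  idx <- match(entries$variant_id, variants$id)
  out <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, , drop = FALSE]
    if (is.na(idx[i])) {
      out[[i]] <- data.frame(
        variant_id = e$variant_id, chrom = NA_character_, pos = NA_integer_,
        effect_allele = NA_character_, other_allele = NA_character_,
        weight = NA_real_, raf = e$raf %||% NA_real_,
        p_value = e$p_value %||% NA_real_,
        pub_date = as.Date(e$pub_date %||% NA),
        exclusion_reason = "not_in_panel", stringsAsFactors = FALSE)
    } else {
      out[[i]] <- harmonize_alleles(as.list(e), variants[idx[i], , drop = FALSE])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Risk-allele-frequency deviation filter
#'
#' Drops harmonized entries whose reported risk allele frequency deviates
#' from the control-cohort frequency of the (harmonized) effect allele by
#' more than `threshold` in allele-frequency units.
#'
#' @param harmonized Output of [harmonize_catalog()] (kept rows are checked;
#'   already-excluded rows pass through unchanged).
#' @param control_raf Named numeric: control-cohort frequency of the effect
#'   allele per variant_id (see [effect_allele_freq()]; computed on females
#'   only for chromosome X).
#' @param threshold Maximum absolute deviation (default 0.15).
#' @return `harmonized` with `exclusion_reason` set to `raf_deviation` where
#'   the rule fires, and a `control_raf` column appended. Rows with no
#'   available control frequency are dropped with the same reason and a
#'   warning.
#' @export
filter_raf <- function(harmonized, control_raf, threshold = 0.15) {
  h <- harmonized
  h$control_raf <- unname(control_raf[h$variant_id])
  open <- is.na(h$exclusion_reason)
  missing_ctrl <- open & is.na(h$control_raf)
  if (any(missing_ctrl)) {
    warning(sum(missing_ctrl), " entries had no control RAF; dropped")
    h$exclusion_reason[missing_ctrl] <- "raf_deviation"
  }
  open <- is.na(h$exclusion_reason)
  dev <- abs(h$raf - h$control_raf)
  h$exclusion_reason[open & dev > threshold] <- "raf_deviation"
  h
}

#' Control-cohort effect allele frequency
#'
#' Frequency of a designated allele per variant from control dosages. For
#' chromosome X variants the frequency is computed on female subjects only.
#'
#' @param geno A `dosage_data` object.
#' @param alleles Named character: for each variant_id, the allele whose
#'   frequency is wanted (must match `a1` or `a2`).
#' @param control_ids Subject IDs to use (default: all).
#' @param subjects Optional subject table with `subject_id` and `sex`
#'   (needed when the panel has chromosome X variants).
#' @return Named numeric of allele frequencies.
#' @export
effect_allele_freq <- function(geno, alleles, control_ids = NULL,
                               subjects = NULL) {
  v <- geno$variants
  ids <- names(alleles)
  idx <- match(ids, v$id)
  if (anyNA(idx)) stop("unknown variant(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  rows <- control_ids %||% rownames(geno$dosages)
  out <- setNames(numeric(length(ids)), ids)
  for (k in seq_along(ids)) {
    j <- idx[k]
    use <- rows
    if (v$chrom[j] %in% c("X", "23")) {
      if (is.null(subjects)) stop("chromosome X RAF needs a subject table ",
                                  "with sex")
      fem <- subjects$subject_id[subjects$sex == "F"]
      use <- intersect(rows, fem)
    }
    freq_a1 <- mean(geno$dosages[use, j]) / 2
    out[k] <- if (toupper(alleles[k]) == toupper(v$a1[j])) freq_a1
    else if (toupper(alleles[k]) == toupper(v$a2[j])) 1 - freq_a1
    else stop("allele ", alleles[k], " matches neither panel allele of ",
              ids[k])
  }
  out
}

#' LD deduplication of harmonized entries
#'
#' Among pairwise-correlated entries (r^2 above `r2_threshold` on the LD
#' panel) or duplicate variant IDs, keeps the entry with the most recent
#' publication date, breaking ties by smaller p-value. Output is ordered by
#' genomic coordinate.
#'
#' @param entries Harmonized, kept entries (rows with `exclusion_reason`
#'   already removed) carrying `variant_id`, `chrom`, `pos`, `pub_date`,
#'   `p_value`.
#' @param ld An `ld_panel` from [compute_ld()].
#' @param r2_threshold LD pruning threshold (default 0.1).
#' @return The retained subset of `entries`, coordinate-sorted.
#' @export
dedup_ld <- function(entries, ld, r2_threshold = 0.1) {
  if (!nrow(entries)) return(entries)
  ord <- order(as.Date(entries$pub_date), decreasing = TRUE)
  # recency first, then smaller p, then coordinate for determinism
  ord <- ord[order(-as.numeric(as.Date(entries$pub_date[ord])),
                   entries$p_value[ord],
                   entries$chrom[ord], entries$pos[ord])]
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (entries$variant_id[i] == entries$variant_id[k] ||
          ld_r2(ld, entries$variant_id[i], entries$variant_id[k]) >
            r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- entries[kept, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Harmonize full summary statistics against a variant panel
#'
#' Allele-pair version of [harmonize_catalog()] for summary statistics that
#' report both effect and other allele. Rows whose allele pair matches the
#' panel (in either order) are kept; a complemented pair on a non-ambiguous
#' variant is treated as a strand flip and repaired; ambiguous variants with
#' mismatching alleles are excluded.
#'
#' @param stats `summary_stats` data.frame.
#' @param variants Panel variant table.
#' @return `stats` with repaired `EFFECT_ALLELE`/`OTHER_ALLELE` and an
#'   `exclusion_reason` column (NA = kept); attribute `repaired_flips` lists
#'   repaired IDs.
#' @export
harmonize_sumstats <- function(stats, variants) {
  idx <- match(stats$ID, variants$id)
  reason <- rep(NA_character_, nrow(stats))
  flips <- character(0)
  reason[is.na(idx)] <- "not_in_panel"
  for (i in which(!is.na(idx))) {
    a1 <- toupper(variants$a1[idx[i]]); a2 <- toupper(variants$a2[idx[i]])
    ea <- toupper(stats$EFFECT_ALLELE[i]); oa <- toupper(stats$OTHER_ALLELE[i])
    if (!all(c(ea, oa) %in% BASES)) { reason[i] <- "no_allele_match"; next }
    if (setequal(c(ea, oa), c(a1, a2))) next
    ambiguous <- is_ambiguous_pair(a1, a2)
    if (!ambiguous &&
        setequal(c(complement_base(ea), complement_base(oa)), c(a1, a2))) {
      stats$EFFECT_ALLELE[i] <- complement_base(ea)
      stats$OTHER_ALLELE[i] <- complement_base(oa)
      flips <- c(flips, stats$ID[i])
    } else if (ambiguous) {
      reason[i] <- "ambiguous_mismatch"
    } else {
      reason[i] <- "no_allele_match"
    }
  }
  stats$exclusion_reason <- reason
  attr(stats, "repaired_flips") <- flips
  stats
}

#' Build a fixed risk-variant model from the latest genome-wide scan
#'
#' Applies the harmonization pipeline to full summary statistics, restricts
#' to genome-wide significant associations (strict `p < p_cut`), applies the
#' RAF-deviation check against control subjects, deduplicates by LD, and
#' packages the survivors as a PRS model.
#'
#' @param stats `summary_stats` data.frame.
#' @param geno Target-panel `dosage_data` (alleles and control dosages).
#' @param control_ids Control subject IDs for RAF and LD (default: all).
#' @param p_cut Significance threshold, strict (default 5e-8).
#' @param r2_threshold,raf_threshold QC thresholds.
#' @param window_bp LD window for deduplication.
#' @param trait_label Label stored on the returned model.
#' @param subjects Optional subject table (chromosome X RAF).
#' @return A [prs_model()] with method tag `latest_gwas`; attribute `audit`
#'   holds the per-row harmonization audit.
#' @export
select_latest_gwas <- function(stats, geno, control_ids = NULL, p_cut = 5e-8,
                               r2_threshold = 0.1, raf_threshold = 0.15,
                               window_bp = 1e6, trait_label = "trait",
                               subjects = NULL) {
  h <- harmonize_sumstats(stats, geno$variants)
  audit <- data.frame(ID = h$ID, exclusion_reason = h$exclusion_reason,
                      stringsAsFactors = FALSE)
  keep <- is.na(h$exclusion_reason)
  sig <- keep & h$P < p_cut
  audit$exclusion_reason[keep & !sig] <- "p_above_threshold"
  hs <- h[sig, , drop = FALSE]
  if (!nrow(hs)) {
    warning("no associations below p < ", p_cut)
    model <- prs_model(empty_entries(), method_tag = "latest_gwas",
                       trait_label = trait_label)
    attr(model, "audit") <- audit
    return(model)
  }
  ctrl <- effect_allele_freq(geno,
                             setNames(hs$EFFECT_ALLELE, hs$ID),
                             control_ids, subjects)
  dev <- abs(hs$EAF - unname(ctrl[hs$ID]))
  raf_bad <- dev > raf_threshold
  audit$exclusion_reason[match(hs$ID[raf_bad], audit$ID)] <- "raf_deviation"
  hs <- hs[!raf_bad, , drop = FALSE]
  ld <- compute_ld(geno, window_bp = window_bp, subject_ids = control_ids,
                   variant_ids = hs$ID)
  ent <- data.frame(variant_id = hs$ID, chrom = hs$CHROM, pos = hs$POS,
                    pub_date = as.Date("2000-01-01"), p_value = hs$P,
                    stringsAsFactors = FALSE)
  kept <- dedup_ld(ent, ld, r2_threshold)
  pruned <- setdiff(hs$ID, kept$variant_id)
  audit$exclusion_reason[match(pruned, audit$ID)] <- "ld_pruned"
  hs <- hs[match(kept$variant_id, hs$ID), , drop = FALSE]
  model <- prs_model(data.frame(
    variant_id = hs$ID, chrom = hs$CHROM, pos = hs$POS,
    effect_allele = hs$EFFECT_ALLELE, other_allele = hs$OTHER_ALLELE,
    weight = hs$BETA, p_value = hs$P, stringsAsFactors = FALSE
  ), method_tag = "latest_gwas", trait_label = trait_label)
  attr(model, "audit") <- audit
  model
}

#' Build a PRS model from association-catalog entries
#'
#' Full catalog arm of the ingest pipeline: harmonize alleles against the
#' target panel, apply the RAF-deviation check against control subjects,
#' deduplicate correlated or repeated entries by recency/p, and package the
#' survivors as a PRS model. No p-value threshold is applied to catalog
#' entries.
#'
#' @inheritParams select_latest_gwas
#' @param entries Catalog-style entry table (see [harmonize_alleles()]).
#' @return A [prs_model()] with method tag `catalog`; attribute `audit`
#'   holds the per-entry audit (kept rows have reason NA).
#' @export
select_catalog_prs <- function(entries, geno, control_ids = NULL,
                               r2_threshold = 0.1, raf_threshold = 0.15,
                               window_bp = 1e6, trait_label = "trait",
                               subjects = NULL) {
  h <- harmonize_catalog(entries, geno$variants)
  open <- is.na(h$exclusion_reason)
  if (any(open)) {
    ctrl <- effect_allele_freq(
      geno, setNames(h$effect_allele[open], h$variant_id[open]),
      control_ids, subjects)
    # control frequencies are keyed by variant_id; duplicated IDs share one
    h2 <- filter_raf(h[open, , drop = FALSE],
                     ctrl[!duplicated(names(ctrl))], raf_threshold)
    h$exclusion_reason[open] <- h2$exclusion_reason
  }
  audit <- h
  kept <- h[is.na(h$exclusion_reason), , drop = FALSE]
  if (nrow(kept)) {
    ld <- compute_ld(geno, window_bp = window_bp, subject_ids = control_ids,
                     variant_ids = unique(kept$variant_id))
    dd <- dedup_ld(kept, ld, r2_threshold)
    pruned <- setdiff(rownames(kept), rownames(dd))
    audit[pruned, "exclusion_reason"] <- "ld_pruned"
    kept <- dd
  }
  model <- prs_model(data.frame(
    variant_id = kept$variant_id, chrom = kept$chrom, pos = kept$pos,
    effect_allele = kept$effect_allele, other_allele = kept$other_allele,
    weight = kept$weight, p_value = kept$p_value, stringsAsFactors = FALSE
  ), method_tag = "catalog", trait_label = trait_label)
  attr(model, "audit") <- audit
  model
}

empty_entries <- function() {
  data.frame(variant_id = character(0), chrom = character(0),
             pos = integer(0), effect_allele = character(0),
             other_allele = character(0), weight = numeric(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}
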