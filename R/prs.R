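# PRS models and dosage scoring.

#' Construct a PRS model
#'
#' A PRS model is a table of (variant, effect allele, weight) entries plus a
#' construction-method tag. The score of subject j is
#' `PRS_j = sum_i beta_i G_ij`, with `G_ij` the dosage of the effect allele.
#'
#' @param entries data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`, and optionally `p_value`.
#' @param method_tag How the model was built (`catalog`, `latest_gwas`,
#'   `clump_threshold@t`, `ldpred@f`, `shared`, `unique`, `external`).
#' @param trait_label Free-text trait name.
#' @return Object of class `prs_model`.
#' @export
prs_model <- function(entries, method_tag = "external",
                      trait_label = "trait") {
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "weight")
  if (!all(need %in% names(entries)))
    stop("entries must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(entries$variant_id))
    stop("duplicate variant_id in PRS model")
  if (nrow(entries) && any(!is.finite(entries$weight)))
    stop("non-finite weight in PRS model")
  if (!"p_value" %in% names(entries)) entries$p_value <- NA_real_
  rownames(entries) <- NULL
  structure(list(entries = entries, method_tag = method_tag,
                 trait_label = trait_label), class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model [%s] %s: %d variants\n", x$method_tag,
              x$trait_label, nrow(x$entries)))
  invisible(x)
}

#' Score subjects against a PRS model
#'
#' `PRS_j = sum_i beta_i G_ij` where `G_ij` is the dosage of the model's
#' effect allele: the stored dosage when the effect allele is the matrix's
#' counted allele, `2 - dosage` when it is the other allele. Model variants
#' absent from the matrix are skipped (unless `strict`), and `coverage`
#' reports the scored fraction of total absolute weight.
#'
#' @param geno A `dosage_data` object.
#' @param model A [prs_model()].
#' @param strict Hard-fail on model variants missing from the matrix
#'   (default FALSE: skip and report coverage).
#' @return data.frame of class `prs_scores` with `subject_id` and `raw`;
#'   attributes `coverage`, `method_tag`, `trait_label`.
#' @export
compute_prs <- function(geno, model, strict = FALSE) {
  stopifnot(inherits(model, "prs_model"))
  e <- model$entries
  v <- geno$variants
  idx <- match(e$variant_id, v$id)
  missing <- is.na(idx)
  if (strict && any(missing))
    stop("model variants missing from dosage matrix: ",
         paste(e$variant_id[missing], collapse = ", "))
  total_mass <- sum(abs(e$weight))
  e <- e[!missing, , drop = FALSE]
  idx <- idx[!missing]
  raw <- numeric(nrow(geno$dosages))
  if (nrow(e)) {
    ea <- toupper(e$effect_allele)
    a1 <- toupper(v$a1[idx]); a2 <- toupper(v$a2[idx])
    flip <- ea == a2
    bad <- !(ea == a1 | flip)
    if (any(bad))
      stop("effect allele matches neither matrix allele for variant(s): ",
           paste(e$variant_id[bad], collapse = ", "))
    d <- geno$dosages[, v$id[idx], drop = FALSE]
    if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
    raw <- drop(d %*% e$weight)
  }
  out <- data.frame(subject_id = rownames(geno$dosages), raw = raw,
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- if (total_mass > 0)
    sum(abs(e$weight)) / total_mass else 1
  attr(out, "method_tag") <- model$method_tag
  attr(out, "trait_label") <- model$trait_label
  class(out) <- c("prs_scores", "data.frame")
  out
}

#' Standard-normal transform of raw scores
#'
#' `(x - mean) / sd` over the supplied analytical set (sample SD, n-1
#' denominator). Recomputed per case-control study rather than globally.
#'
#' @param scores A `prs_scores` data.frame (or any with `subject_id`,
#'   `raw`).
#' @param ids Analytical subject set (default: all rows). The returned
#'   table is restricted to these subjects.
#' @return `scores[ids, ]` with a `z` column; mean 0, SD 1 over the set.
#' @export
ztransform <- function(scores, ids = NULL) {
  s <- if (is.null(ids)) scores else {
    i <- match(ids, scores$subject_id)
    if (anyNA(i)) stop("ids missing from score table")
    scores[i, , drop = FALSE]
  }
  if (nrow(s) < 2) stop("need at least 2 subjects to standardize")
  sdev <- sd(s$raw)
  if (sdev == 0) stop("zero-variance score cannot be standardized")
  s$z <- (s$raw - mean(s$raw)) / sdev
  s
}
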