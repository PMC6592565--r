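# Locus merging and the shared/unique decomposition of subtype PRS.

#' Merge risk SNPs into loci by single-linkage chaining
#'
#' SNPs on the same chromosome belong to one locus iff they are connected
#' by a chain of pairwise distances of at most `window_bp` (so a locus can
#' span more than one window through chaining). The overlap table reports,
#' for every locus, which input models contribute a member SNP.
#'
#' @param models Named list of [prs_model()]s.
#' @param window_bp Merge window (default 1 Mb).
#' @return List with `loci` (data.frame `locus_id`, `chrom`, `start`,
#'   `end`, `n_snps`), `membership` (data.frame `locus_id`, `variant_id`),
#'   and `overlap` (logical matrix loci x models).
#' @export
merge_loci <- function(models, window_bp = 1e6) {
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  uni <- unique(do.call(rbind, lapply(models, function(m)
    m$entries[, c("variant_id", "chrom", "pos")])))
  uni <- uni[order(uni$chrom, uni$pos), , drop = FALSE]
  if (!nrow(uni)) {
    return(list(loci = data.frame(locus_id = character(0),
                                  chrom = character(0), start = integer(0),
                                  end = integer(0), n_snps = integer(0)),
                membership = data.frame(locus_id = character(0),
                                        variant_id = character(0)),
                overlap = matrix(FALSE, 0, length(models),
                                 dimnames = list(NULL, names(models)))))
  }
  new_locus <- c(TRUE, uni$chrom[-1] != uni$chrom[-nrow(uni)] |
                   diff(uni$pos) > window_bp)
  lid <- cumsum(new_locus)
  loci <- data.frame(
    locus_id = sprintf("locus%03d", seq_len(max(lid))),
    chrom = tapply(uni$chrom, lid, `[`, 1),
    start = as.integer(tapply(uni$pos, lid, min)),
    end = as.integer(tapply(uni$pos, lid, max)),
    n_snps = as.integer(table(lid)),
    stringsAsFactors = FALSE
  )
  membership <- data.frame(locus_id = loci$locus_id[lid],
                           variant_id = uni$variant_id,
                           stringsAsFactors = FALSE)
  overlap <- vapply(models, function(m) {
    loci$locus_id %in% membership$locus_id[
      membership$variant_id %in% m$entries$variant_id]
  }, logical(nrow(loci)))
  overlap <- matrix(overlap, nrow = nrow(loci),
                    dimnames = list(loci$locus_id, names(models)))
  list(loci = loci, membership = membership, overlap = overlap)
}

#' Shared and subtype-unique PRS decomposition
#'
#' From three subtype PRS models: the shared model takes one representative
#' SNP per locus present in all three models (the member with the smallest
#' p-value across the source models, ties by coordinate), every weight set
#' to 1 on the risk-increasing allele (an unweighted risk-allele count);
#' each unique model keeps that subtype's SNPs, with their original
#' weights, in loci touched by no other model.
#'
#' @param models Named list of exactly 3 [prs_model()]s.
#' @param window_bp Locus merge window (default 1 Mb).
#' @return List with `shared` (a [prs_model()], method tag `shared`),
#'   `unique` (named list of [prs_model()]s, tag `unique`), and `loci` (the
#'   [merge_loci()] result).
#' @export
decompose_shared_unique <- function(models, window_bp = 1e6) {
  if (length(models) != 3)
    stop("decomposition needs exactly 3 subtype models")
  ml <- merge_loci(models, window_bp)
  shared_loci <- rownames(ml$overlap)[rowSums(ml$overlap) == 3]
  if (!length(shared_loci))
    warning("no loci are shared by all three models; shared PRS is empty")
  all_entries <- do.call(rbind, lapply(names(models), function(nm) {
    e <- models[[nm]]$entries
    if (nrow(e)) e$source <- nm
    e
  }))
  shared_rows <- lapply(shared_loci, function(l) {
    member <- ml$membership$variant_id[ml$membership$locus_id == l]
    cand <- all_entries[all_entries$variant_id %in% member, , drop = FALSE]
    cand$p_value[is.na(cand$p_value)] <- Inf
    cand <- cand[order(cand$p_value, cand$chrom, cand$pos), , drop = FALSE]
    rep <- cand[1, , drop = FALSE]
    # unweighted sum of *risk* alleles: orient toward the risk-increasing
    # allele, then weight 1
    if (rep$weight < 0) {
      tmp <- rep$effect_allele
      rep$effect_allele <- rep$other_allele
      rep$other_allele <- tmp
    }
    rep$weight <- 1
    rep[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "weight", "p_value")]
  })
  shared <- prs_model(
    if (length(shared_rows)) do.call(rbind, shared_rows) else empty_entries(),
    method_tag = "shared", trait_label = "shared")

  unique_models <- lapply(names(models), function(nm) {
    others <- setdiff(names(models), nm)
    uniq_loci <- rownames(ml$overlap)[ml$overlap[, nm] &
                                        rowSums(ml$overlap[, others,
                                                           drop = FALSE]) == 0]
    member <- ml$membership$variant_id[ml$membership$locus_id %in% uniq_loci]
    e <- models[[nm]]$entries
    prs_model(e[e$variant_id %in% member, , drop = FALSE],
              method_tag = "unique", trait_label = nm)
  })
  names(unique_models) <- names(models)
  list(shared = shared, unique = unique_models, loci = ml)
}
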