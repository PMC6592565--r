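# PheWAS drivers: standard, exclusion, and the lagged secondary-diagnosis
# predictor model.

PHEWAS_COVARS <- c("age", "sex", "array", "PC1", "PC2", "PC3", "PC4")

# Design matrix for one analytical set: intercept + focal predictor +
# covariates; zero-variance covariate columns are dropped with a message.
build_design <- function(focal, focal_name, subjects, ids,
                         covars = PHEWAS_COVARS) {
  idx <- match(ids, subjects$subject_id)
  if (anyNA(idx)) stop("subjects missing covariates")
  df <- subjects[idx, covars, drop = FALSE]
  for (v in covars) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  # single-level factors (e.g. a single-sex phenotype) cannot enter the
  # model matrix; drop them up front
  flat <- vapply(df, function(col)
    (is.factor(col) && nlevels(droplevels(col)) < 2) ||
      length(unique(col)) < 2, logical(1))
  if (any(flat)) {
    message("dropping degenerate covariate(s): ",
            paste(names(df)[flat], collapse = ", "))
    df <- df[, !flat, drop = FALSE]
    for (v in names(df)) if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  }
  mm <- stats::model.matrix(~ ., data = df)
  keep <- c(TRUE, apply(mm[, -1, drop = FALSE], 2, function(col)
    length(unique(col)) > 1))
  dropped <- colnames(mm)[!keep]
  if (length(dropped))
    message("dropping degenerate covariate column(s): ",
            paste(dropped, collapse = ", "))
  mm <- mm[, keep, drop = FALSE]
  X <- cbind(mm[, 1, drop = FALSE], focal, mm[, -1, drop = FALSE])
  colnames(X)[1:2] <- c("(Intercept)", focal_name)
  X
}

phewas_one_study <- function(study, scores, subjects, pl = FALSE) {
  ids <- c(study$case_ids, study$control_ids)
  y <- c(rep(1L, length(study$case_ids)), rep(0L, length(study$control_ids)))
  z <- ztransform(scores, ids)
  X <- build_design(z$z, "PRS", subjects, ids)
  fit <- firth_fit(X, y, pl = pl)
  data.frame(
    phecode = study$phecode,
    n_case = length(study$case_ids),
    n_control = length(study$control_ids),
    beta_prs = unname(fit$coef["PRS"]),
    se = unname(fit$se["PRS"]),
    p = unname(if (pl) fit$p_plr["PRS"] else fit$p["PRS"]),
    converged = fit$converged,
    stringsAsFactors = FALSE
  )
}

#' PRS-PheWAS across a phenome of case-control studies
#'
#' One Firth fit per study of case status on the study-standardized PRS
#' plus age, sex, genotyping array and PC1-4, with phenome-wide Bonferroni
#' control (`alpha` divided by the number of studies tested).
#'
#' @param scores A `prs_scores` table covering all study subjects (raw
#'   scores; standardization happens within each study's analytical set).
#' @param studies Named list of `matched_study` objects.
#' @param subjects Subject covariate table.
#' @param alpha Phenome-wide significance level (default 0.05).
#' @param pl Use penalized-likelihood-ratio p-values (default: Wald).
#' @return data.frame of class `phewas_result`: one row per study with
#'   `phecode`, `n_case`, `n_control`, `beta_prs` (log-OR per SD), `se`,
#'   `p`, `direction` ("up"/"down"), `bonferroni_significant`; attribute
#'   `n_tested` and `threshold`.
#' @export
run_phewas <- function(scores, studies, subjects, alpha = 0.05, pl = FALSE) {
  if (!length(studies)) stop("no studies to test")
  rows <- lapply(studies, function(st)
    phewas_one_study(st, scores, subjects, pl = pl))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  n_tested <- nrow(res)
  res$direction <- ifelse(res$beta_prs > 0, "up", "down")
  res$bonferroni_significant <- res$p < alpha / n_tested
  attr(res, "n_tested") <- n_tested
  attr(res, "threshold") <- alpha / n_tested
  class(res) <- c("phewas_result", "data.frame")
  res
}

#' Exclusion PheWAS
#'
#' Re-runs the PheWAS after removing every subject carrying any of the
#' exclusion PheCodes (the primary and related traits the PRS was built
#' for) from all studies, cases and controls alike. Studies whose case
#' count falls to `min_cases` or below are dropped, and the Bonferroni
#' denominator is the number of studies actually tested.
#'
#' @inheritParams run_phewas
#' @param exclusion_phecodes Character vector of PheCodes defining the
#'   excluded subjects.
#' @param incidence The `phecode_incidence` table the studies came from.
#' @param expand_hierarchy Also exclude carriers of ancestors/descendants
#'   of each exclusion code (default TRUE).
#' @param min_cases Strict lower bound on the post-exclusion case count
#'   (default 50).
#' @return A `phewas_result` (see [run_phewas()]).
#' @export
exclusion_phewas <- function(scores, studies, exclusion_phecodes, incidence,
                             subjects, alpha = 0.05, min_cases = 50,
                             expand_hierarchy = TRUE, pl = FALSE) {
  if (!length(exclusion_phecodes)) stop("empty exclusion set")
  excl <- exclusion_phecodes
  if (expand_hierarchy) {
    codes <- unique(incidence$phecode)
    anc_of_excl <- unique(unlist(lapply(exclusion_phecodes,
                                        phecode_ancestors)))
    excl <- union(excl, codes[vapply(codes, function(p)
      any(exclusion_phecodes %in% phecode_ancestors(p)) ||
        p %in% anc_of_excl, logical(1))])
  }
  bad <- unique(incidence$subject_id[incidence$phecode %in% excl])
  pruned <- list()
  for (nm in names(studies)) {
    st <- studies[[nm]]
    st$case_ids <- setdiff(st$case_ids, bad)
    st$control_ids <- setdiff(st$control_ids, bad)
    if (!is.null(st$match_map)) {
      st$match_map <- lapply(st$match_map[setdiff(names(st$match_map), bad)],
                             setdiff, y = bad)
    }
    if (length(st$case_ids) > min_cases && length(st$control_ids) > 0)
      pruned[[nm]] <- st
  }
  if (!length(pruned)) {
    res <- data.frame(phecode = character(0), n_case = integer(0),
                      n_control = integer(0), beta_prs = numeric(0),
                      se = numeric(0), p = numeric(0),
                      converged = logical(0), direction = character(0),
                      bonferroni_significant = logical(0))
    attr(res, "n_tested") <- 0L
    class(res) <- c("phewas_result", "data.frame")
    return(res)
  }
  run_phewas(scores, pruned, subjects, alpha = alpha, pl = pl)
}

#' Lagged secondary-diagnosis predictor model
#'
#' Tests whether prior presence of a secondary diagnosis identifies
#' subjects at increased risk of the primary disease. The binary predictor
#' is 1 for subjects diagnosed with the secondary code whose first primary
#' diagnosis comes at least `lag_days` later, or who never receive the
#' primary diagnosis; 0 for subjects without the secondary code. Subjects
#' whose primary diagnosis follows the secondary one within less than
#' `lag_days` are excluded. A Firth model of primary status on the
#' predictor plus the standard covariates is fit on the remainder.
#'
#' @param incidence A `phecode_incidence` table (first dates per code).
#' @param secondary_phecode,primary_phecode The two codes.
#' @param subjects Subject covariate table.
#' @param lag_days Minimum lag (default 365).
#' @param pl Penalized-likelihood-ratio p-values (default: Wald).
#' @return List of class `secondary_predictor_fit`: the `firth_fit`, the
#'   predictor coefficient summary, and counts (`n`, `n_excluded`,
#'   `n_predictor1`).
#' @export
secondary_predictor_model <- function(incidence, secondary_phecode,
                                      primary_phecode, subjects,
                                      lag_days = 365, pl = FALSE) {
  first_of <- function(code) {
    i <- incidence[incidence$phecode == code, , drop = FALSE]
    setNames(i$first_date, i$subject_id)
  }
  sec <- first_of(secondary_phecode)
  pri <- first_of(primary_phecode)
  ids <- subjects$subject_id
  sec_d <- sec[ids]
  pri_d <- pri[ids]
  has_sec <- !is.na(sec_d)
  has_pri <- !is.na(pri_d)
  predictor <- rep(NA_integer_, length(ids))
  predictor[!has_sec] <- 0L
  late_or_never <- has_sec &
    (!has_pri | (has_pri & as.numeric(pri_d - sec_d) >= lag_days))
  predictor[late_or_never] <- 1L
  keep <- !is.na(predictor)
  if (!any(keep & has_pri) || !any(keep & !has_pri) || !any(predictor[keep] == 1))
    stop("no qualifying subjects for the secondary-predictor model")
  use <- ids[keep]
  X <- build_design(predictor[keep], "predictor", subjects, use)
  fit <- firth_fit(X, as.integer(has_pri[keep]), pl = pl)
  structure(list(
    fit = fit,
    beta = unname(fit$coef["predictor"]),
    se = unname(fit$se["predictor"]),
    p = unname(if (pl) fit$p_plr["predictor"] else fit$p["predictor"]),
    n = length(use),
    n_excluded = sum(!keep),
    n_predictor1 = sum(predictor[keep] == 1L)
  ), class = "secondary_predictor_fit")
}
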