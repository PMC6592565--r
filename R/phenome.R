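# PheCode aggregation of ICD events and matched case-control studies.

#' Parent of a PheCode
#'
#' Hierarchy by decimal digits: parent of "172.11" is "172.1", parent of
#' "172.1" is "172", top-level codes have no parent (NA).
#'
#' @param phecode Character vector of PheCodes.
#' @return Character vector of parents (NA at the top level).
#' @export
phecode_parent <- function(phecode) {
  vapply(phecode, function(p) {
    if (!grepl(".", p, fixed = TRUE)) return(NA_character_)
    q <- substr(p, 1, nchar(p) - 1L)
    sub("\\.$", "", q)
  }, character(1), USE.NAMES = FALSE)
}

phecode_ancestors <- function(phecode) {
  out <- character(0)
  p <- phecode_parent(phecode)
  while (!is.na(p)) {
    out <- c(out, p)
    p <- phecode_parent(p)
  }
  out
}

#' Aggregate ICD events into a PheCode incidence table
#'
#' A subject carries a PheCode iff at least one event maps to it or to a
#' descendant (events propagate up the hierarchy); the first date is the
#' earliest mapping event. Unmapped codes are counted on the `unmapped`
#' attribute.
#'
#' @param events data.frame `subject_id`, `vocab` (ICD9/ICD10), `code`,
#'   `date`.
#' @param definitions PheCode map: data.frame `phecode`, `vocab`, `code`
#'   (and optionally `description`).
#' @return data.frame of class `phecode_incidence`: `subject_id`,
#'   `phecode`, `first_date`.
#' @export
map_codes_to_phecodes <- function(events, definitions) {
  need <- c("phecode", "vocab", "code")
  if (!all(need %in% names(definitions)))
    stop("malformed mapping: need columns ", paste(need, collapse = ", "))
  key_ev <- paste(events$vocab, events$code)
  key_def <- paste(definitions$vocab, definitions$code)
  hit <- match(key_ev, key_def)
  unmapped <- table(key_ev[is.na(hit)])
  mapped <- events[!is.na(hit), , drop = FALSE]
  mapped$phecode <- definitions$phecode[hit[!is.na(hit)]]
  # propagate to ancestors
  anc <- lapply(unique(mapped$phecode), phecode_ancestors)
  names(anc) <- unique(mapped$phecode)
  extra <- mapped[rep(seq_len(nrow(mapped)),
                      lengths(anc[mapped$phecode])), , drop = FALSE]
  extra$phecode <- unlist(anc[mapped$phecode], use.names = FALSE)
  full <- rbind(mapped, extra)
  key <- paste(full$subject_id, full$phecode)
  first <- tapply(as.numeric(full$date), key, min)
  parts <- strsplit(names(first), " ", fixed = TRUE)
  out <- data.frame(
    subject_id = vapply(parts, `[`, character(1), 1L),
    phecode = vapply(parts, `[`, character(1), 2L),
    first_date = as.Date(as.numeric(first), origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject_id, out$phecode), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  class(out) <- c("phecode_incidence", "data.frame")
  out
}

#' Cases and the eligible control pool for one PheCode
#'
#' Cases carry the PheCode. The control pool excludes, beyond the cases,
#' any subject carrying a hierarchical ancestor or descendant of the target
#' code (the usual PheWAS exclusion range); set `exclude_hierarchy = FALSE`
#' to keep them.
#'
#' @param incidence A `phecode_incidence` table.
#' @param phecode Target code.
#' @param subjects Subject table (defines the universe via `subject_id`).
#' @param exclude_hierarchy Apply the ancestor/descendant exclusion
#'   (default TRUE).
#' @return List with `cases` and `control_pool` (character ID vectors).
#' @export
define_case_control <- function(incidence, phecode, subjects,
                                exclude_hierarchy = TRUE) {
  cases <- unique(incidence$subject_id[incidence$phecode == phecode])
  excluded <- cases
  if (exclude_hierarchy) {
    codes <- unique(incidence$phecode)
    related <- codes[vapply(codes, function(p) {
      p != phecode && (phecode %in% phecode_ancestors(p) ||
                         p %in% phecode_ancestors(phecode))
    }, logical(1))]
    if (length(related))
      excluded <- union(excluded,
                        incidence$subject_id[incidence$phecode %in% related])
  }
  list(cases = cases,
       control_pool = setdiff(subjects$subject_id, excluded))
}

#' Match controls to cases
#'
#' For each case, in input order, up to `ratio` controls are drawn without
#' replacement from pool members that are equal on the exact variables and
#' within `caliper_sd` standard deviations on every standardized matching
#' covariate, nearest first by Mahalanobis distance. Cases with no eligible
#' control are dropped (recorded on the result).
#'
#' @param cases,pool Character subject IDs.
#' @param covariates Subject table with `subject_id`, the exact variables
#'   and the matching covariates.
#' @param phecode Code label stored on the study.
#' @param ratio Maximum controls per case (default 10).
#' @param caliper_sd Per-covariate caliper in SD units (default 0.25).
#' @param exact Exact-match variables (default sex and array).
#' @param nn_vars Nearest-neighbor covariates (default age and PC1-4).
#' @return Object of class `matched_study`: list with `phecode`,
#'   `case_ids`, `control_ids`, `match_map` (named list case -> controls),
#'   `achieved_ratio`, `matching_mode = "matched"`, `dropped_cases`.
#' @export
match_controls <- function(cases, pool, covariates, phecode = NA_character_,
                           ratio = 10, caliper_sd = 0.25,
                           exact = c("sex", "array"),
                           nn_vars = c("age", "PC1", "PC2", "PC3", "PC4")) {
  if (!length(pool)) stop("empty control pool")
  cov <- covariates
  idx <- match(c(cases, pool), cov$subject_id)
  if (anyNA(idx)) stop("covariates missing for some subjects")
  if (!all(complete.cases(cov[idx, c(exact, nn_vars)])))
    stop("incomplete covariates for matching")
  cases <- sort(cases)

  # standardize matching covariates over the analytical universe
  uni <- cov[match(unique(c(cases, pool)), cov$subject_id), , drop = FALSE]
  X <- as.matrix(uni[, nn_vars, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  rownames(Z) <- uni$subject_id
  S <- cov(Z)
  Sinv <- tryCatch(solve(S), error = function(e) solve(S + diag(1e-8, ncol(S))))
  exact_key <- setNames(do.call(paste, c(uni[, exact, drop = FALSE],
                                         sep = "\r")), uni$subject_id)

  available <- setNames(rep(TRUE, length(pool)), pool)
  match_map <- vector("list", length(cases))
  names(match_map) <- cases
  dropped <- character(0)
  for (cs in cases) {
    elig <- pool[available[pool] & exact_key[pool] == exact_key[cs]]
    if (length(elig)) {
      diff <- sweep(Z[elig, , drop = FALSE], 2, Z[cs, ])
      within <- rowSums(abs(diff) > caliper_sd) == 0
      elig <- elig[within]
      diff <- diff[within, , drop = FALSE]
    }
    if (!length(elig)) {
      dropped <- c(dropped, cs)
      match_map[[cs]] <- NULL
      next
    }
    d2 <- rowSums((diff %*% Sinv) * diff)
    take <- elig[order(d2, elig)][seq_len(min(ratio, length(elig)))]
    match_map[[cs]] <- take
    available[take] <- FALSE
  }
  match_map <- match_map[!names(match_map) %in% dropped]
  kept_cases <- names(match_map)
  controls <- unlist(match_map, use.names = FALSE)
  structure(list(
    phecode = phecode,
    case_ids = kept_cases,
    control_ids = controls,
    match_map = match_map,
    achieved_ratio = if (length(kept_cases))
      length(controls) / length(kept_cases) else NA_real_,
    matching_mode = "matched",
    dropped_cases = dropped
  ), class = "matched_study")
}

#' @export
print.matched_study <- function(x, ...) {
  cat(sprintf("matched_study %s: %d cases, %d controls (%s, ratio %.2f)\n",
              x$phecode, length(x$case_ids), length(x$control_ids),
              x$matching_mode, x$achieved_ratio))
  invisible(x)
}

#' Build one case-control study per qualifying PheCode
#'
#' One study per PheCode with strictly more than `min_cases` cases. In
#' matched mode controls come from [match_controls()]; in unmatched mode
#' (the sensitivity configuration) the full eligible pool is used.
#'
#' @param incidence A `phecode_incidence` table.
#' @param subjects Subject/covariate table.
#' @param min_cases Strict lower bound on the case count (default 50).
#' @param mode `"matched"` or `"unmatched"`.
#' @param ... Passed to [match_controls()].
#' @return Named list of `matched_study` objects, keyed by PheCode.
#' @export
build_phenome_studies <- function(incidence, subjects, min_cases = 50,
                                  mode = c("matched", "unmatched"), ...) {
  mode <- match.arg(mode)
  counts <- table(unique(incidence[, c("subject_id", "phecode")])$phecode)
  keep <- names(counts)[counts > min_cases]
  out <- list()
  for (ph in sort(keep)) {
    cc <- define_case_control(incidence, ph, subjects)
    if (!length(cc$control_pool)) next
    if (mode == "matched") {
      st <- match_controls(cc$cases, cc$control_pool, subjects,
                           phecode = ph, ...)
    } else {
      st <- structure(list(
        phecode = ph, case_ids = sort(cc$cases),
        control_ids = cc$control_pool,
        match_map = NULL,
        achieved_ratio = length(cc$control_pool) / length(cc$cases),
        matching_mode = "unmatched", dropped_cases = character(0)
      ), class = "matched_study")
    }
    if (length(st$case_ids) > min_cases) out[[ph]] <- st
  }
  out
}
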