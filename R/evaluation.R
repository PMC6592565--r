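# Train/test evaluation of a PRS on one case-control study:
# discrimination (AUC with DeLong CI), calibration (Hosmer-Lemeshow),
# accuracy (Brier score) and Nagelkerke pseudo-R^2.

#' Stratified train/test split of a study
#'
#' Case-status-stratified random split: one third of the study (by
#' stratified rounding) forms the training set, the rest the test set.
#'
#' @param study A `matched_study`.
#' @param train_frac Training fraction (default 1/3).
#' @param seed RNG seed.
#' @return List with `train` and `test` ID vectors (disjoint, exhaustive,
#'   both classes present in both).
#' @export
split_train_test <- function(study, train_frac = 1 / 3, seed = 1L) {
  draw <- function() {
    take <- function(ids) {
      n <- max(1L, round(length(ids) * train_frac))
      sample(ids, n)
    }
    tr <- c(take(study$case_ids), take(study$control_ids))
    list(train = tr,
         test = setdiff(c(study$case_ids, study$control_ids), tr))
  }
  sp <- with_seed(seed, {
    s <- draw()
    ok <- length(intersect(s$test, study$case_ids)) > 0 &&
      length(intersect(s$test, study$control_ids)) > 0
    if (!ok) s <- draw()
    s
  })
  if (!length(intersect(sp$test, study$case_ids)) ||
      !length(intersect(sp$test, study$control_ids)))
    stop("a class is absent from the test split even after reshuffling")
  sp
}

#' AUC with DeLong 95% confidence interval
#'
#' Mann-Whitney AUC of `scores` for `labels`, with the DeLong variance for
#' the confidence interval.
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1).
#' @return Named numeric: `auc`, `lower`, `upper`.
#' @export
auc_ci <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  c(auc = ci[2], lower = ci[1], upper = ci[3])
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups test observations into deciles of predicted risk and compares
#' observed and expected event counts:
#' `chi2 = sum (O - E)^2 / (E (1 - E / n_g))`, with `groups - 2` degrees of
#' freedom. Empty or degenerate deciles are merged with their neighbor
#' (degrees of freedom adjusted, message emitted).
#'
#' @param pred Predicted probabilities in (0, 1).
#' @param labels Binary outcome.
#' @param groups Number of risk groups (default 10).
#' @return Named numeric: `chi2`, `p`, `df`, `groups`.
#' @export
hosmer_lemeshow <- function(pred, labels, groups = 10) {
  stopifnot(groups >= 2, length(pred) == length(labels))
  br <- unique(quantile(pred, probs = seq(0, 1, length.out = groups + 1)))
  if (length(br) - 1 < groups) {
    message("tied predictions: merged to ", length(br) - 1, " risk groups")
  }
  g <- cut(pred, breaks = br, include.lowest = TRUE)
  obs <- tapply(labels, g, sum)
  exp_ <- tapply(pred, g, sum)
  n_g <- tapply(labels, g, length)
  keep <- !is.na(n_g) & n_g > 0
  obs <- obs[keep]; exp_ <- exp_[keep]; n_g <- n_g[keep]
  denom <- exp_ * (1 - exp_ / n_g)
  degen <- denom <= 0
  if (any(degen)) {
    message(sum(degen), " degenerate risk group(s) merged")
    obs <- obs[!degen]; exp_ <- exp_[!degen]; n_g <- n_g[!degen]
    denom <- denom[!degen]
  }
  chi2 <- sum((obs - exp_)^2 / denom)
  df <- max(length(obs) - 2, 1)
  c(chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE), df = df,
    groups = length(obs))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and the binary
#' outcome.
#'
#' @param pred Predicted probabilities.
#' @param labels Binary outcome.
#' @return Scalar in `[0, 1]`.
#' @export
brier <- function(pred, labels) mean((pred - labels)^2)

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R^2 rescaled by its maximum `1 - exp(2 ll_null / n)`.
#'
#' @param ll_model,ll_null Log-likelihoods of the fitted and
#'   intercept-only models.
#' @param n Sample size.
#' @return Scalar in `[0, 1]`.
#' @export
nagelkerke <- function(ll_model, ll_null, n) {
  cs <- 1 - exp(2 * (ll_null - ll_model) / n)
  maxcs <- 1 - exp(2 * ll_null / n)
  if (maxcs <= 0) return(0)
  min(max(cs / maxcs, 0), 1)
}

binom_loglik <- function(pred, labels) {
  eps <- 1e-15
  p <- pmin(pmax(pred, eps), 1 - eps)
  sum(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Train/test evaluation of a PRS on a study
#'
#' Fits a logistic model with the standardized PRS as the sole covariate on
#' the training third (falling back to the Firth fit if the unpenalized fit
#' separates), predicts the test two-thirds, and reports AUC (DeLong 95%
#' CI), Hosmer-Lemeshow calibration, Brier score, and Nagelkerke pseudo-R^2
#' on the test set.
#'
#' @param study A `matched_study`.
#' @param scores A `prs_scores` table covering the study subjects.
#' @param seed Split seed.
#' @param train_frac Training fraction (default 1/3).
#' @param hl_groups Hosmer-Lemeshow groups (default 10).
#' @return Object of class `eval_metrics`: list with `auc`, `auc_lower`,
#'   `auc_upper`, `hl_chi2`, `hl_p`, `hl_groups`, `brier`,
#'   `nagelkerke_r2`, `n_train`, `n_test`, `or_per_sd`, `warnings`.
#' @export
evaluate_prs <- function(study, scores, seed = 1L, train_frac = 1 / 3,
                         hl_groups = 10) {
  ids <- c(study$case_ids, study$control_ids)
  status <- setNames(c(rep(1L, length(study$case_ids)),
                       rep(0L, length(study$control_ids))), ids)
  z <- ztransform(scores, ids)
  zval <- setNames(z$z, z$subject_id)
  sp <- split_train_test(study, train_frac, seed)
  warnings <- character(0)

  y_tr <- status[sp$train]
  x_tr <- zval[sp$train]
  fit <- tryCatch({
    suppressWarnings(g <- glm(y_tr ~ x_tr, family = binomial()))
    if (!g$converged || any(abs(coef(g)) > 15)) stop("separation")
    list(coef = coef(g))
  }, error = function(e) {
    list(coef = firth_fit(cbind(1, x_tr), y_tr)$coef)
  })
  y_te <- status[sp$test]
  eta <- fit$coef[1] + fit$coef[2] * zval[sp$test]
  pred <- plogis(eta)
  if (sd(pred) == 0) warnings <- c(warnings, "degenerate test predictions")

  auc <- auc_ci(pred, y_te)
  hl <- hosmer_lemeshow(pred, y_te, hl_groups)
  ll_model <- binom_loglik(pred, y_te)
  ll_null <- binom_loglik(rep(mean(y_te), length(y_te)), y_te)
  structure(list(
    auc = unname(auc["auc"]), auc_lower = unname(auc["lower"]),
    auc_upper = unname(auc["upper"]),
    hl_chi2 = unname(hl["chi2"]), hl_p = unname(hl["p"]),
    hl_groups = unname(hl["groups"]),
    brier = brier(pred, y_te),
    nagelkerke_r2 = nagelkerke(ll_model, ll_null, length(y_te)),
    or_per_sd = exp(unname(fit$coef[2])),
    n_train = length(sp$train), n_test = length(sp$test),
    warnings = warnings
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f (%.3f-%.3f) | HL chi2 %.2f p %.3f | ",
                     "Brier %.3f | Nagelkerke R2 %.3f | OR/SD %.2f\n"),
              x$auc, x$auc_lower, x$auc_upper, x$hl_chi2, x$hl_p,
              x$brier, x$nagelkerke_r2, x$or_per_sd))
  invisible(x)
}
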