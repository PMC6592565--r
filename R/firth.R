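# Firth bias-reduced logistic regression.
#
# Maximizes the Jeffreys-penalized log-likelihood
#   l*(b) = l(b) + 0.5 log det X'WX ,  W = diag(w mu (1-mu)),
# via modified-score Newton iterations with step-halving.  The penalized
# score is U*(b) = X'(w(y - mu) + h (1/2 - mu)) with h the hat diagonal of
# the weighted information.  Estimates stay finite under complete
# separation; on a saturated 2x2 design the slope equals the classical
# half-cell-correction log odds ratio.

#' Firth penalized logistic regression
#'
#' @param x Design matrix (include the intercept column yourself or use
#'   [run_phewas()]-style wrappers). Must be full rank.
#' @param y Binary outcome (0/1).
#' @param weights Optional case weights (counts); default 1.
#' @param tol Convergence tolerance on the Newton step (default 1e-8).
#' @param max_iter Iteration cap (default 100); non-convergence is flagged,
#'   not an error.
#' @param pl Also compute penalized-likelihood-ratio p-values (default
#'   FALSE: Wald p-values only).
#' @return Object of class `firth_fit`: `coef`, `se`, `p` (Wald), `p_plr`
#'   (if requested), `vcov`, `loglik_pen`, `iterations`, `converged`.
#' @export
firth_fit <- function(x, y, weights = NULL, tol = 1e-8, max_iter = 100,
                      pl = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  w <- weights %||% rep(1, nrow(x))
  stopifnot(length(y) == nrow(x), length(w) == nrow(x), all(y %in% 0:1))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    aliased <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  k <- ncol(x)
  wy <- w * y
  dix <- seq.int(1L, k * k, by = k + 1L)  # diagonal positions
  # state at the current beta; the Cholesky factor serves both the Newton
  # step and 0.5 * log det of the information (a hair of ridge keeps it
  # defined in degenerate corners without touching the estimates)
  b <- rep(0, k)
  eta <- drop(x %*% b)
  mu <- plogis(eta)
  xw <- x * sqrt(w * mu * (1 - mu))
  info <- crossprod(xw)
  info[dix] <- info[dix] + 1e-12 * (1 + info[dix])
  R <- chol(info)
  pll <- sum(wy * eta) + sum(w * plogis(-eta, log.p = TRUE)) +
    sum(log(R[dix]))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    iinv <- chol2inv(R)
    h <- rowSums((xw %*% iinv) * xw)
    score <- drop(crossprod(x, w * (y - mu) + h * (0.5 - mu)))
    step <- drop(iinv %*% score)
    # step-halving on the penalized likelihood
    fac <- 1
    for (half in 0:10) {
      b2 <- b + fac * step
      eta2 <- drop(x %*% b2)
      mu2 <- plogis(eta2)
      xw2 <- x * sqrt(w * mu2 * (1 - mu2))
      info2 <- crossprod(xw2)
      info2[dix] <- info2[dix] + 1e-12 * (1 + info2[dix])
      R2 <- chol(info2)
      pll2 <- sum(wy * eta2) + sum(w * plogis(-eta2, log.p = TRUE)) +
        sum(log(R2[dix]))
      if (is.finite(pll2) && pll2 >= pll - 1e-12) break
      fac <- fac / 2
    }
    pll_prev <- pll
    b <- b2; mu <- mu2; xw <- xw2; R <- R2; pll <- pll2
    # primary criterion: vanishing step; fallback: stationary penalized
    # likelihood with an already-tiny step (near-optimal 2-cycles can keep
    # the raw step from shrinking below machine-level tolerances)
    if (max(abs(fac * step)) < tol ||
        (abs(pll - pll_prev) < 1e-13 && max(abs(fac * step)) < sqrt(tol))) {
      converged <- TRUE
      break
    }
  }
  vc <- chol2inv(R)
  dimnames(vc) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(vc))
  z <- b / se
  fit <- structure(list(
    coef = setNames(b, colnames(x)),
    se = setNames(se, colnames(x)),
    p = setNames(pmin(1, pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)),
                 colnames(x)),
    vcov = vc,
    loglik_pen = as.numeric(pll),
    iterations = iter,
    converged = converged
  ), class = "firth_fit")
  if (pl) {
    fit$p_plr <- vapply(seq_len(k), function(j)
      firth_plr_p(x, y, w, b, pll, j, tol, max_iter), numeric(1))
    names(fit$p_plr) <- colnames(x)
  }
  fit
}

# Penalized-likelihood-ratio p for coefficient j: profile out the others
# with b_j fixed at 0; the penalty keeps the full-design information.
firth_plr_p <- function(x, y, w, b_full, pll_full, j, tol, max_iter) {
  k <- ncol(x)
  free <- setdiff(seq_len(k), j)
  b <- b_full
  b[j] <- 0
  pll_of <- function(b) {
    mu <- plogis(drop(x %*% b))
    wv <- w * mu * (1 - mu)
    ll <- sum(w * ifelse(y == 1, log(pmax(mu, 1e-300)),
                         log(pmax(1 - mu, 1e-300))))
    ll + 0.5 * determinant(crossprod(x * sqrt(wv)),
                           logarithm = TRUE)$modulus
  }
  pll <- pll_of(b)
  for (iter in seq_len(max_iter)) {
    mu <- plogis(drop(x %*% b))
    wv <- w * mu * (1 - mu)
    xw <- x * sqrt(wv)
    info <- crossprod(xw)
    iinv <- tryCatch(chol2inv(chol(info)), error = function(e)
      solve(info + diag(1e-10, k)))
    h <- rowSums((xw %*% iinv) * xw)
    score <- drop(crossprod(x, w * (y - mu) + h * (0.5 - mu)))[free]
    step <- drop(solve(info[free, free, drop = FALSE], score))
    fac <- 1
    for (half in 0:10) {
      cand <- b
      cand[free] <- b[free] + fac * step
      if (is.finite(pll_of(cand)) && pll_of(cand) >= pll - 1e-12) break
      fac <- fac / 2
    }
    b[free] <- b[free] + fac * step
    pll <- pll_of(b)
    if (max(abs(fac * step)) < tol) break
  }
  stat <- 2 * (pll_full - pll)
  pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized logistic regression",
      if (!x$converged) "(NOT converged)", "\n")
  print(data.frame(coef = x$coef, se = x$se, p = x$p))
  invisible(x)
}
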