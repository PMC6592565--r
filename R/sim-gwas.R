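# Discovery-cohort GWAS simulator with QC corruption injection.

#' Simulate discovery-cohort GWAS summary statistics
#'
#' Draws an independent cohort of `config$discovery_n` subjects on the same
#' variant panel, generates disease status for one subtype from the true
#' architecture, and computes per-variant marginal logistic associations
#' (log odds ratio, SE, Wald p, effect allele frequency, N). Rows are then
#' corrupted at the configured rates to exercise downstream quality control:
#' strand flips (both alleles complemented; only applied to non-ambiguous
#' variants, where a flip is detectable), allele-frequency errors (EAF moved
#' by 0.2-0.35), and ambiguous-mismatch rows (alleles of a strand-ambiguous
#' panel variant replaced with the other ambiguous pair).
#'
#' @param architecture A `true_architecture`.
#' @param config The [sim_config()].
#' @param variants The variant table the architecture was simulated on.
#' @param subtype Which subtype's disease the discovery GWAS studied
#'   (default: first).
#' @return data.frame of class `summary_stats` with columns `ID`, `CHROM`,
#'   `POS`, `EFFECT_ALLELE`, `OTHER_ALLELE`, `BETA`, `SE`, `P`, `EAF`, `N`.
#'   Attribute `injections` records each corrupted row (`ID`, `type`).
#' @export
simulate_discovery_gwas <- function(architecture, config, variants,
                                    subtype = NULL) {
  stopifnot(inherits(architecture, "true_architecture"),
            inherits(config, "sim_config"))
  subtypes <- subtype_names(config)
  subtype <- subtype %||% subtypes[1]
  stopifnot(subtype %in% subtypes)
  with_seed(config$seed + 3L, {
    dos <- draw_dosages(config$discovery_n, variants, config, id_prefix = "D")
    eta <- drop(dos %*% architecture$beta[, subtype])
    y <- draw_with_prevalence(eta, config$base_prevalence[[subtype]],
                              paste0("discovery_", subtype))
    m <- ncol(dos)
    beta <- se <- numeric(m)
    for (j in seq_len(m)) {
      fit <- marginal_logistic(dos[, j], y)
      beta[j] <- fit[1]; se[j] <- fit[2]
    }
    p <- 2 * pnorm(-abs(beta / se))
    stats <- data.frame(
      ID = variants$id,
      CHROM = variants$chrom,
      POS = variants$pos,
      EFFECT_ALLELE = variants$a1,
      OTHER_ALLELE = variants$a2,
      BETA = beta,
      SE = se,
      P = p,
      EAF = colMeans(dos) / 2,
      N = config$discovery_n,
      stringsAsFactors = FALSE
    )
    inject_corruption(stats, variants, config$qc_injection_rates)
  })
}

# Single-variant logistic regression (intercept + dosage) via IRLS.
marginal_logistic <- function(g, y, max_iter = 25L, tol = 1e-10) {
  X <- cbind(1, g)
  b <- c(qlogis(max(mean(y), 1e-6)), 0)
  for (i in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% b))
    w <- mu * (1 - mu)
    XtW <- t(X * w)
    step <- tryCatch(solve(XtW %*% X, t(X) %*% (y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) break
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  mu <- plogis(drop(X %*% b))
  info <- t(X * (mu * (1 - mu))) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, 2))
  c(b[2], se[2])
}

# Corrupt rows in place; each row suffers at most one corruption type.
inject_corruption <- function(stats, variants, rates) {
  m <- nrow(stats)
  u <- runif(m)
  kind <- rep("", m)
  kind[u < rates[["strand_flip"]]] <- "strand_flip"
  kind[u >= rates[["strand_flip"]] &
         u < rates[["strand_flip"]] + rates[["raf_error"]]] <- "raf_error"
  kind[u >= rates[["strand_flip"]] + rates[["raf_error"]] &
         u < sum(rates[c("strand_flip", "raf_error", "ambiguous")])] <-
    "ambiguous"
  amb_panel <- is_ambiguous_pair(variants$a1, variants$a2)
  # flips are only meaningful (and repairable) for non-ambiguous variants;
  # ambiguous-mismatch injection needs an ambiguous panel variant
  kind[kind == "strand_flip" & amb_panel] <- ""
  kind[kind == "ambiguous" & !amb_panel] <- ""

  inj <- data.frame(ID = character(0), type = character(0),
                    stringsAsFactors = FALSE)
  for (i in which(kind != "")) {
    if (kind[i] == "strand_flip") {
      stats$EFFECT_ALLELE[i] <- complement_base(stats$EFFECT_ALLELE[i])
      stats$OTHER_ALLELE[i] <- complement_base(stats$OTHER_ALLELE[i])
    } else if (kind[i] == "raf_error") {
      delta <- runif(1, 0.20, 0.35) * sample(c(-1, 1), 1)
      eaf <- stats$EAF[i] + delta
      if (eaf < 0.01 || eaf > 0.99) eaf <- stats$EAF[i] - delta
      stats$EAF[i] <- eaf
    } else if (kind[i] == "ambiguous") {
      # replace with the *other* ambiguous pair so neither allele matches
      pair <- if (toupper(stats$EFFECT_ALLELE[i]) %in% c("A", "T"))
        c("C", "G") else c("A", "T")
      stats$EFFECT_ALLELE[i] <- pair[1]
      stats$OTHER_ALLELE[i] <- pair[2]
    }
    inj <- rbind(inj, data.frame(ID = stats$ID[i], type = kind[i],
                                 stringsAsFactors = FALSE))
  }
  attr(stats, "injections") <- inj
  class(stats) <- c("summary_stats", "data.frame")
  stats
}
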