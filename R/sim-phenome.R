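# Synthetic coded phenome.
#
# Disease model per subtype s:  logit P(case) = alpha_s + sum_i beta_is G_ij,
# with alpha_s solved so the marginal prevalence matches the configured
# target on the simulated cohort.  An "overall" code covers anyone with any
# subtype.  Secondary traits are driven by the standardized shared-locus
# genetic score (hence genetically correlated with the subtypes); mediated
# traits are driven by overall disease status itself and carry no direct
# genetic signal; null codes are independent coin flips.  Every diagnosis is
# emitted as dated ICD9 or ICD10 events through a synthetic two-vocabulary
# code map, and subjects carry sex, age, genotyping array and four PCs.

PHENO_WINDOW_START <- as.Date("2008-01-01")
PHENO_WINDOW_DAYS <- 3652L  # 10 years

#' Simulate a dated ICD-coded phenome
#'
#' @param geno A `dosage_data` object from [simulate_genotypes()].
#' @param architecture A `true_architecture` from [simulate_architecture()].
#' @param config The [sim_config()] used to generate both.
#' @return A list of class `sim_phenome` with elements:
#'   * `subjects`: data.frame `subject_id`, `sex`, `age`, `array`,
#'     `PC1`..`PC4`.
#'   * `events`: data.frame `subject_id`, `vocab` (ICD9/ICD10), `code`,
#'     `date`.
#'   * `phecode_map`: data.frame `phecode`, `description`, `vocab`, `code`
#'     (one ICD9 and one ICD10 alias per phenotype).
#'   * `phecodes`: named list tagging the phecode assigned to each simulated
#'     trait (`overall`, per-subtype, `secondary`, `mediated`, `null`).
#'   * `truth`: data.frame of 0/1 status per subject for every simulated
#'     trait, plus the standardized shared genetic score.
#' @export
simulate_phenome <- function(geno, architecture, config) {
  stopifnot(inherits(geno, "dosage_data"),
            inherits(architecture, "true_architecture"),
            inherits(config, "sim_config"))
  dos <- geno$dosages
  if (!identical(colnames(dos), rownames(architecture$beta)))
    stop("genotypes and architecture refer to different variant panels")
  n <- nrow(dos)
  subtypes <- subtype_names(config)

  with_seed(config$seed + 2L, {
    subjects <- data.frame(
      subject_id = rownames(dos),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = round(runif(n, 30, 85)),
      array = sample(c("arrayA", "arrayB"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (k in 1:4) subjects[[paste0("PC", k)]] <- rnorm(n)

    status <- list()
    for (s in subtypes) {
      eta <- drop(dos %*% architecture$beta[, s])
      status[[s]] <- draw_with_prevalence(eta, config$base_prevalence[[s]], s)
    }
    status$overall <- as.integer(Reduce(`|`, status[subtypes]))

    # shared genetic score (first subtype's betas restricted to shared loci)
    shared_z <- rep(0, n)
    if (length(architecture$shared_ids)) {
      sc <- drop(dos[, architecture$shared_ids, drop = FALSE] %*%
                   architecture$beta[architecture$shared_ids, subtypes[1]])
      if (sd(sc) > 0) shared_z <- (sc - mean(sc)) / sd(sc)
    }
    sec_names <- character(0)
    if (config$n_secondary_traits > 0) {
      sec_names <- sprintf("secondary%d", seq_len(config$n_secondary_traits))
      for (nm in sec_names) {
        status[[nm]] <- draw_with_prevalence(0.5 * shared_z, 0.10, nm)
      }
    }
    med_names <- character(0)
    if (config$n_mediated_traits > 0) {
      med_names <- sprintf("mediated%d", seq_len(config$n_mediated_traits))
      for (nm in med_names) {
        status[[nm]] <- draw_with_prevalence(1.5 * status$overall, 0.08, nm)
      }
    }
    null_names <- character(0)
    if (config$n_null_codes > 0) {
      null_names <- sprintf("null%03d", seq_len(config$n_null_codes))
      null_prev <- runif(config$n_null_codes, 0.03, 0.10)
      for (k in seq_along(null_names)) {
        status[[null_names[k]]] <- rbinom(n, 1L, null_prev[k])
      }
    }

    # phecode assignment: subtypes nest under the overall code "172"
    phecodes <- c(
      list(overall = "172"),
      setNames(as.list(sprintf("172.%d", seq_along(subtypes))), subtypes),
      setNames(as.list(sprintf("21%d", seq_along(sec_names))), sec_names),
      setNames(as.list(sprintf("28%d", seq_along(med_names))), med_names),
      setNames(as.list(sprintf("4%02d", seq_along(null_names))), null_names)
    )
    phecode_map <- make_phecode_map(phecodes)

    # events: subtype/mediated/null dates uniform over the window; secondary
    # dates likewise, so both orderings relative to a later primary
    # diagnosis occur and the 365-day lag rule is exercised.
    traits_with_events <- setdiff(names(status), "overall")
    ev <- list()
    for (nm in traits_with_events) {
      cases <- which(status[[nm]] == 1L)
      if (!length(cases)) next
      n_ev <- 1L + rpois(length(cases), 0.5)
      subj <- rep(subjects$subject_id[cases], n_ev)
      vocab <- sample(c("ICD9", "ICD10"), length(subj), replace = TRUE)
      code_of <- setNames(phecode_map$code,
                          paste(phecode_map$phecode, phecode_map$vocab))
      code <- code_of[paste(phecodes[[nm]], vocab)]
      date <- PHENO_WINDOW_START +
        sample.int(PHENO_WINDOW_DAYS, length(subj), replace = TRUE) - 1L
      ev[[nm]] <- data.frame(subject_id = subj, vocab = vocab,
                             code = unname(code), date = date,
                             stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, ev)
    rownames(events) <- NULL
    events <- events[order(events$subject_id, events$date), , drop = FALSE]

    truth <- data.frame(subject_id = subjects$subject_id,
                        as.data.frame(status), shared_z = shared_z,
                        stringsAsFactors = FALSE)
    structure(list(subjects = subjects, events = events,
                   phecode_map = phecode_map, phecodes = phecodes,
                   truth = truth),
              class = "sim_phenome")
  })
}

# Solve the intercept so mean(plogis(alpha + eta)) hits the target, then draw.
draw_with_prevalence <- function(eta, target, label) {
  f <- function(a) mean(plogis(a + eta)) - target
  alpha <- uniroot(f, c(-30, 30))$root
  y <- rbinom(length(eta), 1L, plogis(alpha + eta))
  prev <- mean(y)
  if (prev == 0 || prev == 1)
    stop("degenerate simulation: trait '", label, "' has prevalence ", prev)
  y
}

# One ICD9 and one ICD10 alias per phecode (synthetic vocabulary).
make_phecode_map <- function(phecodes) {
  ph <- unlist(phecodes, use.names = FALSE)
  desc <- names(phecodes)
  # include explicit rows for the hierarchy root so ICD lookups exist for it
  data.frame(
    phecode = rep(ph, each = 2L),
    description = rep(desc, each = 2L),
    vocab = rep(c("ICD9", "ICD10"), times = length(ph)),
    code = as.vector(rbind(paste0("9-", ph), paste0("X-", ph))),
    stringsAsFactors = FALSE
  )
}
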