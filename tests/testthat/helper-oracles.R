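# Independent oracles and in-code fixtures shared across tests.

# Seeded evaluation that restores the ambient RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

# Closed-form Firth slope on a saturated 2x2 design: the half-cell-corrected
# log odds ratio.
firth_2x2_closed <- function(a, b, c, d) {
  log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
}

# Fit a 2x2 design (cells: a = x1y1, b = x0y1, c = x1y0, d = x0y0) through
# firth_fit using counts as case weights.
firth_2x2_fit <- function(a, b, c, d) {
  x <- cbind(1, c(1, 0, 1, 0))
  y <- c(1, 1, 0, 0)
  firth_fit(x, y, weights = c(a, b, c, d))
}

# Brute-force Mann-Whitney AUC by pair counting.
auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (v in s1) tot <- tot + sum(v > s0) + 0.5 * sum(v == s0)
  tot / (length(s1) * length(s0))
}

# Naive greedy clumping oracle: repeatedly scan for the smallest-p active
# variant (ties by chrom, pos), retire correlated neighbors in-window.
oracle_clump <- function(stats, r2mat, chrom, pos, cfg) {
  maf <- pmin(stats$EAF, 1 - stats$EAF)
  active <- maf > cfg$maf_min & stats$P < cfg$p_entry
  kept <- character(0)
  while (any(active)) {
    idx <- which(active)
    best <- idx[order(stats$P[idx], chrom[idx], pos[idx])][1]
    kept <- c(kept, stats$ID[best])
    active[best] <- FALSE
    for (j in which(active)) {
      if (chrom[j] == chrom[best] &&
          abs(pos[j] - pos[best]) <= cfg$window_bp &&
          r2mat[best, j] > cfg$r2_threshold) {
        active[j] <- FALSE
      }
    }
  }
  ord <- match(kept, stats$ID)
  kept[order(chrom[ord], pos[ord])]
}

# Naive recency/p deduplication oracle.
oracle_dedup <- function(entries, r2mat, thr) {
  ord <- order(-as.numeric(as.Date(entries$pub_date)), entries$p_value,
               entries$chrom, entries$pos)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (k in kept) {
      if (entries$variant_id[i] == entries$variant_id[k] ||
          r2mat[i, k] > thr) conflict <- TRUE
    }
    if (!conflict) kept <- c(kept, i)
  }
  sort(entries$variant_id[kept])
}

# Build an ld_panel object directly from a correlation matrix.
make_ld_panel <- function(ids, chrom, pos, r) {
  dimnames(r) <- list(ids, ids)
  structure(list(ids = ids, chrom = chrom, pos = pos, r = r),
            class = "ld_panel")
}

# Random symmetric "correlation-like" matrix with unit diagonal.
random_r_matrix <- function(m) {
  r <- matrix(runif(m * m, -1, 1), m, m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

# Synthetic marginal effects coherent with an LD panel:
#   betahat_std ~ N(D beta_true, D / n)
make_marginal_effects <- function(ld, n, h2, frac_causal = 1, seed = 1) {
  m <- length(ld$ids)
  with_seed(seed, {
    beta <- rep(0, m)
    causal <- sample(m, max(1, round(m * frac_causal)))
    beta[causal] <- rnorm(length(causal), 0, sqrt(h2 / length(causal)))
    D <- ld$r
    ch <- chol(D + diag(1e-6, m))
    betahat <- drop(D %*% beta) + drop(t(ch) %*% rnorm(m)) / sqrt(n)
    eaf <- runif(m, 0.05, 0.95)
    se <- 1 / sqrt(n)  # standardized scale; z = betahat * sqrt(n)
    data.frame(id = ld$ids, chrom = ld$chrom, pos = ld$pos,
               effect_allele = "A", other_allele = "G", eaf = eaf, n = n,
               beta = betahat, beta_std = betahat, se = se,
               p = 2 * pnorm(-abs(betahat) * sqrt(n)),
               true_beta = beta, stringsAsFactors = FALSE)
  })
}

# Small cached cohort so module tests do not re-simulate per block.
.fixture <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture$cohort)) {
    cfg <- sim_config(n_subjects = 1200, n_variants = 400, n_null_codes = 8,
                      discovery_n = 6000, seed = 11)
    geno <- simulate_genotypes(cfg)
    arch <- simulate_architecture(cfg, geno$variants)
    phe <- simulate_phenome(geno, arch, cfg)
    stats <- simulate_discovery_gwas(arch, cfg, geno$variants)
    .fixture$cohort <- list(cfg = cfg, geno = geno, arch = arch, phe = phe,
                            stats = stats)
  }
  .fixture$cohort
}

# Rich matching pool: controls clustered tightly around the cases'
# covariates, same sex/array, so calipers are easy to satisfy.
rich_matching_pool <- function(n_cases = 40, per_case = 30, seed = 5) {
  with_seed(seed, {
    case_ids <- sprintf("C%03d", seq_len(n_cases))
    sex <- sample(c("F", "M"), n_cases, replace = TRUE)
    arr <- sample(c("arrayA", "arrayB"), n_cases, replace = TRUE)
    base <- data.frame(subject_id = case_ids, sex = sex, array = arr,
                       age = runif(n_cases, 40, 70),
                       PC1 = rnorm(n_cases), PC2 = rnorm(n_cases),
                       PC3 = rnorm(n_cases), PC4 = rnorm(n_cases),
                       stringsAsFactors = FALSE)
    pools <- lapply(seq_len(n_cases), function(i) {
      p <- base[rep(i, per_case), ]
      p$subject_id <- sprintf("P%03d_%02d", i, seq_len(per_case))
      for (v in c("age", "PC1", "PC2", "PC3", "PC4"))
        p[[v]] <- p[[v]] + rnorm(per_case, 0, 0.02)
      p
    })
    covariates <- rbind(base, do.call(rbind, pools))
    rownames(covariates) <- NULL
    list(cases = case_ids, pool = setdiff(covariates$subject_id, case_ids),
         covariates = covariates)
  })
}

# Tiny hand-built PRS models on a shared coordinate system.
toy_model <- function(ids, chrom, pos, weight, p = NA_real_,
                      effect = "A", other = "G", tag = "external",
                      trait = "toy") {
  prs_model(data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = rep_len(effect, length(ids)),
    other_allele = rep_len(other, length(ids)),
    weight = weight, p_value = rep_len(p, length(ids)),
    stringsAsFactors = FALSE), method_tag = tag, trait_label = trait)
}
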