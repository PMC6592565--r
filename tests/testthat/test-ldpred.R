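mk_raw_stats <- function(ids, ea, oa, eaf, n = 10000, beta = 0.1,
                         se = 0.02, p = 1e-4) {
  structure(data.frame(
    ID = ids, CHROM = "1", POS = seq_along(ids) * 1000L,
    EFFECT_ALLELE = ea, OTHER_ALLELE = oa, BETA = beta, SE = se, P = p,
    EAF = eaf, N = n, stringsAsFactors = FALSE),
    class = c("summary_stats", "data.frame"))
}

test_that("default input filters drop ambiguous, rare and non-SNP rows", {
  st <- mk_raw_stats(c("v1", "v2", "v3", "v4"),
                     ea = c("A", "A", "A", "AT"),
                     oa = c("G", "T", "G", "G"),
                     eaf = c(0.3, 0.3, 0.005, 0.3))
  panel <- data.frame(id = st$ID, chrom = "1", pos = st$POS, a1 = "A",
                      a2 = "G", stringsAsFactors = FALSE)
  me <- filter_ldpred_input(st, panel)
  expect_equal(me$id, "v1")  # v2 ambiguous, v3 MAF 0.5%, v4 indel
  # overlap filter: variants absent from either panel are dropped
  expect_error(filter_ldpred_input(mk_raw_stats("v1", "A", "G", 0.3), panel,
                                   target_variants = panel[0, ]),
               "no variants")
  expect_error(filter_ldpred_input(mk_raw_stats("zz", "A", "G", 0.3), panel),
               "no variants")
})

test_that("aggregate heritability estimator recovers simulated h2", {
  m <- 2000; n <- 20000
  ld <- make_ld_panel(sprintf("v%04d", 1:m), rep("1", m), 1:m * 1000L,
                      diag(m))
  me <- make_marginal_effects(ld, n = n, h2 = 0.5, seed = 42)
  h2 <- estimate_h2_aggregate(me, ld, n)
  expect_gt(h2, 0.4)
  expect_lt(h2, 0.6)
  # doubling N with the same chi2-generating h2 leaves the estimate stable
  me2 <- make_marginal_effects(ld, n = 2 * n, h2 = 0.5, seed = 43)
  h2b <- estimate_h2_aggregate(me2, ld, 2 * n)
  expect_lt(abs(h2b - h2), 0.12)
  # null statistics clamp to 0.01 with a warning
  me0 <- make_marginal_effects(ld, n = n, h2 = 1e-6, seed = 44)
  expect_warning(h20 <- estimate_h2_aggregate(me0, ld, n), "clamped")
  expect_equal(h20, 0.01)
})

test_that("infinitesimal weights obey the identity-LD closed form", {
  m <- 100; n <- 1000; h2 <- 0.5
  ld <- make_ld_panel(sprintf("v%03d", 1:m), rep("1", m), 1:m * 1000L,
                      diag(m))
  me <- make_marginal_effects(ld, n = n, h2 = h2, seed = 7)
  inf <- ldpred_inf(me, ld, h2 = h2, n = n)
  shrink <- n * h2 / (n * h2 + m)  # = 500/600
  expect_equal(shrink, 500 / 600)
  expect_equal(inf$weight_std, me$beta_std * shrink, tolerance = 1e-12)
  # no-shrinkage limit as h2 -> infinity
  inf_inf <- ldpred_inf(me, ld, h2 = 1e9, n = n)
  expect_equal(inf_inf$weight_std, me$beta_std, tolerance = 1e-6)
})

test_that("perfectly correlated duplicates split the effect", {
  # two copies of one variant: D = [[1,1],[1,1]] (ridge-jittered solve);
  # analytic solution of (lambda I + D) w = beta with beta = (b, b):
  # w = b / (2 + lambda) each, i.e. half the single-variant weight as
  # lambda -> 0
  n <- 10000; h2 <- 0.5; m <- 2
  lambda <- m / (n * h2)
  ld <- make_ld_panel(c("a", "b"), c("1", "1"), c(100L, 200L),
                      matrix(c(1, 1 - 1e-9, 1 - 1e-9, 1), 2))
  me <- data.frame(id = c("a", "b"), chrom = "1", pos = c(100L, 200L),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   n = n, beta = 0.1, beta_std = 0.05, se = 0.02, p = 1e-5,
                   stringsAsFactors = FALSE)
  w <- ldpred_inf(me, ld, h2 = h2, n = n)$weight_std
  expect_equal(w, rep(0.05 / (2 + lambda), 2), tolerance = 1e-4)
  # versus the single-variant case (its own M = 1): w = b / (1 + 1/(n h2))
  me1 <- me[1, , drop = FALSE]
  ld1 <- make_ld_panel("a", "1", 100L, matrix(1, 1, 1))
  w1 <- ldpred_inf(me1, ld1, h2 = h2, n = n)$weight_std
  lambda1 <- 1 / (n * h2)
  expect_equal(w1, 0.05 / (1 + lambda1), tolerance = 1e-10)
  # the duplicated pair splits what the lone variant would carry
  expect_equal(w[1] / w1, (1 + lambda1) / (2 + lambda), tolerance = 1e-3)
})

test_that("Gibbs sampler is seed-reproducible and null-calibrated", {
  m <- 120; n <- 10000
  ld <- make_ld_panel(sprintf("v%03d", 1:m), rep("1", m), 1:m * 1000L,
                      diag(m))
  me <- make_marginal_effects(ld, n = n, h2 = 0.2, seed = 9)
  cfg <- ldpred_config(h2 = 0.2, burn_in = 30, iterations = 200, seed = 77,
                       radius_snps = 50)
  g1 <- ldpred_gibbs(me, ld, cfg, fraction = 0.1)
  g2 <- ldpred_gibbs(me, ld, cfg, fraction = 0.1)
  expect_identical(g1$weight_std, g2$weight_std)  # bit reproducible
  # zero marginal effects: posterior means near zero
  me0 <- me
  me0$beta_std <- 0
  g0 <- ldpred_gibbs(me0, ld, cfg, fraction = 0.1)
  expect_true(all(abs(g0$weight_std) <= 3 * pmax(g0$weight_mcse, 1e-6)))
})

test_that("fraction = 1 chain agrees with the infinitesimal closed form", {
  m <- 150; n <- 10000; h2 <- 0.3
  with_seed(13, {
    g <- matrix(rbinom(400 * m, 2, 0.3), 400, m)
    colnames(g) <- sprintf("v%03d", 1:m)
  })
  geno <- structure(list(
    dosages = g,
    variants = data.frame(id = colnames(g), chrom = "1",
                          pos = 1:m * 1000L, a1 = "A", a2 = "G",
                          maf = 0.3, block = 1:m, stringsAsFactors = FALSE)),
    class = "dosage_data")
  rownames(geno$dosages) <- sprintf("S%03d", 1:400)
  ld <- compute_ld(geno)
  me <- make_marginal_effects(ld, n = n, h2 = h2, seed = 14)
  inf <- ldpred_inf(me, ld, h2 = h2, n = n)
  chains <- lapply(1:5, function(s) {
    cfg <- ldpred_config(h2 = h2, burn_in = 50, iterations = 400, seed = s)
    ldpred_gibbs(me, ld, cfg, fraction = 1)$weight_std
  })
  pooled <- Reduce(`+`, chains) / length(chains)
  # Monte-Carlo SE taken as the between-chain SD (conservative for the
  # pooled mean); small floor guards near-zero-variance coordinates
  sds <- apply(do.call(cbind, chains), 1, sd)
  expect_true(all(abs(pooled - inf$weight_std) <= 3 * pmax(sds, 5e-4)))
})

test_that("sparser priors shrink null variants harder", {
  m <- 200; n <- 5000
  ld <- make_ld_panel(sprintf("v%03d", 1:m), rep("1", m), 1:m * 1000L,
                      diag(m))
  me <- make_marginal_effects(ld, n = n, h2 = 0.05, seed = 20)
  med <- vapply(c(1, 0.1, 0.01), function(f) {
    cfg <- ldpred_config(h2 = 0.05, burn_in = 30, iterations = 200,
                         seed = 5)
    median(abs(ldpred_gibbs(me, ld, cfg, fraction = f)$weight_std))
  }, numeric(1))
  expect_true(all(diff(med) < 0))  # monotone decreasing with fraction
})

test_that("sparse truth favors the matching sparse prior on held-out data", {
  # 1% causal truth: compare predictive correlation of fraction 0.01 vs 1
  m <- 300; n <- 2000
  with_seed(55, {
    gtrain <- matrix(rbinom(3000 * m, 2, 0.3), 3000, m)
    colnames(gtrain) <- sprintf("v%03d", 1:m)
    rownames(gtrain) <- sprintf("S%04d", 1:3000)
  })
  geno <- structure(list(
    dosages = gtrain,
    variants = data.frame(id = colnames(gtrain), chrom = "1",
                          pos = 1:m * 1000L, a1 = "A", a2 = "G", maf = 0.3,
                          block = 1:m, stringsAsFactors = FALSE)),
    class = "dosage_data")
  ld <- make_ld_panel(colnames(gtrain), rep("1", m), 1:m * 1000L, diag(m))
  me <- make_marginal_effects(ld, n = n, h2 = 0.4, frac_causal = 0.01,
                              seed = 56)
  y <- drop(scale(gtrain) %*% me$true_beta) + rnorm(3000, 0, sqrt(0.6))
  cors <- vapply(c(0.01, 1), function(f) {
    cfg <- ldpred_config(h2 = 0.4, burn_in = 40, iterations = 300, seed = 6)
    w <- ldpred_gibbs(me, ld, cfg, fraction = f)$weight_std
    cor(drop(scale(gtrain) %*% w), y)
  }, numeric(1))
  expect_gt(cors[1], cors[2])
})

test_that("divergence guard aborts with a diagnostic", {
  m <- 50; n <- 10000
  ld <- make_ld_panel(sprintf("v%02d", 1:m), rep("1", m), 1:m * 1000L,
                      diag(m))
  me <- make_marginal_effects(ld, n = n, h2 = 0.5, seed = 70)
  cfg <- ldpred_config(h2 = 0.001, burn_in = 10, iterations = 50, seed = 2)
  expect_error(ldpred_gibbs(me, ld, cfg, fraction = 1), "diverged")
})
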