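test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(within_block_r = 1), "within_block_r")
  expect_error(sim_config(n_variants = 50, block_size = 10,
                          n_shared_causal = 6,
                          n_unique_causal_per_subtype = 10),
               "distinct LD blocks")
  expect_error(sim_config(base_prevalence = c(a = 0, b = 0.1, c = 0.1)),
               "base_prevalence")
})

test_that("a fixed seed reproduces byte-identical simulations", {
  cfg <- sim_config(n_subjects = 300, n_variants = 120, seed = 99,
                    n_shared_causal = 2, n_unique_causal_per_subtype = 2,
                    discovery_n = 500)
  run <- function() {
    g <- simulate_genotypes(cfg)
    a <- simulate_architecture(cfg, g$variants)
    p <- simulate_phenome(g, a, cfg)
    list(g = g, a = a, p = p)
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})

test_that("dosages live in [0,2] and blocks control LD", {
  co <- small_cohort()
  d <- co$geno$dosages
  expect_true(all(d >= 0 & d <= 2))
  # block span < 1 Mb, consecutive blocks > 1 Mb apart
  v <- co$geno$variants
  spans <- tapply(v$pos, v$block, function(p) diff(range(p)))
  expect_true(all(spans < 1e6))

  # r = 0: independent variants
  cfg0 <- sim_config(n_subjects = 2000, n_variants = 60, block_size = 6,
                     within_block_r = 0, n_shared_causal = 2,
                     n_unique_causal_per_subtype = 2, seed = 3)
  g0 <- simulate_genotypes(cfg0)
  r0 <- cor(g0$dosages)
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.05)

  # r = 0.6 recovered within Monte-Carlo tolerance at n = 5,000
  cfg6 <- sim_config(n_subjects = 5000, n_variants = 60, block_size = 6,
                     within_block_r = 0.6, n_shared_causal = 2,
                     n_unique_causal_per_subtype = 2, seed = 4)
  g6 <- simulate_genotypes(cfg6)
  v6 <- g6$variants
  within <- c()
  for (b in unique(v6$block)) {
    idx <- which(v6$block == b)
    rb <- cor(g6$dosages[, idx])
    within <- c(within, rb[upper.tri(rb)])
  }
  expect_gt(mean(within), 0.55)
  expect_lt(mean(within), 0.65)

  # duplicated column has r^2 = 1
  dd <- cbind(g0$dosages[, 1], g0$dosages[, 1])
  expect_equal(cor(dd)[1, 2]^2, 1)
})

test_that("architecture has the requested shared/unique structure", {
  co <- small_cohort()
  arch <- co$arch
  cfg <- co$cfg
  subtypes <- names(cfg$base_prevalence)
  nz <- lapply(subtypes, function(s) names(which(arch$beta[, s] != 0)))
  names(nz) <- subtypes
  # shared set is exactly the three-way intersection
  expect_setequal(arch$shared_ids, Reduce(intersect, nz))
  # per-subtype causal count
  for (s in subtypes)
    expect_length(nz[[s]],
                  cfg$n_shared_causal + cfg$n_unique_causal_per_subtype)
  # unique sets pairwise disjoint and disjoint from shared
  all_unique <- unlist(arch$unique_ids)
  expect_equal(anyDuplicated(all_unique), 0L)
  expect_length(intersect(all_unique, arch$shared_ids), 0)
  # shared effects identical across subtypes
  expect_true(all(arch$beta[arch$shared_ids, 1] ==
                    arch$beta[arch$shared_ids, 2]))
  expect_true(all(arch$beta[arch$shared_ids, 1] ==
                    arch$beta[arch$shared_ids, 3]))
  # causal variants come from distinct LD blocks
  causal <- unique(c(arch$shared_ids, all_unique))
  blocks <- co$geno$variants$block[match(causal, co$geno$variants$id)]
  expect_equal(anyDuplicated(blocks), 0L)

  # zero shared loci -> empty intersection
  cfg0 <- sim_config(n_subjects = 100, n_variants = 120, n_shared_causal = 0,
                     n_unique_causal_per_subtype = 2, seed = 8)
  g0 <- simulate_genotypes(cfg0)
  a0 <- simulate_architecture(cfg0, g0$variants)
  expect_length(a0$shared_ids, 0)
})

test_that("null-architecture prevalence matches the target", {
  cfg <- sim_config(n_subjects = 10000, n_variants = 120, seed = 21,
                    n_shared_causal = 2, n_unique_causal_per_subtype = 2,
                    n_null_codes = 0, n_secondary_traits = 0,
                    n_mediated_traits = 0)
  geno <- simulate_genotypes(cfg)
  arch <- simulate_architecture(cfg, geno$variants)
  arch$beta[] <- 0  # all effects off
  phe <- simulate_phenome(geno, arch, cfg)
  for (s in names(cfg$base_prevalence)) {
    pi <- cfg$base_prevalence[[s]]
    tol <- 2 * sqrt(pi * (1 - pi) / cfg$n_subjects)
    expect_lt(abs(mean(phe$truth[[s]]) - pi), tol)
  }
})

test_that("secondary traits correlate with the shared-locus score", {
  co <- small_cohort()
  tr <- co$phe$truth
  ct <- cor.test(tr$secondary1, tr$shared_z)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("phenome events use both vocabularies with parseable dates", {
  co <- small_cohort()
  ev <- co$phe$events
  expect_setequal(unique(ev$vocab), c("ICD9", "ICD10"))
  expect_s3_class(ev$date, "Date")
  # every subtype case has at least one event
  tr <- co$phe$truth
  sub1 <- names(co$cfg$base_prevalence)[1]
  cases <- tr$subject_id[tr[[sub1]] == 1]
  code9 <- co$phe$phecode_map$code[
    co$phe$phecode_map$phecode == co$phe$phecodes[[sub1]]]
  with_code <- unique(ev$subject_id[ev$code %in% code9])
  expect_setequal(cases, with_code)
})

test_that("discovery GWAS is calibrated at null and accurate at causal loci", {
  co <- small_cohort()
  stats <- co$stats
  inj <- attr(stats, "injections")
  causal <- rownames(co$arch$beta)[co$arch$beta[, 1] != 0]
  clean_null <- setdiff(setdiff(stats$ID, causal), inj$ID)
  # null calibration: |betahat| < 3 SE for ~99.7% of null variants; allow
  # a margin for LD tagging of causal blocks
  nn <- stats[stats$ID %in% clean_null, ]
  tagged <- co$geno$variants$block[match(nn$ID, co$geno$variants$id)] %in%
    co$geno$variants$block[match(causal, co$geno$variants$id)]
  nn <- nn[!tagged, ]
  expect_gt(mean(abs(nn$BETA) < 3 * nn$SE), 0.98)
  # causal variants estimated near truth (n = 6,000 here)
  cc <- stats[stats$ID %in% setdiff(causal, inj$ID), ]
  err <- abs(cc$BETA - co$arch$beta[cc$ID, 1])
  expect_lt(median(err), 0.1)
})

test_that("injected corruptions are present at the configured rates", {
  co <- small_cohort()
  inj <- attr(co$stats, "injections")
  expect_true(all(inj$type %in% c("strand_flip", "raf_error", "ambiguous")))
  n <- nrow(co$stats)
  rates <- co$cfg$qc_injection_rates
  n_flip <- sum(inj$type == "strand_flip")
  # flips only land on non-ambiguous panel variants (~2/3 of the panel)
  expect_gt(n_flip, 0)
  expect_lt(n_flip, 3 * rates[["strand_flip"]] * n)
  # each flipped row differs from the panel by complement
  v <- co$geno$variants
  for (id in inj$ID[inj$type == "strand_flip"]) {
    i <- match(id, co$stats$ID); j <- match(id, v$id)
    expect_setequal(c(co$stats$EFFECT_ALLELE[i], co$stats$OTHER_ALLELE[i]),
                    complement_base(c(v$a1[j], v$a2[j])))
  }
})

test_that("simulation TSV round trip preserves dosages and events", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  paths <- write_simulation(co$geno, co$phe, dir)
  back <- read_dosage_data(paths["dosages"], paths["variants"])
  expect_equal(unname(back$dosages), unname(co$geno$dosages),
               ignore_attr = TRUE)
  expect_equal(back$variants$id, co$geno$variants$id)
  ev <- read.delim(paths["events"], stringsAsFactors = FALSE)
  expect_equal(nrow(ev), nrow(co$phe$events))
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", ev$DATE)))
})
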