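mini_geno <- function(dosages, a1 = NULL, a2 = NULL) {
  m <- ncol(dosages)
  structure(list(
    dosages = dosages,
    variants = data.frame(
      id = colnames(dosages), chrom = "1", pos = seq_len(m) * 100L,
      a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m),
      maf = colMeans(dosages) / 2, block = seq_len(m),
      stringsAsFactors = FALSE)), class = "dosage_data")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scoring is a weighted dosage sum with allele orientation", {
  d <- matrix(c(2, 1, 0, 1, 2, 0.5), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("v1", "v2")))
  g <- mini_geno(d)
  # one variant, weight 1, dosage 2 -> 2
  m1 <- toy_model("v1", "1", 100L, 1.0)
  expect_equal(compute_prs(g, m1)$raw, c(2, 1, 0))
  # weights (0.5, 0.25) on dosages (1, 2) -> 1.0
  m2 <- toy_model(c("v1", "v2"), "1", c(100L, 200L), c(0.5, 0.25))
  expect_equal(compute_prs(g, m2)$raw[2], 0.5 * 1 + 0.25 * 2)
  # effect allele = matrix other allele: dosage flips to 2 - d
  m3 <- toy_model("v2", "1", 200L, 0.3, effect = "G", other = "A")
  expect_equal(compute_prs(g, m3)$raw[3], 0.3 * (2 - 0.5))
  # unknown allele is a hard error naming the variant
  m4 <- toy_model("v2", "1", 200L, 0.3, effect = "T", other = "C")
  expect_error(compute_prs(g, m4), "v2")
})

test_that("missing model variants are skipped with coverage reported", {
  d <- matrix(c(1, 2), nrow = 2, dimnames = list(c("s1", "s2"), "v1"))
  g <- mini_geno(d)
  m <- toy_model(c("v1", "vX"), "1", c(100L, 200L), c(0.5, 1.5))
  sc <- compute_prs(g, m)
  expect_equal(sc$raw, c(0.5, 1.0))
  expect_equal(attr(sc, "coverage"), 0.5 / 2.0)
  expect_error(compute_prs(g, m, strict = TRUE), "vX")
})

test_that("scoring is linear in disjoint models and allele-flip invariant", {
  co <- small_cohort()
  v <- co$geno$variants
  with_seed(17, {
    pick <- sample(nrow(v), 20)
    w <- rnorm(20)
  })
  mA <- prs_model(data.frame(
    variant_id = v$id[pick[1:10]], chrom = v$chrom[pick[1:10]],
    pos = v$pos[pick[1:10]], effect_allele = v$a1[pick[1:10]],
    other_allele = v$a2[pick[1:10]], weight = w[1:10],
    stringsAsFactors = FALSE))
  mB <- prs_model(data.frame(
    variant_id = v$id[pick[11:20]], chrom = v$chrom[pick[11:20]],
    pos = v$pos[pick[11:20]], effect_allele = v$a1[pick[11:20]],
    other_allele = v$a2[pick[11:20]], weight = w[11:20],
    stringsAsFactors = FALSE))
  mAB <- prs_model(rbind(mA$entries, mB$entries))
  expect_equal(compute_prs(co$geno, mAB)$raw,
               compute_prs(co$geno, mA)$raw + compute_prs(co$geno, mB)$raw)
  # flip a matrix variant's counted allele: d -> 2 - d, labels swapped
  g2 <- co$geno
  j <- pick[1]
  g2$dosages[, j] <- 2 - g2$dosages[, j]
  tmp <- g2$variants$a1[j]
  g2$variants$a1[j] <- g2$variants$a2[j]
  g2$variants$a2[j] <- tmp
  expect_equal(compute_prs(g2, mAB)$raw, compute_prs(co$geno, mAB)$raw)
})

test_that("z-transform standardizes over the analytical set", {
  sc <- structure(data.frame(subject_id = c("a", "b", "c"), raw = c(1, 2, 3),
                             stringsAsFactors = FALSE),
                  class = c("prs_scores", "data.frame"))
  z <- ztransform(sc)
  expect_equal(z$z, c(-1, 0, 1))  # sample SD = 1
  expect_error(ztransform(sc[1, ]), "at least 2")
  sc$raw <- rep(5, 3)
  expect_error(ztransform(sc), "zero-variance")
  with_seed(3, {
    sc2 <- data.frame(subject_id = sprintf("s%d", 1:50), raw = rnorm(50))
  })
  z2 <- ztransform(sc2, ids = sc2$subject_id[1:20])
  expect_equal(mean(z2$z), 0, tolerance = 1e-12)
  expect_equal(sd(z2$z), 1, tolerance = 1e-12)
  expect_equal(nrow(z2), 20)
})

test_that("locus merging chains SNPs within 1 Mb on one chromosome", {
  m1 <- toy_model(c("a", "b"), "1", c(1000000L, 1500000L), c(1, 1))
  ml <- merge_loci(list(x = m1))
  expect_equal(nrow(ml$loci), 1)  # 0.5 Mb apart: one locus
  m2 <- toy_model(c("a", "b"), c("1", "2"), c(1000000L, 1000000L), c(1, 1))
  expect_equal(nrow(merge_loci(list(x = m2))$loci), 2)  # different chroms
  # chaining: 1.0 / 1.9 / 2.8 Mb with 0.9 Mb gaps -> a single locus
  m3 <- toy_model(c("a", "b", "c"), "1", c(1000000L, 1900000L, 2800000L),
                  rep(1, 3))
  ml3 <- merge_loci(list(x = m3))
  expect_equal(nrow(ml3$loci), 1)
  expect_equal(ml3$loci$end - ml3$loci$start, 1800000L)
  # overlap table flags contributing models
  mA <- toy_model("a", "1", 1000000L, 1)
  mB <- toy_model("b", "1", 1500000L, 1)
  mC <- toy_model("z", "3", 500000L, 1)
  ov <- merge_loci(list(A = mA, B = mB, C = mC))$overlap
  expect_equal(dim(ov), c(2L, 3L))
  expect_true(all(ov[1, c("A", "B")]))
  expect_false(ov[1, "C"])
})

test_that("shared/unique decomposition follows the locus overlap", {
  # three models: locus L1 (pos ~1e6) in all three, L2 unique to A,
  # L3 unique to B, L4 in A and B only (neither shared nor unique)
  mA <- toy_model(c("a1", "a2", "a4"), "1", c(1000000L, 5000000L, 9000000L),
                  c(0.2, 0.3, 0.1), p = c(1e-9, 1e-7, 1e-5))
  mB <- toy_model(c("b1", "b3", "b4"), "1", c(1100000L, 7000000L, 9100000L),
                  c(-0.4, 0.2, 0.3), p = c(1e-12, 1e-6, 1e-4))
  mC <- toy_model("c1", "1", 1200000L, 0.5, p = 1e-8)
  dec <- decompose_shared_unique(list(A = mA, B = mB, C = mC))
  # shared: one representative for L1, smallest p across models (b1),
  # oriented to the risk allele with weight 1
  expect_equal(nrow(dec$shared$entries), 1)
  expect_equal(dec$shared$entries$variant_id, "b1")
  expect_equal(dec$shared$entries$weight, 1)
  expect_equal(dec$shared$entries$effect_allele, "G")  # flipped: b1 had -0.4
  expect_equal(dec$shared$method_tag, "shared")
  # unique: a2 for A, b3 for B, nothing for C; original weights kept
  expect_equal(dec$unique$A$entries$variant_id, "a2")
  expect_equal(dec$unique$A$entries$weight, 0.3)
  expect_equal(dec$unique$B$entries$variant_id, "b3")
  expect_equal(nrow(dec$unique$C$entries), 0)
  # shared and unique loci never intersect per subtype
  shared_loci <- dec$loci$membership$locus_id[
    dec$loci$membership$variant_id %in% dec$shared$entries$variant_id]
  for (nm in names(dec$unique)) {
    uloci <- dec$loci$membership$locus_id[
      dec$loci$membership$variant_id %in% dec$unique[[nm]]$entries$variant_id]
    expect_length(intersect(shared_loci, uloci), 0)
  }
  # fully disjoint models: unique(A) = all of A, empty shared with warning
  mD <- toy_model("d1", "5", 1000000L, 0.2)
  mE <- toy_model("e1", "6", 1000000L, 0.2)
  mF <- toy_model("f1", "7", 1000000L, 0.2)
  expect_warning(dec2 <- decompose_shared_unique(list(D = mD, E = mE, F = mF)),
                 "no loci")
  expect_equal(nrow(dec2$shared$entries), 0)
  expect_equal(dec2$unique$D$entries$variant_id, "d1")
})

test_that("true-architecture PRS discriminates its own subtype best", {
  cfg <- sim_config(n_subjects = 10000, n_variants = 200, block_size = 5,
                    within_block_r = 0.3, effect_sd = 0.3,
                    n_null_codes = 0, n_secondary_traits = 0,
                    n_mediated_traits = 0, seed = 61)
  geno <- simulate_genotypes(cfg)
  arch <- simulate_architecture(cfg, geno$variants)
  phe <- simulate_phenome(geno, arch, cfg)
  subtypes <- names(cfg$base_prevalence)
  v <- geno$variants
  auc <- matrix(NA_real_, 3, 3, dimnames = list(subtypes, subtypes))
  for (s in subtypes) {
    nz <- arch$beta[, s] != 0
    m <- prs_model(data.frame(
      variant_id = v$id[nz], chrom = v$chrom[nz], pos = v$pos[nz],
      effect_allele = v$a1[nz], other_allele = v$a2[nz],
      weight = arch$beta[nz, s], stringsAsFactors = FALSE))
    sc <- compute_prs(geno, m)
    for (t in subtypes) {
      auc[s, t] <- auc_pairs(sc$raw, phe$truth[[t]])
    }
  }
  # genetic signal: own-subtype AUC well above 0.5
  own <- diag(auc)
  expect_true(all(own > 0.55))
  # specificity: each PRS discriminates its own subtype best
  for (s in subtypes)
    expect_equal(which.max(auc[s, ]), match(s, subtypes),
                 ignore_attr = TRUE)
})
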