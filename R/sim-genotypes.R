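# Block-LD genotype generator.
#
# LD model: each block carries, per subject and per haplotype, one latent
# "block haplotype" allele ~ Bernoulli(p).  Every variant in the block copies
# that allele with probability phi = sqrt(within_block_r) and otherwise draws
# a fresh Bernoulli(p).  Two variants then share the latent allele with
# probability phi^2 = r, so their allele (and dosage) correlation is exactly
# r in expectation; distinct blocks are independent.  Dosage = sum of the two
# haplotypes, i.e. hard genotypes in {0, 1, 2} under HWE.

#' Simulate a block-LD dosage panel
#'
#' Generates a subjects-by-variants allele dosage matrix with equicorrelated
#' LD blocks and a matching variant table (chromosome, 1-based position,
#' forward-strand alleles, realized allele frequency). Blocks span less than
#' 1 Mb and consecutive blocks are separated by more than 1 Mb.
#'
#' @param config A [sim_config()].
#' @return An object of class `dosage_data`: a list with `dosages` (numeric
#'   matrix, rownames subject IDs, colnames variant IDs; counted allele is
#'   `a1`) and `variants` (data.frame with `id`, `chrom`, `pos`, `a1`, `a2`,
#'   `maf`, `block`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    panel <- make_variant_panel(config)
    dos <- draw_dosages(config$n_subjects, panel, config,
                        id_prefix = "S")
    rf <- attr(dos, "realized_freq")
    panel$maf <- pmin(rf, 1 - rf)  # realized, not target, MAF
    structure(list(dosages = dos, variants = panel), class = "dosage_data")
  })
}

# Variant panel: alleles, coordinates, per-block MAF.
make_variant_panel <- function(config) {
  m <- config$n_variants
  n_blocks <- ceiling(m / config$block_size)
  block <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(m)]
  within_idx <- sequence(tabulate(block))
  # Up to 10 blocks per chromosome; blocks 2 Mb apart, variants 5 kb apart
  # (capped so a block always spans < 1 Mb).
  chrom <- ((block - 1L) %/% 10L) + 1L
  block_on_chr <- ((block - 1L) %% 10L)
  step <- min(5000L, floor(9e5 / config$block_size))
  pos <- 1e6 + block_on_chr * 2e6 + (within_idx - 1L) * step
  block_maf <- runif(n_blocks, config$maf_range[1], config$maf_range[2])
  a1 <- character(m); a2 <- character(m)
  for (i in seq_len(m)) {
    pair <- sample(BASES, 2L)
    a1[i] <- pair[1]; a2[i] <- pair[2]
  }
  data.frame(
    id = sprintf("rs%d", seq_len(m) + 1000L),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    a1 = a1,
    a2 = a2,
    maf = block_maf[block],
    freq_a1 = block_maf[block],  # generating frequency of the counted allele
    block = block,
    stringsAsFactors = FALSE
  )
}

# Draw dosages for a fresh cohort on an existing panel (uses current RNG
# stream; callers control seeding).
draw_dosages <- function(n, panel, config, id_prefix = "S") {
  m <- nrow(panel)
  phi <- sqrt(config$within_block_r)
  dos <- matrix(0, nrow = n, ncol = m)
  for (h in 1:2) {
    hap <- matrix(0L, nrow = n, ncol = m)
    for (b in unique(panel$block)) {
      idx <- which(panel$block == b)
      p <- (panel$freq_a1 %||% panel$maf)[idx[1]]
      latent <- rbinom(n, 1L, p)
      for (j in idx) {
        copy <- runif(n) < phi
        hap[, j] <- ifelse(copy, latent, rbinom(n, 1L, p))
      }
    }
    dos <- dos + hap
  }
  dimnames(dos) <- list(sprintf("%s%05d", id_prefix, seq_len(n)), panel$id)
  # record realized frequency of the counted allele
  attr(dos, "realized_freq") <- colMeans(dos) / 2
  dos
}

#' Simulate a fresh cohort on an existing variant panel
#'
#' Draws genotypes for new subjects with the same variant panel, block
#' structure and allele frequencies as an existing `dosage_data` object —
#' e.g. an independent target cohort, an LD reference subset, or replicate
#' cohorts sharing one causal architecture.
#'
#' @param geno A `dosage_data` whose panel to reuse.
#' @param config The [sim_config()] that generated it (LD parameters).
#' @param n_subjects Cohort size (default `config$n_subjects`).
#' @param seed RNG seed for the new draw.
#' @param id_prefix Subject ID prefix (default "R").
#' @return A `dosage_data` with the same `variants` table.
#' @export
simulate_cohort <- function(geno, config, n_subjects = config$n_subjects,
                            seed = config$seed, id_prefix = "R") {
  stopifnot(inherits(geno, "dosage_data"), inherits(config, "sim_config"))
  if (is.null(geno$variants$block))
    stop("panel lacks block structure; was it built by simulate_genotypes()?")
  with_seed(seed, {
    dos <- draw_dosages(n_subjects, geno$variants, config,
                        id_prefix = id_prefix)
    structure(list(dosages = dos, variants = geno$variants),
              class = "dosage_data")
  })
}

#' @export
print.dosage_data <- function(x, ...) {
  cat(sprintf("dosage_data: %d subjects x %d variants (%d LD blocks)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$block))))
  invisible(x)
}
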