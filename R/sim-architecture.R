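#' Simulate a shared/unique causal architecture for three subtypes
#'
#' Draws causal loci from distinct LD blocks: a shared set whose effects are
#' identical across the three subtypes, plus a disjoint unique set per
#' subtype. Effects are Normal(0, effect_sd^2) per-allele log odds ratios.
#'
#' @param config A [sim_config()].
#' @param variants Variant table from [simulate_genotypes()] (the `variants`
#'   element), carrying a `block` column.
#' @return An object of class `true_architecture`: list with `beta` (matrix
#'   variants x subtypes of true log odds ratios, rownames variant IDs),
#'   `shared_ids` (character), and `unique_ids` (named list per subtype).
#' @export
simulate_architecture <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  subtypes <- subtype_names(config)
  n_loci <- config$n_shared_causal + 3L * config$n_unique_causal_per_subtype
  blocks <- unique(variants$block)
  if (n_loci > length(blocks))
    stop("insufficient variants: need ", n_loci, " distinct LD blocks, have ",
         length(blocks))
  with_seed(config$seed + 1L, {
    chosen <- sample(blocks, n_loci)
    # one causal variant per chosen block
    pick1 <- function(b) {
      idx <- which(variants$block == b)
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }
    causal_idx <- vapply(chosen, pick1, integer(1))
    shared_idx <- causal_idx[seq_len(config$n_shared_causal)]
    n_uni <- config$n_unique_causal_per_subtype
    rest <- causal_idx[seq.int(config$n_shared_causal + 1L,
                               length.out = 3L * n_uni)]
    unique_idx <- if (n_uni > 0L) {
      split(rest, rep(subtypes, each = n_uni))[subtypes]
    } else {
      setNames(rep(list(integer(0)), 3L), subtypes)
    }

    beta <- matrix(0, nrow = nrow(variants), ncol = 3,
                   dimnames = list(variants$id, subtypes))
    shared_eff <- rnorm(length(shared_idx), 0, config$effect_sd)
    for (s in subtypes) {
      beta[shared_idx, s] <- shared_eff
      beta[unique_idx[[s]], s] <- rnorm(length(unique_idx[[s]]), 0,
                                        config$effect_sd)
    }
    structure(list(
      beta = beta,
      shared_ids = variants$id[shared_idx],
      unique_ids = lapply(unique_idx, function(i) variants$id[i])
    ), class = "true_architecture")
  })
}

#' @export
print.true_architecture <- function(x, ...) {
  cat(sprintf("true_architecture: %d shared loci; unique per subtype: %s\n",
              length(x$shared_ids),
              paste(sprintf("%s=%d", names(x$unique_ids),
                            lengths(x$unique_ids)), collapse = ", ")))
  invisible(x)
}
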