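# Shared helpers: allele arithmetic, seeded evaluation, small validators.

BASES <- c("A", "C", "G", "T")

#' Complement DNA bases
#'
#' Strand complement of single-base allele codes (vectorised).
#'
#' @param x Character vector of bases ("A", "C", "G", "T").
#' @return Character vector of complementary bases.
#' @export
complement_base <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- unname(comp[toupper(x)])
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(x[is.na(out)])
    stop("malformed base(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Is an allele pair strand-ambiguous?
#'
#' A/T and C/G pairs read the same on both strands, so strand flips cannot
#' be detected from the alleles alone.
#'
#' @param a1,a2 Character vectors of single-base alleles.
#' @return Logical vector.
#' @export
is_ambiguous_pair <- function(a1, a2) {
  toupper(a1) == complement_base(toupper(a2))
}

is_snp_allele <- function(x) {
  !is.na(x) & toupper(x) %in% BASES
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
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

stopifnot_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
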