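# Delimited-text readers/writers for the pipeline's interchange formats.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation outputs as TSV files
#'
#' Emits the standard interchange files for a simulated cohort: dosage
#' matrix (rows subjects, columns variant IDs), variant table, subject
#' table, code events, and the truth table of per-subject trait status.
#'
#' @param geno A `dosage_data`.
#' @param phenome A `sim_phenome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_simulation <- function(geno, phenome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dosages = file.path(dir, "dosages.tsv"),
    variants = file.path(dir, "variants.tsv"),
    subjects = file.path(dir, "subjects.tsv"),
    events = file.path(dir, "events.tsv"),
    truth = file.path(dir, "truth.tsv"),
    phecode_map = file.path(dir, "phecode_map.tsv")
  )
  dos <- data.frame(SUBJECT_ID = rownames(geno$dosages), geno$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(dos, paths["dosages"])
  v <- geno$variants
  write_tsv(data.frame(CHROM = v$chrom, POS = v$pos, ID = v$id, A1 = v$a1,
                       A2 = v$a2, MAF = v$maf), paths["variants"])
  write_tsv(phenome$subjects, paths["subjects"])
  ev <- phenome$events
  ev$date <- format(ev$date, "%Y-%m-%d")
  names(ev) <- c("SUBJECT_ID", "VOCAB", "CODE", "DATE")
  write_tsv(ev, paths["events"])
  write_tsv(phenome$truth, paths["truth"])
  write_tsv(phenome$phecode_map, paths["phecode_map"])
  paths
}

#' Write GWAS summary statistics as TSV
#'
#' @param stats `summary_stats` data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sumstats <- function(stats, path) write_tsv(stats, path)

#' Read GWAS summary statistics from TSV
#'
#' Expects columns `ID`, `CHROM`, `POS`, `EFFECT_ALLELE`, `OTHER_ALLELE`,
#' `BETA`, `SE`, `P`, `EAF`, `N`.
#'
#' @param path TSV path.
#' @return `summary_stats` data.frame.
#' @export
read_sumstats <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(CHROM = "character"))
  need <- c("ID", "CHROM", "POS", "EFFECT_ALLELE", "OTHER_ALLELE", "BETA",
            "SE", "P", "EAF", "N")
  if (!all(need %in% names(s)))
    stop("summary statistics missing column(s): ",
         paste(setdiff(need, names(s)), collapse = ", "))
  class(s) <- c("summary_stats", "data.frame")
  s
}

#' Read catalog-style association entries from TSV
#'
#' Expects columns `variant_id`, `risk_allele`, `raf`, `odds_ratio`,
#' `p_value`, `pub_date` and optionally `ancestry_label`, `trait`.
#'
#' @param path TSV path.
#' @return data.frame of catalog entries with `pub_date` parsed as Date.
#' @export
read_catalog <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "risk_allele", "raf", "odds_ratio", "p_value",
            "pub_date")
  if (!all(need %in% names(e)))
    stop("catalog file missing column(s): ",
         paste(setdiff(need, names(e)), collapse = ", "))
  e$pub_date <- as.Date(e$pub_date)
  e
}

#' Read a dosage matrix and variant table from TSV
#'
#' Inverse of the [write_simulation()] dosage/variant files.
#'
#' @param dosage_path,variant_path TSV paths.
#' @return A `dosage_data` object.
#' @export
read_dosage_data <- function(dosage_path, variant_path) {
  d <- read.delim(dosage_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  v <- read.delim(variant_path, stringsAsFactors = FALSE,
                  colClasses = c(CHROM = "character"))
  variants <- data.frame(id = v$ID, chrom = v$CHROM, pos = v$POS,
                         a1 = v$A1, a2 = v$A2, maf = v$MAF,
                         stringsAsFactors = FALSE)
  m <- m[, variants$id, drop = FALSE]
  structure(list(dosages = m, variants = variants), class = "dosage_data")
}

#' Write per-subject PRS scores as TSV
#'
#' @param scores A `prs_scores` table (ideally after [ztransform()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(SUBJECT_ID = scores$subject_id, RAW = scores$raw,
                    Z = scores$z %||% NA_real_,
                    COVERAGE = attr(scores, "coverage") %||% NA_real_)
  write_tsv(out, path)
}
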