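# Static results catalog: downloadable weight files, PheWAS JSON payloads,
# and a server-free HTML tree with inline SVG Manhattan plots.

#' Export a PRS model as a downloadable weight file
#'
#' TSV with columns CHROM, POS, ID, EFFECT_ALLELE, OTHER_ALLELE, WEIGHT,
#' METHOD_TAG, TRAIT; weights written at full double precision so a
#' read-back reproduces the model exactly.
#'
#' @param model A [prs_model()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_weights <- function(model, path) {
  stopifnot(inherits(model, "prs_model"))
  e <- model$entries
  if (!nrow(e)) warning("empty PRS model: writing header-only weight file")
  df <- data.frame(
    CHROM = e$chrom, POS = e$pos, ID = e$variant_id,
    EFFECT_ALLELE = e$effect_allele, OTHER_ALLELE = e$other_allele,
    WEIGHT = sprintf("%.17g", e$weight),
    P_VALUE = sprintf("%.17g", e$p_value),
    METHOD_TAG = rep(model$method_tag, nrow(e)),
    TRAIT = rep(model$trait_label, nrow(e)),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Read a weight file back into a PRS model
#'
#' @param path Weight-file path written by [export_weights()].
#' @return A [prs_model()].
#' @export
read_prs_model <- function(path) {
  w <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(CHROM = "character"))
  prs_model(data.frame(
    variant_id = w$ID, chrom = w$CHROM, pos = w$POS,
    effect_allele = w$EFFECT_ALLELE, other_allele = w$OTHER_ALLELE,
    weight = as.numeric(w$WEIGHT),
    p_value = suppressWarnings(as.numeric(w$P_VALUE %||% NA)),
    stringsAsFactors = FALSE
  ), method_tag = if (nrow(w)) w$METHOD_TAG[1] else "external",
  trait_label = if (nrow(w)) w$TRAIT[1] else "trait")
}

#' PheWAS results as a plot-ready JSON document
#'
#' Per-phecode records (code, description, group, -log10 p, direction, OR
#' with CI), the phenome-wide Bonferroni threshold, and a PRS provenance
#' block. Records with undefined p-values are flagged, not dropped.
#'
#' @param results A `phewas_result`.
#' @param metadata Named list describing the PRS (trait, method_tag, ...).
#' @param descriptions Optional named character: phecode -> description.
#' @param path Optional path; when given the JSON is written there.
#' @return The document as a list (invisibly when `path` is given).
#' @export
export_phewas_json <- function(results, metadata = list(), descriptions = NULL,
                               path = NULL) {
  stopifnot(nrow(results) > 0)
  z <- qnorm(0.975)
  records <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    flagged <- !is.finite(r$p)
    list(
      phecode = r$phecode,
      description = unname(descriptions[r$phecode] %||% r$phecode),
      group = sub("\\..*$", "", r$phecode),
      n_case = r$n_case, n_control = r$n_control,
      neglog10_p = if (flagged) NA else -log10(r$p),
      direction = r$direction,
      or = exp(r$beta_prs),
      or_lower = exp(r$beta_prs - z * r$se),
      or_upper = exp(r$beta_prs + z * r$se),
      bonferroni_significant = r$bonferroni_significant,
      flagged = flagged
    )
  })
  doc <- list(
    prs = metadata,
    n_studies = attr(results, "n_tested") %||% nrow(results),
    bonferroni_threshold = attr(results, "threshold") %||%
      (0.05 / nrow(results)),
    results = records
  )
  if (!is.null(path)) {
    # digits = I(17): enough significant digits to round-trip doubles
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Validate a PheWAS JSON document against the shipped schema
#'
#' Structural check against the field lists in the package's JSON schema
#' (`inst/extdata/phewas-results-schema.json`).
#'
#' @param doc A list as returned by [export_phewas_json()] (or parsed from
#'   disk with `jsonlite::read_json`).
#' @return TRUE (invisibly) or an error describing the first violation.
#' @export
validate_phewas_json <- function(doc) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "phewas-results-schema.json",
                                            package = "prsphewas"))
  need_top <- unlist(schema$required)
  miss <- setdiff(need_top, names(doc))
  if (length(miss)) stop("document missing field(s): ",
                         paste(miss, collapse = ", "))
  need_rec <- unlist(schema$properties$results$items$required)
  for (i in seq_along(doc$results)) {
    m <- setdiff(need_rec, names(doc$results[[i]]))
    if (length(m)) stop("result record ", i, " missing field(s): ",
                        paste(m, collapse = ", "))
  }
  invisible(TRUE)
}

#' Bundle one (trait, method) result set for the catalog
#'
#' @param trait,method_tag Identity of the PRS.
#' @param model The [prs_model()].
#' @param phewas A `phewas_result`.
#' @param exclusion Optional exclusion-scan `phewas_result`.
#' @param metrics Optional `eval_metrics`.
#' @param descriptions Optional phecode -> description vector.
#' @return List of class `catalog_bundle`.
#' @export
catalog_bundle <- function(trait, method_tag, model, phewas,
                           exclusion = NULL, metrics = NULL,
                           descriptions = NULL) {
  structure(list(trait = trait, method_tag = method_tag, model = model,
                 phewas = phewas, exclusion = exclusion, metrics = metrics,
                 descriptions = descriptions), class = "catalog_bundle")
}

#' Render the static results catalog
#'
#' Writes an index page plus one page per (trait, method) bundle with an
#' inline SVG Manhattan plot, the embedded JSON payload, a top-hit table,
#' and a link to the downloadable weight file. No server is required.
#'
#' @param bundles List of [catalog_bundle()]s.
#' @param dir Output directory.
#' @return Named character vector of written page paths.
#' @export
render_catalog <- function(bundles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pages <- character(0)
  items <- character(0)
  for (b in bundles) {
    stopifnot(inherits(b, "catalog_bundle"))
    slug <- gsub("[^A-Za-z0-9]+", "_", paste(b$trait, b$method_tag, sep = "_"))
    wfile <- paste0(slug, "_weights.tsv")
    export_weights(b$model, file.path(dir, wfile))
    json <- export_phewas_json(b$phewas,
                               metadata = list(trait = b$trait,
                                               method_tag = b$method_tag),
                               descriptions = b$descriptions)
    page <- paste0(slug, ".html")
    html <- render_result_page(b, json, wfile)
    writeLines(html, file.path(dir, page))
    pages[slug] <- file.path(dir, page)
    items <- c(items, sprintf('<li><a href="%s">%s — %s</a></li>',
                              page, escape_html(b$trait),
                              escape_html(b$method_tag)))
  }
  index <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
             "<title>PRS-PheWAS catalog</title></head><body>",
             "<h1>PRS-PheWAS catalog</h1>", "<ul>", items, "</ul>",
             "</body></html>")
  writeLines(index, file.path(dir, "index.html"))
  c(index = file.path(dir, "index.html"), pages)
}

escape_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_result_page <- function(b, json, wfile) {
  res <- b$phewas
  top <- res[order(res$p), , drop = FALSE]
  top <- head(top, 10)
  top_rows <- sprintf(
    "<tr><td>%s</td><td>%d</td><td>%d</td><td>%.3f</td><td>%.2e</td><td>%s</td></tr>",
    escape_html(top$phecode), top$n_case, top$n_control,
    exp(top$beta_prs), top$p, ifelse(top$bonferroni_significant, "yes", "no"))
  metrics_block <- if (!is.null(b$metrics)) {
    m <- b$metrics
    sprintf(paste0("<h2>Evaluation</h2><p>AUC %.3f (%.3f–%.3f); HL χ² %.2f ",
                   "(p %.3f); Brier %.3f; Nagelkerke R² %.3f; OR/SD %.2f ",
                   "(train n=%d, test n=%d)</p>"),
            m$auc, m$auc_lower, m$auc_upper, m$hl_chi2, m$hl_p, m$brier,
            m$nagelkerke_r2, m$or_per_sd, m$n_train, m$n_test)
  } else ""
  exclusion_block <- if (!is.null(b$exclusion) && nrow(b$exclusion)) {
    ex <- b$exclusion[order(b$exclusion$p), , drop = FALSE]
    ex <- head(ex, 5)
    paste0("<h2>Exclusion PheWAS (top hits)</h2><ul>",
           paste(sprintf("<li>%s: OR %.3f, p %.2e</li>",
                         escape_html(ex$phecode), exp(ex$beta_prs), ex$p),
                 collapse = ""),
           "</ul>")
  } else ""
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>%s — %s</title></head><body>", escape_html(b$trait),
            escape_html(b$method_tag)),
    sprintf("<h1>%s — %s</h1>", escape_html(b$trait),
            escape_html(b$method_tag)),
    sprintf('<p><a href="%s">Download weight file</a> (%d variants)</p>',
            wfile, nrow(b$model$entries)),
    "<h2>PheWAS</h2>", manhattan_svg(res),
    "<h2>Top associations</h2>",
    "<table border='1'><tr><th>phecode</th><th>cases</th><th>controls</th>",
    "<th>OR/SD</th><th>p</th><th>phenome-wide</th></tr>", top_rows,
    "</table>", metrics_block, exclusion_block,
    "<h2>JSON payload</h2>",
    "<script type='application/json' id='phewas-data'>",
    as.character(jsonlite::toJSON(json, auto_unbox = TRUE, digits = I(17),
                                  na = "null")),
    "</script>", "</body></html>")
}

#' Static SVG Manhattan plot of PheWAS results
#'
#' @param results A `phewas_result`.
#' @param width,height Pixel dimensions.
#' @return A character vector of SVG markup.
#' @export
manhattan_svg <- function(results, width = 900, height = 300) {
  res <- results[order(results$phecode), , drop = FALSE]
  nl <- -log10(pmax(res$p, 1e-300))
  nl[!is.finite(nl)] <- 0
  ymax <- max(nl, -log10(attr(results, "threshold") %||% 0.05), 1) * 1.1
  n <- nrow(res)
  px <- 40 + (seq_len(n) - 0.5) / n * (width - 60)
  py <- (height - 30) - nl / ymax * (height - 50)
  group <- as.integer(factor(sub("\\..*$", "", res$phecode)))
  cols <- rep(c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                "#8c564b"), length.out = max(group))
  thr <- attr(results, "threshold") %||% (0.05 / n)
  ty <- (height - 30) - (-log10(thr)) / ymax * (height - 50)
  pts <- sprintf('<circle cx="%.1f" cy="%.1f" r="3" fill="%s"><title>%s p=%.2e</title></circle>',
                 px, py, cols[group], escape_html(res$phecode), res$p)
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('<line x1="40" y1="%.1f" x2="%d" y2="%.1f" stroke="red" stroke-dasharray="4"/>',
            ty, width - 20, ty),
    sprintf('<line x1="40" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            height - 30, width - 20, height - 30),
    '<text x="5" y="15" font-size="11">-log10(p)</text>',
    pts, "</svg>")
}
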