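#' Compare formulations in a single report
#'
#' Scores each formulation against one affinity table and assembles a
#' comparison report with one row per formulation: label, annotation,
#' component summary, TE, TERE fraction and denominator, alpha load,
#' risk percent and relevance flag. Rows are ordered by descending TE
#' (larger TE reads as closer to estradiol's activity), ties broken by
#' label ascending; `sort = FALSE` preserves the input order, which is
#' useful when mirroring a published table row for row.
#'
#' @param formulations non-empty list of [formulation()] objects (a
#'   single formulation is also accepted).
#' @param table an [affinity_table()].
#' @param mode `"combined"` or `"beta_only"`.
#' @param sort order rows by descending TE (default) or keep input order.
#' @param registry compound registry for aglycone conversion.
#' @param threshold_denominator relevance cutoff, see
#'   [classify_relevance()].
#' @return an object of class `tere_comparison`: list with
#'   `affinity_label`, `mode`, `rows` (data.frame) and `scores` (the
#'   underlying `tere_score` objects, in row order).
#' @export
#' @examples
#' f1 <- formulation("assay-1", data.frame(
#'   compound = c("daidzein", "genistein"), intake_mg = c(25, 75)))
#' f2 <- formulation("assay-2", data.frame(
#'   compound = c("daidzein", "genistein"), intake_mg = c(75, 25)))
#' compare_formulations(list(f1, f2))
compare_formulations <- function(formulations,
                                 table = default_affinity_table(),
                                 mode = c("combined", "beta_only"),
                                 sort = TRUE,
                                 registry = default_compound_registry(),
                                 threshold_denominator = 15.2) {
  mode <- match.arg(mode)
  if (inherits(formulations, "formulation")) formulations <- list(formulations)
  if (!is.list(formulations) || length(formulations) == 0L ||
      !all(vapply(formulations, inherits, TRUE, "formulation"))) {
    stop_terescore(
      "`formulations` must be a non-empty list of formulation objects",
      "terescore_validation_error")
  }

  scores <- lapply(formulations, function(f) {
    tryCatch(
      score_formulation(f, table = table, mode = mode, registry = registry,
                        threshold_denominator = threshold_denominator),
      terescore_error = function(e) stop_terescore(
        paste0("failed to score formulation '", f$label, "': ",
               conditionMessage(e)),
        class(e)[1])
    )
  })

  rows <- do.call(rbind, lapply(scores, function(s) {
    data.frame(
      label = s$label,
      annotation = s$annotation,
      components = paste(
        sprintf("%g mg %s", s$per_compound$intake_mg, s$per_compound$compound),
        collapse = " + "),
      te = s$te,
      tere_fraction = s$tere_fraction,
      tere_denominator = s$tere_denominator,
      alpha_load = s$alpha_load,
      risk_percent = s$risk_percent,
      relevance = s$relevance,
      stringsAsFactors = FALSE
    )
  }))

  ord <- seq_len(nrow(rows))
  if (isTRUE(sort)) ord <- order(-rows$te, rows$label)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL

  structure(
    list(affinity_label = table$label, mode = mode,
         rows = rows, scores = scores[ord]),
    class = "tere_comparison"
  )
}

#' Format a comparison report
#'
#' @param report a `tere_comparison` from [compare_formulations()].
#' @param format `"tsv"` (stable machine interface), `"text"` (aligned
#'   table) or `"structured"` (YAML document).
#' @return character vector of output lines.
#' @export
format_comparison <- function(report, format = c("tsv", "text", "structured")) {
  stopifnot(inherits(report, "tere_comparison"))
  format <- match.arg(format)
  rows <- report$rows

  disp <- data.frame(
    label = rows$label,
    annotation = rows$annotation,
    components = rows$components,
    te = trimws(formatC(rows$te, format = "fg", digits = 6)),
    tere = rows$tere_fraction,
    alpha_load = signif(rows$alpha_load, 3),
    risk_percent = formatC(rows$risk_percent, format = "f", digits = 1),
    relevance = rows$relevance,
    stringsAsFactors = FALSE
  )

  if (format == "tsv") {
    header <- paste(names(disp), collapse = "\t")
    body <- apply(disp, 1, paste, collapse = "\t")
    return(c(header, unname(body)))
  }
  if (format == "structured") {
    doc <- list(
      affinity_label = report$affinity_label,
      mode = report$mode,
      formulations = lapply(seq_len(nrow(rows)), function(i) {
        r <- rows[i, ]
        list(label = r$label, annotation = r$annotation,
             components = r$components, te = r$te,
             tere = r$tere_fraction, tere_denominator = r$tere_denominator,
             alpha_load = r$alpha_load, risk_percent = r$risk_percent,
             relevance = r$relevance)
      })
    )
    return(strsplit(yaml::as.yaml(doc, precision = 15L), "\n", fixed = TRUE)[[1]])
  }
  # aligned plain text
  m <- rbind(names(disp), as.matrix(disp))
  widths <- apply(nchar(m, type = "width"), 2, max)
  fmt_row <- function(r) paste(mapply(formatC, r, width = widths,
                                      flag = "-"), collapse = "  ")
  c(fmt_row(m[1, ]),
    paste(rep("-", sum(widths) + 2 * (ncol(m) - 1)), collapse = ""),
    apply(m[-1, , drop = FALSE], 1, fmt_row))
}

#' Write a comparison report to a file or connection
#'
#' @inheritParams format_comparison
#' @param path output file path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path,
                             format = c("tsv", "text", "structured")) {
  lines <- format_comparison(report, format)
  if (identical(path, "")) writeLines(lines) else writeLines(lines, path)
  invisible(path)
}

#' @export
print.tere_comparison <- function(x, ...) {
  cat("<tere_comparison> ", nrow(x$rows), " formulation(s), mode ", x$mode,
      ", affinities: ", x$affinity_label, "\n", sep = "")
  writeLines(format_comparison(x, "text"))
  invisible(x)
}
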