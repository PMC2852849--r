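#' Construct an affinity table
#'
#' An affinity table holds per-compound relative binding affinities (RBA,
#' percent of estradiol's binding, so estradiol is 100) at the alpha and
#' beta estrogen receptors, plus optional proxy entries: a proxy maps a
#' compound with no measured affinities onto a structurally and
#' metabolically similar compound whose affinities stand in for it.
#' Affinities are stored on the printed percentage scale (0.860 means
#' 0.860%); division by 100 happens only inside the scoring step.
#'
#' @param records data.frame with columns `name`, `rba_alpha`, `rba_beta`
#'   and optionally `source` (free-text provenance). Names are
#'   canonicalized via [canonical_name()].
#' @param proxies named character vector mapping a compound name to the
#'   compound whose affinities stand in for it. Every target must be a
#'   record; chains (proxy of a proxy) are rejected.
#' @param label name of the affinity set.
#' @return an object of class `affinity_table`.
#' @seealso [default_affinity_table()], [resolve_affinity()],
#'   [read_affinity_table()]
#' @export
#' @examples
#' affinity_table(
#'   data.frame(name = "estradiol", rba_alpha = 100, rba_beta = 100),
#'   label = "reference only"
#' )
affinity_table <- function(records, proxies = character(), label = "custom") {
  if (!is.data.frame(records) ||
      !all(c("name", "rba_alpha", "rba_beta") %in% names(records))) {
    stop_terescore(
      "`records` must be a data.frame with columns name, rba_alpha, rba_beta",
      "terescore_validation_error"
    )
  }
  if (nrow(records) == 0L) {
    stop_terescore("affinity table needs at least one record",
                   "terescore_validation_error")
  }
  if (length(proxies) && (is.null(names(proxies)) || any(!nzchar(names(proxies))))) {
    stop_terescore("`proxies` must be a named character vector",
                   "terescore_validation_error")
  }
  if (!is_scalar_string(label)) {
    stop_terescore("`label` must be a non-empty string",
                   "terescore_validation_error")
  }

  records <- data.frame(
    name      = canonical_name(as.character(records$name)),
    rba_alpha = as.numeric(records$rba_alpha),
    rba_beta  = as.numeric(records$rba_beta),
    source    = if ("source" %in% names(records))
      as.character(records$source) else "",
    stringsAsFactors = FALSE
  )
  records$source[is.na(records$source)] <- ""

  if (anyDuplicated(records$name)) {
    stop_terescore(
      paste0("duplicate affinity records for: ",
             paste(unique(records$name[duplicated(records$name)]),
                   collapse = ", ")),
      "terescore_validation_error"
    )
  }
  if (any(!is.finite(records$rba_alpha)) || any(!is.finite(records$rba_beta)) ||
      any(records$rba_alpha < 0) || any(records$rba_beta < 0)) {
    stop_terescore("relative binding affinities must be finite and >= 0",
                   "terescore_validation_error")
  }

  if (length(proxies)) {
    proxies <- stats::setNames(canonical_name(as.character(proxies)),
                               canonical_name(names(proxies)))
  } else {
    proxies <- stats::setNames(character(), character())
  }
  if (length(proxies)) {
    missing_target <- setdiff(unname(proxies), records$name)
    if (length(missing_target)) {
      stop_terescore(
        paste0("proxy target(s) not in records: ",
               paste(missing_target, collapse = ", ")),
        "terescore_validation_error"
      )
    }
    chained <- intersect(unname(proxies), names(proxies))
    if (length(chained)) {
      stop_terescore(
        paste0("proxy chains are not allowed (proxy of a proxy): ",
               paste(chained, collapse = ", ")),
        "terescore_validation_error"
      )
    }
    shadowed <- intersect(names(proxies), records$name)
    if (length(shadowed)) {
      stop_terescore(
        paste0("proxy name(s) shadow existing records: ",
               paste(shadowed, collapse = ", ")),
        "terescore_validation_error"
      )
    }
  }

  structure(
    list(records = records, proxies = proxies, label = label),
    class = "affinity_table"
  )
}

#' The packaged default affinity table
#'
#' Relative binding affinities (percent of estradiol) at alpha and beta
#' estrogen receptors for estradiol and the five major isoflavone
#' aglycones, from the Fokialakis et al. competitive-binding data set,
#' plus a proxy mapping glycitein onto daidzein (glycitein's affinities
#' are not tabulated; its gut metabolism parallels daidzein's and its
#' contribution is minor, so daidzein's affinities stand in).
#'
#' Estradiol's beta-receptor binding is reported as "at most 100"; the
#' table stores 100 so that the estradiol reference score is exactly
#' defined (TERE uses 100 as the full-binding reference).
#'
#' @return an [affinity_table()].
#' @export
#' @examples
#' default_affinity_table()
default_affinity_table <- function() {
  affinity_table(
    records = data.frame(
      name      = c("estradiol", "daidzein", "genistein",
                    "formononetin", "biochanin a"),
      rba_alpha = c(100, 0.031, 0.860, 0.084, 0.094),
      rba_beta  = c(100, 0.020, 43.9, 0.017, 0.010),
      source    = "Fokialakis et al. ER competitive binding",
      stringsAsFactors = FALSE
    ),
    proxies = c(glycitein = "daidzein"),
    label = "Fokialakis ER binding set"
  )
}

#' Resolve a compound's affinities
#'
#' Looks a compound up in an affinity table, following a proxy entry if
#' there is no direct record. Matching is case-insensitive and
#' whitespace/hyphen-insensitive.
#'
#' @param table an [affinity_table()].
#' @param compound_name compound to resolve.
#' @return one-row data.frame with columns `name` (the query, canonical),
#'   `rba_alpha`, `rba_beta`, `source`, and `resolved_via` ("" for a
#'   direct hit, else the proxied compound's name).
#' @export
#' @examples
#' resolve_affinity(default_affinity_table(), "glycitein")
resolve_affinity <- function(table, compound_name) {
  stopifnot(inherits(table, "affinity_table"))
  if (!is_scalar_string(compound_name)) {
    stop_terescore("`compound_name` must be a non-empty string",
                   "terescore_validation_error")
  }
  key <- canonical_name(compound_name)
  if (!nzchar(key)) {
    stop_terescore("`compound_name` must be a non-empty string",
                   "terescore_validation_error")
  }

  via <- ""
  idx <- match(key, table$records$name)
  if (is.na(idx) && key %in% names(table$proxies)) {
    via <- unname(table$proxies[[key]])
    idx <- match(via, table$records$name)
  }
  if (is.na(idx)) {
    known <- sort(unique(c(table$records$name, names(table$proxies))))
    stop_terescore(
      paste0("no affinity data for compound '", key, "' in table '",
             table$label, "'; known compounds: ",
             paste(known, collapse = ", ")),
      "terescore_unknown_compound_error",
      data = list(compound = key, known = known)
    )
  }
  rec <- table$records[idx, , drop = FALSE]
  data.frame(name = key,
             rba_alpha = rec$rba_alpha,
             rba_beta = rec$rba_beta,
             source = rec$source,
             resolved_via = via,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read an affinity table from file
#'
#' Accepts either a YAML document with fields `label`, `records` (list of
#' `{name, rba_alpha, rba_beta, source?}`) and optional `proxies` (map),
#' or a plain 3-column CSV `name,rba_alpha,rba_beta` (no proxies). The
#' format is chosen by extension: `.csv` for CSV, anything else is parsed
#' as YAML.
#'
#' @param path file path.
#' @return an [affinity_table()].
#' @export
read_affinity_table <- function(path) {
  if (!file.exists(path)) {
    stop_terescore(paste0("affinity file not found: ", path),
                   "terescore_io_error")
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
      error = function(e) stop_terescore(
        paste0("failed to parse affinity CSV ", path, ": ",
               conditionMessage(e)),
        "terescore_parse_error")
    )
    need <- c("name", "rba_alpha", "rba_beta")
    if (!all(need %in% names(df))) {
      stop_terescore(
        paste0("affinity CSV must have header columns ",
               paste(need, collapse = ", "), "; got: ",
               paste(names(df), collapse = ", ")),
        "terescore_parse_error")
    }
    return(affinity_table(df, label = basename(path)))
  }

  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_terescore(
      paste0("failed to parse affinity document ", path, ": ",
             conditionMessage(e)),
      "terescore_parse_error")
  )
  if (is.null(doc$records)) {
    stop_terescore("affinity document must contain a `records` list",
                   "terescore_parse_error")
  }
  recs <- lapply(seq_along(doc$records), function(i) {
    r <- doc$records[[i]]
    if (is.null(r$name) || is.null(r$rba_alpha) || is.null(r$rba_beta)) {
      stop_terescore(
        paste0("record ", i, " must declare name, rba_alpha and rba_beta"),
        "terescore_parse_error")
    }
    data.frame(name = as.character(r$name),
               rba_alpha = as.numeric(r$rba_alpha),
               rba_beta = as.numeric(r$rba_beta),
               source = if (is.null(r$source)) "" else as.character(r$source),
               stringsAsFactors = FALSE)
  })
  proxies <- character()
  if (!is.null(doc$proxies)) {
    proxies <- unlist(doc$proxies)
    if (!is.character(proxies)) proxies <- vapply(doc$proxies, as.character, "")
  }
  affinity_table(do.call(rbind, recs),
                 proxies = proxies,
                 label = if (is.null(doc$label)) basename(path)
                         else as.character(doc$label))
}

#' Write an affinity table to a YAML document
#'
#' The written document round-trips through [read_affinity_table()] to an
#' identical table.
#'
#' @param table an [affinity_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(table, path) {
  stopifnot(inherits(table, "affinity_table"))
  doc <- list(
    label = table$label,
    records = lapply(seq_len(nrow(table$records)), function(i) {
      r <- table$records[i, ]
      out <- list(name = r$name, rba_alpha = r$rba_alpha, rba_beta = r$rba_beta)
      if (nzchar(r$source)) out$source <- r$source
      out
    })
  )
  if (length(table$proxies)) doc$proxies <- as.list(table$proxies)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @export
print.affinity_table <- function(x, ...) {
  cat("<affinity_table> ", x$label, "\n", sep = "")
  cat("  ", nrow(x$records), " record(s), RBA as % of estradiol\n", sep = "")
  print(x$records, row.names = FALSE)
  if (length(x$proxies)) {
    cat("  proxies:",
        paste(names(x$proxies), "->", unname(x$proxies), collapse = "; "),
        "\n")
  }
  invisible(x)
}
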