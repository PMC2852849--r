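# Accepted formulation-file schema. `annotation` is optional free text
# (reported outcome etc.); anything else in the header is rejected.
.formulation_columns <- c("formulation_label", "compound", "intake_mg",
                          "is_aglycone_equivalent", "annotation")

parse_flag <- function(x, row) {
  x <- tolower(trimws(as.character(x)))
  if (is.na(x) || x == "") return(TRUE)
  if (x %in% c("true", "t", "1", "yes")) return(TRUE)
  if (x %in% c("false", "f", "0", "no")) return(FALSE)
  stop_terescore(
    paste0("row ", row, ": is_aglycone_equivalent must be true or false, got '",
           x, "'"),
    "terescore_schema_error")
}

parse_intake <- function(x, row) {
  x <- trimws(as.character(x))
  # period decimal separator only, for reproducibility across locales
  if (!grepl("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", x)) {
    stop_terescore(
      paste0("row ", row, ": intake_mg must be a non-negative decimal, got '",
             x, "'"),
      "terescore_schema_error")
  }
  as.numeric(x)
}

#' Read formulations from a file
#'
#' A formulation file is either a CSV with header columns
#' `formulation_label, compound, intake_mg` and optionally
#' `is_aglycone_equivalent` (true/false, default true) and `annotation`,
#' one component per row; or a YAML document with a `formulations` list
#' of `{label, annotation?, components: [{compound, intake_mg,
#' is_aglycone_equivalent?}]}`. CSV vs YAML is chosen by the `.csv`
#' extension. Components with duplicate compound names within one
#' formulation are merged by summing intakes; labels are preserved
#' verbatim and formulations come back in order of first appearance.
#'
#' @param path file path.
#' @return list of [formulation()] objects.
#' @export
read_formulations <- function(path) {
  if (!file.exists(path)) {
    stop_terescore(paste0("formulation file not found: ", path),
                   "terescore_io_error")
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(read_formulations_csv(path))
  }
  read_formulations_yaml(path)
}

read_formulations_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    strip.white = TRUE, check.names = FALSE),
    error = function(e) stop_terescore(
      paste0("failed to parse ", path, ": ", conditionMessage(e)),
      "terescore_parse_error"))
  if (nrow(df) == 0L) {
    stop_terescore(paste0("formulation file is empty: ", path),
                   "terescore_schema_error")
  }
  unknown <- setdiff(names(df), .formulation_columns)
  if (length(unknown)) {
    stop_terescore(
      paste0("unknown column(s) in ", path, ": ",
             paste(unknown, collapse = ", "), "; accepted: ",
             paste(.formulation_columns, collapse = ", ")),
      "terescore_schema_error")
  }
  need <- c("formulation_label", "compound", "intake_mg")
  if (!all(need %in% names(df))) {
    stop_terescore(
      paste0("missing required column(s) in ", path, ": ",
             paste(setdiff(need, names(df)), collapse = ", ")),
      "terescore_schema_error")
  }

  df$.row <- seq_len(nrow(df)) + 1L  # +1: header line
  df$.intake <- mapply(parse_intake, df$intake_mg, df$.row)
  df$.flag <- if ("is_aglycone_equivalent" %in% names(df)) {
    mapply(parse_flag, df$is_aglycone_equivalent, df$.row)
  } else TRUE
  df$.annotation <- if ("annotation" %in% names(df)) df$annotation else ""

  labels <- unique(df$formulation_label)
  lapply(labels, function(lab) {
    d <- df[df$formulation_label == lab, , drop = FALSE]
    ann <- d$.annotation[nzchar(d$.annotation)]
    formulation(
      label = lab,
      components = data.frame(compound = d$compound,
                              intake_mg = d$.intake,
                              is_aglycone_equivalent = d$.flag,
                              stringsAsFactors = FALSE),
      annotation = if (length(ann)) ann[1] else ""
    )
  })
}

read_formulations_yaml <- function(path) {
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_terescore(
      paste0("failed to parse ", path, ": ", conditionMessage(e)),
      "terescore_parse_error"))
  if (is.null(doc$formulations)) {
    # a single bare formulation document is also accepted
    doc <- list(formulations = list(doc))
  }
  if (length(doc$formulations) == 0L) {
    stop_terescore(paste0("formulation file is empty: ", path),
                   "terescore_schema_error")
  }
  lapply(doc$formulations, function(f) {
    if (is.null(f$label) || is.null(f$components)) {
      stop_terescore("each formulation needs `label` and `components`",
                     "terescore_schema_error")
    }
    comp <- do.call(rbind, lapply(f$components, function(cm) {
      if (is.null(cm$compound) || is.null(cm$intake_mg)) {
        stop_terescore("each component needs `compound` and `intake_mg`",
                       "terescore_schema_error")
      }
      data.frame(
        compound = as.character(cm$compound),
        intake_mg = parse_intake(cm$intake_mg, "?"),
        is_aglycone_equivalent = if (is.null(cm$is_aglycone_equivalent)) TRUE
                                 else isTRUE(cm$is_aglycone_equivalent),
        stringsAsFactors = FALSE)
    }))
    formulation(as.character(f$label), comp,
                annotation = if (is.null(f$annotation)) "" else
                  as.character(f$annotation))
  })
}

#' Write formulations to a CSV file
#'
#' Inverse of [read_formulations()]: the written file reads back to
#' formulations with identical labels, merged components and
#' annotations.
#'
#' @param formulations list of [formulation()] objects (or one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_formulations <- function(formulations, path) {
  if (inherits(formulations, "formulation")) formulations <- list(formulations)
  stopifnot(length(formulations) > 0,
            all(vapply(formulations, inherits, TRUE, "formulation")))
  rows <- do.call(rbind, lapply(formulations, function(f) {
    data.frame(
      formulation_label = f$label,
      compound = f$components$compound,
      intake_mg = format(f$components$intake_mg, trim = TRUE, digits = 15),
      is_aglycone_equivalent = tolower(as.character(
        f$components$is_aglycone_equivalent)),
      annotation = f$annotation,
      stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Generate the packaged worked-example fixtures
#'
#' Writes, into `output_dir`, formulation files for every worked example
#' the scoring method was demonstrated on -- the two 100 mg
#' daidzein/genistein assays, three clinical-trial mixtures (a soy OTC
#' extract, a red-clover extract, a soy-germ preparation), the nine
#' clinical-trial mixtures of the comparison table, and the 10 mg / 15
#' mg pure-genistein dose cases -- plus the default affinity table as a
#' YAML document. The red-clover trial's published score table is
#' internally inconsistent (its printed receptor totals are not the sums
#' of its printed per-compound cells), so that fixture is suitable for
#' invariant checks but not for digit-level reproduction.
#'
#' Regeneration is deterministic: running twice produces byte-identical
#' files.
#'
#' @param output_dir writable directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(output_dir) {
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  p <- function(...) file.path(output_dir, ...)
  comp <- function(compound, intake_mg) {
    data.frame(compound = compound, intake_mg = intake_mg,
               stringsAsFactors = FALSE)
  }

  files <- c(
    two_assays = p("two_assays.csv"),
    soy_otc = p("soy_otc.csv"),
    red_clover = p("red_clover.csv"),
    soy_germ = p("soy_germ.csv"),
    clinical_trials = p("clinical_trials.csv"),
    genistein_doses = p("genistein_doses.csv"),
    affinity = p("affinity_default.yaml")
  )

  write_formulations(list(
    formulation("assay-1", comp(c("daidzein", "genistein"), c(25, 75))),
    formulation("assay-2", comp(c("daidzein", "genistein"), c(75, 25)))
  ), files[["two_assays"]])

  # soy OTC, 60 mg/day total; glycitein scores via the daidzein proxy
  write_formulations(
    formulation("soy-otc",
                comp(c("daidzein", "glycitein", "genistein"),
                     c(12, 1.26, 45)),
                annotation = "reduction of ~50% of hot flushes"),
    files[["soy_otc"]])

  write_formulations(
    formulation("red-clover",
                comp(c("daidzein", "formononetin", "genistein", "biochanin a"),
                     c(0.1, 16, 1, 26)),
                annotation = "bone density endpoint, non-significant"),
    files[["red_clover"]])

  # soy germ: pooled daidzein + glycitein intake encoded as daidzein
  # (lossless for scoring: the proxy gives both the same affinities)
  write_formulations(
    formulation("soy-germ",
                comp(c("daidzein", "genistein"), c(1206, 185)),
                annotation = "attenuation of bone loss"),
    files[["soy_germ"]])

  write_formulations(list(
    formulation("[25]", comp("genistein", 50),
                annotation = "down 24% hot flushes"),
    formulation("[26]", comp("genistein", 54),
                annotation = "up 3% BMD; up bone formation; down bone resorption"),
    formulation("[27,28]", comp("genistein", 54),
                annotation = "up nitrites/nitrates; up brachial FMD; down endothelin-1"),
    formulation("[29]", comp(c("genistein", "daidzein", "glycitein"),
                             c(48, 24, 8)),
                annotation = "up FMD"),
    formulation("[30]", comp(c("genistein", "daidzein", "glycitein"),
                             c(40.9, 40.9, 8.2)),
                annotation = "no change in FMD; up endothelium-independent vasodilation"),
    formulation("[31]a", comp("biochanin a", 80),
                annotation = "no change in FMD"),
    formulation("[31]b", comp("formononetin", 80),
                annotation = "no change in FMD"),
    formulation("[32]", comp(c("genistein", "daidzein", "biochanin a",
                               "formononetin"),
                             c(4, 3.5, 24.5, 8)),
                annotation = "up arterial compliance"),
    formulation("[33]", comp(c("genistein", "daidzein", "glycitein"),
                             c(76, 37, 5)),
                annotation = "up arterial compliance; no change in FMD")
  ), files[["clinical_trials"]])

  write_formulations(list(
    formulation("genistein-10mg", comp("genistein", 10),
                annotation = "no relevant effect reported"),
    formulation("genistein-15mg", comp("genistein", 15),
                annotation = "lowest dose with significant hot-flush reduction")
  ), files[["genistein_doses"]])

  write_affinity_table(default_affinity_table(), files[["affinity"]])

  invisible(files)
}
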