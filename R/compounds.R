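# Standard atomic masses (g/mol, 4-decimal IUPAC conventional values).
# Covers the elements of organic small molecules; extend here if a
# registry ever needs more.
.atomic_masses <- c(
  H = 1.0080, C = 12.0110, N = 14.0070, O = 15.9990, P = 30.9738,
  S = 32.0600, F = 18.9984, Cl = 35.4500, Br = 79.9040, I = 126.9045,
  Na = 22.9898, K = 39.0983, Ca = 40.0780, Mg = 24.3050, Fe = 55.8450,
  Zn = 65.3800, Se = 78.9710, B = 10.8100, Si = 28.0850
)

#' Molar mass from a molecular formula
#'
#' Parses a Hill-notation molecular formula (element symbols followed by
#' optional positive integer counts, e.g. `"C15H10O5"`) and returns the
#' molar mass as the count-weighted sum of standard atomic masses.
#'
#' @param molecular_formula a Hill-notation formula string.
#' @return molar mass in g/mol.
#' @export
#' @examples
#' molar_mass("C15H10O5") # genistein, ~270.24
#' molar_mass("H2O")
molar_mass <- function(molecular_formula) {
  if (!is_scalar_string(molecular_formula)) {
    stop_terescore("`molecular_formula` must be a non-empty string",
                   "terescore_formula_error")
  }
  f <- gsub("[[:space:]]", "", molecular_formula)
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
  parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
  if (length(parts) == 0L || sum(nchar(parts)) != nchar(f)) {
    stop_terescore(
      paste0("malformed molecular formula: '", molecular_formula, "'"),
      "terescore_formula_error")
  }
  total <- 0
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    cnt_str <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
    if (!sym %in% names(.atomic_masses)) {
      stop_terescore(
        paste0("unknown element symbol '", sym, "' in formula '",
               molecular_formula, "'"),
        "terescore_formula_error")
    }
    if (is.na(cnt) || cnt < 1L) {
      stop_terescore(
        paste0("element count must be a positive integer in '",
               molecular_formula, "' (", p, ")"),
        "terescore_formula_error")
    }
    total <- total + .atomic_masses[[sym]] * cnt
  }
  total
}

#' The packaged compound registry
#'
#' Registers the isoflavone aglycones and their naturally occurring
#' conjugates, keyed by canonical name, each with a molecular formula and
#' (for conjugates) the parent aglycone. Isoflavones occur in plants
#' mostly as 7-O-glucosides (genistin, daidzin, glycitin) and their
#' 6''-O-malonyl and 6''-O-acetyl esters; dosing and scoring run in
#' aglycone-equivalent milligrams, so conjugate intakes are rescaled by
#' the aglycone/conjugate molar-mass ratio. Masses are always computed
#' from the formulas, never tabulated, so the formula is the single
#' source of truth.
#'
#' @return data.frame with columns `name`, `molecular_formula`,
#'   `parent_aglycone` ("" for aglycones).
#' @export
#' @examples
#' default_compound_registry()
default_compound_registry <- function() {
  reg <- data.frame(
    name = c(
      "estradiol",
      "genistein", "daidzein", "glycitein", "formononetin", "biochanin a",
      "genistin", "daidzin", "glycitin",
      "malonylgenistin", "malonyldaidzin", "malonylglycitin",
      "acetylgenistin", "acetyldaidzin", "acetylglycitin"
    ),
    molecular_formula = c(
      "C18H24O2",
      "C15H10O5", "C15H10O4", "C16H12O5", "C16H12O4", "C16H12O5",
      "C21H20O10", "C21H20O9", "C22H22O10",
      # glucoside + C3H2O3 (malonyl) / + C2H2O (acetyl)
      "C24H22O13", "C24H22O12", "C25H24O13",
      "C23H22O11", "C23H22O10", "C24H24O11"
    ),
    parent_aglycone = c(
      "",
      "", "", "", "", "",
      "genistein", "daidzein", "glycitein",
      "genistein", "daidzein", "glycitein",
      "genistein", "daidzein", "glycitein"
    ),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

validate_registry <- function(registry) {
  if (!is.data.frame(registry) ||
      !all(c("name", "molecular_formula", "parent_aglycone") %in% names(registry))) {
    stop_terescore(
      "registry must have columns name, molecular_formula, parent_aglycone",
      "terescore_validation_error")
  }
  registry$name <- canonical_name(as.character(registry$name))
  registry$parent_aglycone <- canonical_name(as.character(registry$parent_aglycone))
  registry$parent_aglycone[is.na(registry$parent_aglycone)] <- ""
  if (anyDuplicated(registry$name)) {
    stop_terescore("duplicate compound names in registry",
                   "terescore_validation_error")
  }
  # every formula must parse; every parent must be a registered aglycone
  invisible(vapply(registry$molecular_formula, molar_mass, numeric(1)))
  aglycones <- registry$name[!nzchar(registry$parent_aglycone)]
  bad <- setdiff(setdiff(unique(registry$parent_aglycone), ""), aglycones)
  if (length(bad)) {
    stop_terescore(
      paste0("parent aglycone(s) not registered as aglycones: ",
             paste(bad, collapse = ", ")),
      "terescore_validation_error")
  }
  registry
}

#' Read / write a compound registry
#'
#' A registry file is a YAML list of `{name, molecular_formula,
#' parent_aglycone?}` entries under a top-level `compounds` key.
#'
#' @param path file path.
#' @return data.frame as in [default_compound_registry()].
#' @export
read_compound_registry <- function(path) {
  if (!file.exists(path)) {
    stop_terescore(paste0("registry file not found: ", path),
                   "terescore_io_error")
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_terescore(
      paste0("failed to parse registry ", path, ": ", conditionMessage(e)),
      "terescore_parse_error"))
  if (is.null(doc$compounds)) {
    stop_terescore("registry document must contain a `compounds` list",
                   "terescore_parse_error")
  }
  rows <- lapply(doc$compounds, function(r) {
    if (is.null(r$name) || is.null(r$molecular_formula)) {
      stop_terescore("each compound needs name and molecular_formula",
                     "terescore_parse_error")
    }
    data.frame(
      name = as.character(r$name),
      molecular_formula = as.character(r$molecular_formula),
      parent_aglycone = if (is.null(r$parent_aglycone)) ""
                        else as.character(r$parent_aglycone),
      stringsAsFactors = FALSE)
  })
  validate_registry(do.call(rbind, rows))
}

#' @rdname read_compound_registry
#' @param registry a compound registry data.frame.
#' @export
write_compound_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  doc <- list(compounds = lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    out <- list(name = r$name, molecular_formula = r$molecular_formula)
    if (nzchar(r$parent_aglycone)) out$parent_aglycone <- r$parent_aglycone
    out
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Convert an intake to aglycone equivalents
#'
#' For an aglycone the intake is returned unchanged; for a conjugate the
#' intake is rescaled by the molar-mass ratio aglycone/conjugate, i.e.
#' the milligrams of free aglycone liberated by complete hydrolysis of
#' the conjugate dose. The factor is strictly below 1 for any true
#' conjugate (the sugar/acyl moiety always adds mass).
#'
#' @param intake_mg daily intake in mg (>= 0).
#' @param compound_name a registered compound.
#' @param registry a compound registry; defaults to
#'   [default_compound_registry()].
#' @return list with `aglycone` (canonical name) and `intake_mg`
#'   (aglycone-equivalent mg/day).
#' @export
#' @examples
#' aglycone_equivalent(100, "genistin") # ~62.5 mg genistein
aglycone_equivalent <- function(intake_mg, compound_name,
                                registry = default_compound_registry()) {
  if (!is_scalar_number(intake_mg) || intake_mg < 0) {
    stop_terescore("`intake_mg` must be a single non-negative number",
                   "terescore_validation_error")
  }
  registry <- validate_registry(registry)
  key <- canonical_name(compound_name)
  idx <- match(key, registry$name)
  if (is.na(idx)) {
    stop_terescore(
      paste0("compound '", key, "' is not in the registry; known: ",
             paste(sort(registry$name), collapse = ", ")),
      "terescore_unknown_compound_error",
      data = list(compound = key))
  }
  parent <- registry$parent_aglycone[idx]
  if (!nzchar(parent)) {
    return(list(aglycone = key, intake_mg = intake_mg))
  }
  pidx <- match(parent, registry$name)
  factor <- molar_mass(registry$molecular_formula[pidx]) /
    molar_mass(registry$molecular_formula[idx])
  list(aglycone = parent, intake_mg = intake_mg * factor)
}
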