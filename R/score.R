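#' Construct a formulation
#'
#' A formulation is a labeled set of components, each a compound with a
#' daily intake in milligrams. Intakes are normally already expressed as
#' aglycone equivalents (the convention in clinical-trial reports); a
#' component may instead carry `is_aglycone_equivalent = FALSE`, in which
#' case scoring first converts it via [aglycone_equivalent()].
#'
#' Duplicate compounds (after name canonicalization) are merged by
#' summing their intakes.
#'
#' @param label free-text label for the formulation.
#' @param components data.frame with columns `compound`, `intake_mg` and
#'   optionally `is_aglycone_equivalent` (default `TRUE`).
#' @param annotation optional free text carried through to reports, e.g.
#'   a reported clinical outcome.
#' @return an object of class `formulation`.
#' @export
#' @examples
#' formulation("assay-1", data.frame(
#'   compound = c("daidzein", "genistein"),
#'   intake_mg = c(25, 75)
#' ))
formulation <- function(label, components, annotation = "") {
  if (!is_scalar_string(label)) {
    stop_terescore("`label` must be a non-empty string",
                   "terescore_validation_error")
  }
  if (!is.data.frame(components) ||
      !all(c("compound", "intake_mg") %in% names(components)) ||
      nrow(components) == 0L) {
    stop_terescore(
      "`components` must be a non-empty data.frame with columns compound, intake_mg",
      "terescore_validation_error")
  }
  if (is.null(annotation) || is.na(annotation)) annotation <- ""

  comp <- data.frame(
    compound = canonical_name(as.character(components$compound)),
    intake_mg = as.numeric(components$intake_mg),
    is_aglycone_equivalent = if ("is_aglycone_equivalent" %in% names(components))
      as.logical(components$is_aglycone_equivalent) else TRUE,
    stringsAsFactors = FALSE
  )
  comp$is_aglycone_equivalent[is.na(comp$is_aglycone_equivalent)] <- TRUE
  if (any(!is.finite(comp$intake_mg)) || any(comp$intake_mg < 0)) {
    stop_terescore("intake_mg must be finite and >= 0 for every component",
                   "terescore_validation_error")
  }

  # merge duplicates: intakes sum; the conversion flag must agree
  if (anyDuplicated(comp$compound)) {
    split_rows <- split(comp, comp$compound)
    comp <- do.call(rbind, lapply(split_rows, function(d) {
      if (length(unique(d$is_aglycone_equivalent)) > 1L) {
        stop_terescore(
          paste0("component '", d$compound[1],
                 "' appears with conflicting is_aglycone_equivalent flags"),
          "terescore_validation_error")
      }
      data.frame(compound = d$compound[1],
                 intake_mg = sum(d$intake_mg),
                 is_aglycone_equivalent = d$is_aglycone_equivalent[1],
                 stringsAsFactors = FALSE)
    }))
    comp <- comp[order(match(comp$compound, unique(comp$compound))), ]
  }
  rownames(comp) <- NULL

  if (all(comp$intake_mg == 0)) {
    stop_terescore(
      paste0("formulation '", label,
             "' must have at least one component with intake_mg > 0"),
      "terescore_validation_error")
  }

  structure(
    list(label = label, components = comp, annotation = as.character(annotation)),
    class = "formulation"
  )
}

#' @export
print.formulation <- function(x, ...) {
  cat("<formulation> ", x$label, "\n", sep = "")
  if (nzchar(x$annotation)) cat("  ", x$annotation, "\n", sep = "")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Receptor-bound contribution of one compound
#'
#' The elementary scoring step: daily intake (mg) weighted by the
#' compound's relative binding affinity at one receptor, `intake_mg *
#' rba / 100`. The result is a theoretical, unitless quantity on the
#' scale where 1 mg of estradiol contributes 1 per receptor.
#'
#' @param intake_mg daily intake in mg (>= 0).
#' @param rba relative binding affinity, percent of estradiol (>= 0).
#' @return the contribution (vectorized over both arguments).
#' @export
#' @examples
#' receptor_contribution(75, 43.9)
receptor_contribution <- function(intake_mg, rba) {
  if (!is.numeric(intake_mg) || !is.numeric(rba) ||
      any(intake_mg < 0, na.rm = TRUE) || any(rba < 0, na.rm = TRUE)) {
    stop_terescore("intake_mg and rba must be numeric and >= 0",
                   "terescore_validation_error")
  }
  intake_mg * rba / 100
}

#' Render a TERE denominator as a fraction string
#'
#' @param tere_denominator positive number (may be `Inf`).
#' @return the string `"1/x"` with `x` to 2 decimals.
#' @export
#' @examples
#' tere_fraction(2.978)
tere_fraction <- function(tere_denominator) {
  ifelse(is.infinite(tere_denominator), "1/Inf",
         paste0("1/", formatC(tere_denominator, format = "f", digits = 2)))
}

#' Score a formulation
#'
#' Computes the full score breakdown for a formulation against an
#' affinity table. Components not flagged as aglycone equivalents are
#' first converted; per-compound alpha and beta contributions are
#' `intake_mg * rba / 100`; the Theoretical Efficacy (TE) is the sum of
#' both channels (`mode = "combined"`) or of the beta channel only
#' (`mode = "beta_only"`); the TERE denominator is `100 / TE`, computed
#' from the unrounded TE, so that a formulation's potency reads as the
#' fraction 1/x of estradiol's reference activity (estradiol's reference
#' is the constant 100 and is definitional -- the affinity table need not
#' contain estradiol). The risk/benefit partition splits the combined
#' total into its alpha share (tumour-proliferation concern) and beta
#' share (bone/cardiovascular/CNS benefit); the alpha load is the
#' absolute alpha total, reported unclassified.
#'
#' @param x a [formulation()].
#' @param table an [affinity_table()]; default the packaged table.
#' @param mode `"combined"` (default) or `"beta_only"`.
#' @param registry compound registry used for aglycone conversion.
#' @param threshold_denominator relevance cutoff passed to
#'   [classify_relevance()].
#' @return an object of class `tere_score`: a list with `label`,
#'   `annotation`, `mode`, `per_compound` (data.frame: compound,
#'   intake_mg, rba_alpha, rba_beta, alpha_contribution,
#'   beta_contribution), `alpha_total`, `beta_total`, `te`,
#'   `tere_denominator`, `tere` (= te/100), `tere_fraction`,
#'   `risk_percent`, `benefit_percent`, `alpha_load`, `relevance`.
#' @export
#' @examples
#' f <- formulation("assay-1", data.frame(
#'   compound = c("daidzein", "genistein"), intake_mg = c(25, 75)))
#' score_formulation(f)
score_formulation <- function(x,
                              table = default_affinity_table(),
                              mode = c("combined", "beta_only"),
                              registry = default_compound_registry(),
                              threshold_denominator = 15.2) {
  stopifnot(inherits(x, "formulation"), inherits(table, "affinity_table"))
  mode <- match.arg(mode)

  comp <- x$components
  # aglycone conversion where flagged, then re-merge (two conjugates can
  # share one parent aglycone)
  conv <- lapply(seq_len(nrow(comp)), function(i) {
    if (comp$is_aglycone_equivalent[i]) {
      list(aglycone = comp$compound[i], intake_mg = comp$intake_mg[i])
    } else {
      aglycone_equivalent(comp$intake_mg[i], comp$compound[i], registry)
    }
  })
  conv <- data.frame(
    compound = vapply(conv, `[[`, "", "aglycone"),
    intake_mg = vapply(conv, `[[`, 0, "intake_mg"),
    stringsAsFactors = FALSE
  )
  conv <- stats::aggregate(intake_mg ~ compound, data = conv, FUN = sum)

  aff <- do.call(rbind, lapply(conv$compound, resolve_affinity, table = table))
  per <- data.frame(
    compound = conv$compound,
    intake_mg = conv$intake_mg,
    rba_alpha = aff$rba_alpha,
    rba_beta = aff$rba_beta,
    alpha_contribution = receptor_contribution(conv$intake_mg, aff$rba_alpha),
    beta_contribution = receptor_contribution(conv$intake_mg, aff$rba_beta),
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  alpha_total <- sum(per$alpha_contribution)
  beta_total <- sum(per$beta_contribution)
  te <- if (mode == "beta_only") beta_total else alpha_total + beta_total
  denom <- if (te > 0) 100 / te else Inf
  both <- alpha_total + beta_total
  risk <- if (both > 0) 100 * alpha_total / both else NA_real_
  benefit <- if (both > 0) 100 * beta_total / both else NA_real_

  structure(
    list(
      label = x$label,
      annotation = x$annotation,
      mode = mode,
      per_compound = per,
      alpha_total = alpha_total,
      beta_total = beta_total,
      te = te,
      tere = te / 100,
      tere_denominator = denom,
      tere_fraction = tere_fraction(denom),
      risk_percent = risk,
      benefit_percent = benefit,
      alpha_load = alpha_total,
      relevance = classify_relevance(denom, threshold_denominator)
    ),
    class = "tere_score"
  )
}

#' Classify the clinical relevance of a TERE score
#'
#' Formulations whose theoretical potency falls too far below
#' estradiol's are unlikely to show measurable clinical bioactivity. The
#' default cutoff is a TERE of 1/15.2, the score of the lowest genistein
#' dose (15 mg/day) empirically associated with a significant reduction
#' of hot flushes -- roughly the "1/15" rule of thumb. A score at or
#' above the cutoff (denominator at or below `threshold_denominator`) is
#' `POTENTIALLY_RELEVANT`; below it (larger denominator, including an
#' infinite one) is `LOW`.
#'
#' @param tere_denominator positive number, the `x` of the TERE fraction
#'   1/x; `Inf` allowed (zero-potency formulation).
#' @param threshold_denominator positive cutoff denominator.
#' @return `"LOW"` or `"POTENTIALLY_RELEVANT"` (vectorized).
#' @export
#' @examples
#' classify_relevance(22.8) # 10 mg genistein: LOW
#' classify_relevance(15.2) # 15 mg genistein: POTENTIALLY_RELEVANT
classify_relevance <- function(tere_denominator, threshold_denominator = 15.2) {
  if (!is.numeric(tere_denominator) || any(tere_denominator <= 0, na.rm = TRUE)) {
    stop_terescore("`tere_denominator` must be positive",
                   "terescore_validation_error")
  }
  if (!is_scalar_number(threshold_denominator) || threshold_denominator <= 0) {
    stop_terescore("`threshold_denominator` must be a positive number",
                   "terescore_validation_error")
  }
  ifelse(tere_denominator > threshold_denominator,
         "LOW", "POTENTIALLY_RELEVANT")
}

#' Risk/benefit partition of a score
#'
#' Splits the combined receptor-bound total of a scored formulation into
#' its alpha-receptor share (risk percent) and beta-receptor share
#' (benefit percent); the two always sum to 100.
#'
#' @param breakdown a `tere_score` from [score_formulation()].
#' @return named numeric vector `c(risk_percent, benefit_percent)`.
#' @export
risk_benefit <- function(breakdown) {
  stopifnot(inherits(breakdown, "tere_score"))
  both <- breakdown$alpha_total + breakdown$beta_total
  if (both <= 0) {
    stop_terescore(
      "risk/benefit partition undefined: formulation has zero bound total",
      "terescore_degenerate_error")
  }
  c(risk_percent = 100 * breakdown$alpha_total / both,
    benefit_percent = 100 * breakdown$beta_total / both)
}

#' @export
print.tere_score <- function(x, ...) {
  cat("<tere_score> ", x$label,
      if (nzchar(x$annotation)) paste0("  [", x$annotation, "]"), "\n", sep = "")
  cat("  mode: ", x$mode, "\n", sep = "")
  per <- x$per_compound
  per$alpha_contribution <- signif(per$alpha_contribution, 6)
  per$beta_contribution <- signif(per$beta_contribution, 6)
  print(per, row.names = FALSE)
  cat(sprintf("  TE: %.4g   TERE: %s (denominator %.4g)\n",
              x$te, x$tere_fraction, x$tere_denominator))
  if (is.na(x$risk_percent)) {
    cat("  risk/benefit: undefined (zero bound total)\n")
  } else {
    cat(sprintf("  risk: %.1f%%   benefit: %.1f%%   alpha load: %.3g\n",
                x$risk_percent, x$benefit_percent, x$alpha_load))
  }
  cat("  relevance: ", x$relevance, "\n", sep = "")
  invisible(x)
}
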