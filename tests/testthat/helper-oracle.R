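# Independent naive recomputation of the score: a plain loop over
# components with its own proxy lookup, kept deliberately separate from
# the package's vectorized path so the two can cross-check each other.
oracle_score <- function(components, table = default_affinity_table(),
                         mode = "combined") {
  alpha <- 0
  beta <- 0
  for (i in seq_len(nrow(components))) {
    nm <- canonical_name(components$compound[i])
    if (!nm %in% table$records$name && nm %in% names(table$proxies)) {
      nm <- table$proxies[[nm]]
    }
    j <- which(table$records$name == nm)
    stopifnot(length(j) == 1L)
    alpha <- alpha + components$intake_mg[i] * table$records$rba_alpha[j] / 100
    beta <- beta + components$intake_mg[i] * table$records$rba_beta[j] / 100
  }
  te <- if (mode == "beta_only") beta else alpha + beta
  list(alpha_total = alpha, beta_total = beta, te = te,
       tere_denominator = if (te > 0) 100 / te else Inf)
}

# Random formulations over the default table's compounds, for
# property-style tests. Intakes span the 0.1-1500 mg/day range seen in
# supplement trials.
random_formulation <- function(label = "random") {
  pool <- c("daidzein", "genistein", "formononetin", "biochanin a",
            "glycitein")
  n <- sample(1:5, 1)
  formulation(label, data.frame(
    compound = sample(pool, n),
    intake_mg = round(stats::runif(n, 0.1, 1500), 3)
  ))
}

two_assay_formulations <- function() {
  list(
    formulation("assay-1", data.frame(
      compound = c("daidzein", "genistein"), intake_mg = c(25, 75))),
    formulation("assay-2", data.frame(
      compound = c("daidzein", "genistein"), intake_mg = c(75, 25)))
  )
}
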