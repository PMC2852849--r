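test_that("receptor contribution is intake times affinity over 100", {
  expect_equal(receptor_contribution(75, 43.9), 32.925)
  expect_equal(receptor_contribution(45, 0.860), 0.387)
  expect_equal(receptor_contribution(0, 43.9), 0)
  expect_equal(receptor_contribution(c(25, 75), c(0.031, 0.860)),
               c(0.00775, 0.645))
  expect_error(receptor_contribution(-1, 10),
               class = "terescore_validation_error")
})

test_that("formulations merge duplicates and validate intakes", {
  f <- formulation("x", data.frame(compound = c("genistein", "GENISTEIN"),
                                   intake_mg = c(40, 5)))
  expect_identical(nrow(f$components), 1L)
  expect_equal(f$components$intake_mg, 45)

  expect_error(formulation("x", data.frame(compound = "genistein",
                                           intake_mg = -3)),
               class = "terescore_validation_error")
  expect_error(formulation("x", data.frame(compound = "genistein",
                                           intake_mg = 0)),
               class = "terescore_validation_error")
  expect_error(formulation("x", data.frame(compound = character(),
                                           intake_mg = numeric())),
               class = "terescore_validation_error")
})

test_that("the worked two-assay scores reproduce", {
  fs <- two_assay_formulations()
  s1 <- score_formulation(fs[[1]])
  expect_equal(s1$alpha_total, 0.65275)
  expect_equal(s1$beta_total, 32.93)
  expect_equal(s1$te, 33.58275)
  expect_equal(s1$tere_denominator, 100 / 33.58275)
  expect_equal(s1$tere_fraction, "1/2.98")
  expect_equal(s1$risk_percent, 1.9, tolerance = 0.05 / 1.9)
  expect_equal(s1$benefit_percent, 98.1, tolerance = 0.05 / 98.1)

  s2 <- score_formulation(fs[[2]])
  expect_equal(s2$te, 11.22825)
  expect_equal(s2$tere_denominator, 100 / 11.22825)
  expect_equal(s2$risk_percent, 2.1, tolerance = 0.05 / 2.1)
})

test_that("beta-only mode counts only the beta channel", {
  g10 <- formulation("g10", data.frame(compound = "genistein", intake_mg = 10))
  s <- score_formulation(g10, mode = "beta_only")
  expect_equal(s$te, 4.39)
  expect_equal(s$tere_denominator, 100 / 4.39)
  # alpha-side fields still reflect the alpha channel
  expect_equal(s$alpha_load, 0.086)
})

test_that("the estradiol reference scores 1 per mg per channel", {
  e1 <- formulation("e2", data.frame(compound = "estradiol", intake_mg = 1))
  s <- score_formulation(e1)
  expect_equal(s$te, 2)
  expect_equal(s$tere_denominator, 50)

  # the reference is definitional: a table without estradiol still scores
  # against the constant 100
  tab <- affinity_table(
    data.frame(name = "genistein", rba_alpha = 0.860, rba_beta = 43.9))
  s2 <- score_formulation(
    formulation("g", data.frame(compound = "genistein", intake_mg = 100)),
    table = tab)
  expect_equal(s2$tere_denominator, 100 / 44.76)
})

test_that("conjugate components convert before scoring when flagged", {
  raw <- formulation("conjugated", data.frame(
    compound = c("genistin", "genistein"),
    intake_mg = c(100, 10),
    is_aglycone_equivalent = c(FALSE, TRUE)))
  s <- score_formulation(raw)
  # 100 mg genistin ~ 62.5 mg genistein; merged with the 10 mg aglycone
  expect_identical(s$per_compound$compound, "genistein")
  expect_equal(s$per_compound$intake_mg, 72.5, tolerance = 1e-4)

  # the flag defaults to "already aglycone equivalent", so an unconverted
  # glucoside has no affinity record of its own and scoring refuses it
  expect_error(
    score_formulation(
      formulation("g", data.frame(compound = "genistin", intake_mg = 100))),
    class = "terescore_unknown_compound_error")
})

test_that("zero-affinity formulations degrade to an infinite denominator", {
  tab <- affinity_table(
    data.frame(name = "inert", rba_alpha = 0, rba_beta = 0))
  s <- score_formulation(
    formulation("inert", data.frame(compound = "inert", intake_mg = 100)),
    table = tab)
  expect_identical(s$te, 0)
  expect_identical(s$tere_denominator, Inf)
  expect_identical(s$tere_fraction, "1/Inf")
  expect_identical(s$relevance, "LOW")
  expect_true(is.na(s$risk_percent))
  expect_error(risk_benefit(s), class = "terescore_degenerate_error")
})

test_that("relevance classification separates sub-threshold scores", {
  expect_identical(classify_relevance(22.8), "LOW")
  expect_identical(classify_relevance(15.2), "POTENTIALLY_RELEVANT")
  expect_identical(classify_relevance(Inf), "LOW")
  expect_identical(classify_relevance(2.98), "POTENTIALLY_RELEVANT")
  # cutoff is configurable
  expect_identical(classify_relevance(22.8, threshold_denominator = 30),
                   "POTENTIALLY_RELEVANT")
  expect_error(classify_relevance(0), class = "terescore_validation_error")
})

test_that("risk and benefit partition the combined total", {
  fs <- two_assay_formulations()
  rb1 <- risk_benefit(score_formulation(fs[[1]]))
  expect_equal(unname(rb1["risk_percent"]), 100 * 0.65275 / 33.58275)
  expect_equal(sum(rb1), 100)

  rb2 <- risk_benefit(score_formulation(fs[[2]]))
  expect_equal(unname(rb2["risk_percent"]), 100 * 0.23825 / 11.22825)

  # all-alpha edge case
  tab <- affinity_table(data.frame(name = "alphaonly", rba_alpha = 5,
                                   rba_beta = 0))
  rb3 <- risk_benefit(score_formulation(
    formulation("a", data.frame(compound = "alphaonly", intake_mg = 10)),
    table = tab))
  expect_equal(unname(rb3), c(100, 0))
})

test_that("scores obey dose linearity, order and merge invariance", {
  withr::local_seed(1407)
  for (rep in 1:25) {
    f <- random_formulation()
    s <- score_formulation(f)

    # dose linearity
    a <- stats::runif(1, 0.01, 20)
    scaled <- formulation(f$label, data.frame(
      compound = f$components$compound,
      intake_mg = a * f$components$intake_mg))
    ss <- score_formulation(scaled)
    expect_equal(ss$te, a * s$te, tolerance = 1e-12)
    expect_equal(ss$alpha_load, a * s$alpha_load, tolerance = 1e-12)
    expect_equal(ss$tere_denominator, s$tere_denominator / a,
                 tolerance = 1e-12)
    expect_equal(ss$risk_percent, s$risk_percent, tolerance = 1e-12)
    expect_equal(ss$benefit_percent, s$benefit_percent, tolerance = 1e-12)
    expect_equal(s$risk_percent + s$benefit_percent, 100, tolerance = 1e-9)

    # order invariance
    perm <- sample(nrow(f$components))
    shuffled <- formulation(f$label, f$components[perm, ])
    expect_equal(score_formulation(shuffled)$te, s$te, tolerance = 1e-12)

    # merge invariance: split the first component in two
    first <- f$components[1, ]
    split_comp <- rbind(
      data.frame(compound = first$compound, intake_mg = 0.3 * first$intake_mg),
      data.frame(compound = first$compound, intake_mg = 0.7 * first$intake_mg),
      f$components[-1, c("compound", "intake_mg")])
    expect_equal(score_formulation(formulation(f$label, split_comp))$te,
                 s$te, tolerance = 1e-12)

    # beta-only never exceeds combined
    sb <- score_formulation(f, mode = "beta_only")
    expect_lte(sb$te, s$te)

    # naive-loop oracle agrees to 1e-12 relative
    o <- oracle_score(f$components)
    expect_equal(s$te, o$te, tolerance = 1e-12)
    expect_equal(s$alpha_total, o$alpha_total, tolerance = 1e-12)
    expect_equal(s$beta_total, o$beta_total, tolerance = 1e-12)
  }
})

test_that("beta-only equals combined exactly when alpha affinities vanish", {
  tab <- affinity_table(data.frame(name = c("b1", "b2"),
                                   rba_alpha = c(0, 0),
                                   rba_beta = c(10, 20)))
  f <- formulation("b", data.frame(compound = c("b1", "b2"),
                                   intake_mg = c(5, 5)))
  expect_identical(score_formulation(f, table = tab, mode = "beta_only")$te,
                   score_formulation(f, table = tab, mode = "combined")$te)
})
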