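test_that("isotope compositions enforce their invariants", {
  expect_error(isotope_composition(0.1, 0.8, 0.2, 0.1), "sum to 1")
  expect_error(isotope_composition(0.5, 0, 0.3, 0.2), "a56")
  expect_error(isotope_composition(-0.1, 1.0, 0.05, 0.05), "\\[0, 1\\]")
  nat <- natural_iron_composition()
  expect_s3_class(nat, "isotope_composition")
  expect_equal(sum(unclass(nat)), 1, tolerance = 1e-12)
  # fraction-weighted molar mass of natural iron is the standard 55.845
  expect_equal(iso_molar_mass(nat), 55.845, tolerance = 1e-3)
})

test_that("blood volume models give expected volumes and reject bad input", {
  expect_equal(estimate_blood_volume(list(weight = 50.5)), 3.2825)
  expect_equal(estimate_blood_volume(list(weight = 41.7)), 2.7105)
  expect_error(estimate_blood_volume(list(weight = 0)), "positive")
  expect_error(estimate_blood_volume(list(weight = 50), "no_such_model"),
               "unknown blood-volume model")
  bv <- estimate_blood_volume(list(weight = 50.5, height = 1.6),
                              "nadler_female")
  expect_gt(bv, 2); expect_lt(bv, 5)
  expect_error(estimate_blood_volume(list(weight = 50.5), "nadler_female"),
               "height")
})

test_that("circulating iron is the Hb-bound pool and is bilinear", {
  expect_equal(circulating_iron(3.2825, 13.7), 1560.5, tolerance = 1e-4)
  expect_error(circulating_iron(1, 0), "hb")
  expect_error(circulating_iron(0, 13), "blood_volume")
  # linear in both arguments
  expect_equal(circulating_iron(3.2825, 13.7 / 2),
               circulating_iron(3.2825, 13.7) / 2)
  expect_equal(circulating_iron(3.2825 * 2, 13.7),
               circulating_iron(3.2825, 13.7) * 2)
})

test_that("tracer inversion returns zero for unenriched blood", {
  nat <- natural_iron_composition()
  r <- iso_ratios(nat)
  res <- tracer_amounts(NULL, ratio_pair(r[["r57"]], r[["r58"]]), nat,
                        label_composition("Fe57"), label_composition("Fe58"),
                        circulating_fe = 1500)
  expect_equal(res$m57, 0, tolerance = 1e-12)
  expect_equal(res$m58, 0, tolerance = 1e-12)
  expect_identical(res$baseline_used, "natural")
})

test_that("tracer inversion recovers forward-modelled spikes exactly", {
  nat <- natural_iron_composition()
  l57 <- isotope_composition(0.001, 0.020, 0.960, 0.019)
  l58 <- isotope_composition(0.001, 0.002, 0.004, 0.993)
  n_nat <- 26.86; n57 <- 0.020; n58 <- 0.015 # mmol
  rr <- oracle_mix_ratios(n_nat, n57, n58, nat, l57, l58)
  res <- tracer_amounts(NULL, ratio_pair(rr[["r57"]], rr[["r58"]]), nat,
                        l57, l58, circulating_fe = n_nat * iso_molar_mass(nat))
  expect_equal(res$n57, n57, tolerance = 1e-9)
  expect_equal(res$n58, n58, tolerance = 1e-9)
  expect_equal(res$m57, n57 * iso_molar_mass(l57), tolerance = 1e-9)

  # linearity: doubling both spikes doubles the recovered amounts
  rr2 <- oracle_mix_ratios(n_nat, 2 * n57, 2 * n58, nat, l57, l58)
  res2 <- tracer_amounts(NULL, ratio_pair(rr2[["r57"]], rr2[["r58"]]), nat,
                         l57, l58, n_nat * iso_molar_mass(nat))
  expect_equal(res2$n57, 2 * res$n57, tolerance = 1e-9)
  expect_equal(res2$n58, 2 * res$n58, tolerance = 1e-9)
})

test_that("forward-inverse round trip holds across random valid designs", {
  set.seed(421)
  nat <- natural_iron_composition()
  for (i in 1:200) {
    l57 <- random_label("a57"); l58 <- random_label("a58")
    n_nat <- runif(1, 15, 40)
    n57 <- runif(1, 1e-5, 0.05); n58 <- runif(1, 1e-5, 0.05)
    rr <- oracle_mix_ratios(n_nat, n57, n58, nat, l57, l58)
    res <- tracer_amounts(NULL, ratio_pair(rr[["r57"]], rr[["r58"]]), nat,
                          l57, l58, n_nat * iso_molar_mass(nat))
    expect_equal(res$n57, n57, tolerance = 1e-9)
    expect_equal(res$n58, n58, tolerance = 1e-9)
  }
})

test_that("measured baseline ratios calibrate the native pool", {
  nat <- natural_iron_composition()
  l57 <- label_composition("Fe57"); l58 <- label_composition("Fe58")
  r <- iso_ratios(nat)
  base <- ratio_pair(r[["r57"]] * 1.002, r[["r58"]] * 0.998)
  n_nat <- 28; n57 <- 0.002; n58 <- 0.0015
  rr <- oracle_mix_ratios(n_nat, n57, n58, nat, l57, l58,
                          base_r57 = base[["r57"]], base_r58 = base[["r58"]])
  res <- tracer_amounts(base, ratio_pair(rr[["r57"]], rr[["r58"]]), nat,
                        l57, l58, n_nat * iso_molar_mass(nat))
  expect_equal(res$n57, n57, tolerance = 1e-9)
  expect_equal(res$n58, n58, tolerance = 1e-9)
  expect_identical(res$baseline_used, "measured")
})

test_that("swapping the label arguments permutes the recovered amounts", {
  nat <- natural_iron_composition()
  l57 <- label_composition("Fe57"); l58 <- label_composition("Fe58")
  n_nat <- 25; n57 <- 0.01; n58 <- 0.02
  rr <- oracle_mix_ratios(n_nat, n57, n58, nat, l57, l58)
  cfe <- n_nat * iso_molar_mass(nat)
  a <- tracer_amounts(NULL, ratio_pair(rr[["r57"]], rr[["r58"]]), nat,
                      l57, l58, cfe)
  b <- tracer_amounts(NULL, ratio_pair(rr[["r57"]], rr[["r58"]]), nat,
                      l58, l57, cfe)
  expect_equal(a$n57, b$n58, tolerance = 1e-9)
  expect_equal(a$n58, b$n57, tolerance = 1e-9)
})

test_that("degenerate and inconsistent designs are flagged, not silent", {
  nat <- natural_iron_composition()
  l57 <- label_composition("Fe57")
  r <- iso_ratios(nat)
  # identical labels: the 2x2 balance is singular
  expect_error(
    tracer_amounts(NULL, ratio_pair(r[["r57"]] * 1.01, r[["r58"]] * 1.01),
                   nat, l57, l57, 1500),
    "degenerate")
  # enrichment far below baseline implies a large negative label amount
  l58 <- label_composition("Fe58")
  expect_error(
    tracer_amounts(NULL, ratio_pair(r[["r57"]] * 0.8, r[["r58"]] * 0.8),
                   nat, l57, l58, 1500),
    "inconsistent")
  # tiny negatives (measurement noise around zero) are clipped with a note
  rr <- oracle_mix_ratios(26, 1e-12, 1e-3, nat, l57, l58)
  expect_message(
    res <- tracer_amounts(NULL,
                          ratio_pair(rr[["r57"]] * (1 - 1e-10), rr[["r58"]]),
                          nat, l57, l58, 26 * iso_molar_mass(nat)),
    "clipped")
  expect_identical(res$m57, 0)
  expect_true(res$clipped)
})

test_that("fractional absorption follows the incorporation model", {
  expect_equal(fractional_absorption(0.0888, 3, 0.8), 0.037)
  expect_equal(fractional_absorption(0, 3), 0)
  expect_equal(fractional_absorption(2.4, 3, 0.8), 1)
  expect_error(fractional_absorption(1, 0), "dose")
  expect_error(fractional_absorption(1, 3, 0), "incorporation")
  # strictly increasing in tracer, decreasing in dose
  tr <- seq(0.01, 1, length.out = 20)
  expect_true(all(diff(fractional_absorption(tr, 3)) > 0))
  ds <- seq(1, 10, length.out = 20)
  expect_true(all(diff(fractional_absorption(0.5, ds)) < 0))
})

test_that("atom percent excess recovers constructed enrichment", {
  nat <- natural_iron_composition()
  r <- iso_ratios(nat)
  base <- ratio_pair(r[["r57"]], r[["r58"]])
  expect_equal(atom_percent_excess(base, base), c(ape57 = 0, ape58 = 0))

  # add pure 57Fe until a57 rises by 0.0027 absolute -> APE57 = 0.27
  x <- 0.0027 / (1 - nat[["a57"]])
  mixed <- unclass(nat) * (1 - x)
  mixed["a57"] <- mixed["a57"] + x
  enr <- ratio_pair(mixed[["a57"]] / mixed[["a56"]],
                    mixed[["a58"]] / mixed[["a56"]])
  # adding only 57Fe dilutes the 58 fraction below baseline, which the op
  # reports as a warning and clips to zero
  expect_warning(ape <- atom_percent_excess(enr, base), "below baseline")
  expect_equal(ape[["ape57"]], 0.27, tolerance = 1e-9)
  expect_equal(ape[["ape58"]], 0, tolerance = 1e-9)

  # monotone: larger r57 at fixed r58 never decreases ape57
  r57s <- r[["r57"]] * seq(1, 1.5, length.out = 10)
  apes <- sapply(r57s, function(v) suppressWarnings(
    atom_percent_excess(ratio_pair(v, r[["r58"]]), base)[["ape57"]]))
  expect_true(all(diff(apes) >= 0))
})

test_that("geometric mean summary matches closed form", {
  s <- geometric_mean_summary(c(0.02, 0.074))
  expect_equal(s$geo_mean, sqrt(0.02 * 0.074), tolerance = 1e-12)
  expect_equal(s$geo_mean, 0.0385, tolerance = 1e-3)
  expect_equal(geometric_mean_summary(0.4), list(geo_mean = 0.4, min = 0.4,
                                                 max = 0.4))
  expect_equal(geometric_mean_summary(rep(0.05, 7))$geo_mean, 0.05)
  expect_error(geometric_mean_summary(c(0.1, 0)), "positive")
})

test_that("paired log t-test reports fold change as geometric mean ratio", {
  x <- c(0.02, 0.03, 0.05, 0.04)
  same <- paired_log_ttest(x, x)
  expect_equal(same$fold_change, 1)
  expect_equal(same$mean_log_diff, 0)
  expect_true(same$undefined) # zero-variance differences flagged, not zeroed

  doubled <- paired_log_ttest(2 * x, x)
  expect_equal(doubled$fold_change, 2, tolerance = 1e-12)
  expect_true(doubled$undefined)

  set.seed(77)
  ok <- replicate(200, {
    h <- exp(rnorm(10, log(0.013), 0.05))
    l <- h * 2.85 * exp(rnorm(10, 0, 0.05))
    paired_log_ttest(l, h)$fold_change
  })
  expect_lt(abs(mean(ok) - 2.85) / 2.85, 0.05)

  # consistency with the independent geometric-mean route
  set.seed(8)
  l <- exp(rnorm(10, log(0.04), 0.3)); h <- exp(rnorm(10, log(0.012), 0.4))
  tt <- paired_log_ttest(l, h)
  expect_equal(tt$fold_change,
               geometric_mean_summary(l)$geo_mean /
                 geometric_mean_summary(h)$geo_mean,
               tolerance = 1e-12)
  expect_false(tt$undefined)
  expect_equal(tt$df, 9)
})
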