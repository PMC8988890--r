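test_that("descriptive summary matches hand calculation", {
  d <- descriptive_summary(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(d$cv, 50)
  flat <- descriptive_summary(rep(4, 5))
  expect_equal(flat$sd, 0); expect_equal(flat$cv, 0)
  expect_error(descriptive_summary(3), ">= 2")
  # CV is unit-free
  x <- c(700, 650, 820, 760)
  expect_equal(descriptive_summary(x)$cv, descriptive_summary(x / 100)$cv)
})

test_that("one-way ANOVA reproduces a hand-worked decomposition", {
  # groups (1,2,3), (4,5,6), (7,8,9): SSg = 54 (df 2), SSe = 6 (df 6)
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("A", "B", "C"), each = 3)
  a <- oneway_anova(v, g)
  expect_equal(a$ms_geno, 27)
  expect_equal(a$ms_error, 1)
  expect_equal(a$f, 27)
  expect_equal(a$df_geno, 2); expect_equal(a$df_error, 6)
  expect_equal(a$r, 3); expect_true(a$balanced)
  expect_equal(a$p, pf(27, 2, 6, lower.tail = FALSE))
})

test_that("degenerate ANOVA layouts are flagged", {
  all_same <- oneway_anova(rep(5, 6), rep(c("A", "B", "C"), each = 2))
  expect_identical(all_same$flag, "undefined")
  expect_true(is.na(all_same$f))

  sep <- oneway_anova(c(0, 0, 1, 1), c("A", "A", "B", "B"))
  expect_identical(sep$flag, "zero_error_ms")
  expect_equal(sep$ms_error, 0)
  expect_identical(sep$f, Inf)

  expect_warning(
    unb <- oneway_anova(c(1, 2, 3, 4, 5, 6, 7), rep(c("A", "B"), c(3, 4))),
    "unbalanced")
  expect_equal(unb$r, 3.5)
})

test_that("variance components follow expected mean squares", {
  vc <- variance_components(100, 10, 3)
  expect_equal(vc$gv, 30); expect_equal(vc$ev, 10); expect_equal(vc$pv, 40)
  expect_false(vc$floored)
  floored <- variance_components(5, 10, 3)
  expect_equal(floored$gv, 0); expect_true(floored$floored)
  expect_equal(variance_components(10, 10, 4)$gv, 0)
  expect_error(variance_components(10, 5, 0), "r must be")
  # published component table is internally consistent (pv = gv + ev) to
  # its printed one-decimal precision
  tab <- millet_table("genetic_parameters")
  expect_true(all(abs(tab$pv - (tab$gv + tab$ev)) <= 0.1 + 1e-9))
})

test_that("coefficients of variation and heritability match printed values", {
  cvs <- genetic_cvs(8493.1, 8738.6, 245.5, 738)
  expect_equal(round(cvs[["gcv"]], 1), 12.5)
  expect_equal(round(cvs[["pcv"]], 1), 12.7)
  expect_equal(round(cvs[["ecv"]], 1), 2.1)
  expect_equal(genetic_cvs(0, 10, 10, 100)[["gcv"]], 0)
  expect_error(genetic_cvs(1, 2, 1, 0), "grand_mean")

  expect_equal(round(heritability_broad(8493.1, 8738.6), 1), 97.2)
  expect_equal(heritability_broad(10, 10), 100)
  expect_equal(genetic_advance_over_mean(0, 100, 50), 0)
  gam <- genetic_advance_over_mean(0.971906, 8738.6, 738)
  expect_equal(round(gam, 1), 25.4)
})

test_that("gcv never exceeds pcv and h2 stays within [0, 100]", {
  set.seed(11)
  for (i in 1:50) {
    msg <- runif(1, 0, 500); mse <- runif(1, 0, 500); r <- sample(2:5, 1)
    vc <- variance_components(msg, mse, r)
    cvs <- genetic_cvs(vc$gv, vc$pv, vc$ev, runif(1, 10, 1000))
    expect_lte(cvs[["gcv"]], cvs[["pcv"]] + 1e-12)
    h2 <- heritability_broad(vc$gv, vc$pv)
    expect_gte(h2, 0); expect_lte(h2, 100)
  }
})

test_that("Shannon-Weaver index hits its closed-form anchors", {
  expect_equal(shannon_weaver_index(c(1, 1, 1, 1, 2, 2, 2, 2), 2), log(2))
  expect_equal(shannon_weaver_index(rep(3, 10), 5), 0)
  # uniform over k classes attains the maximum log(k)
  k <- 6
  vals <- rep(seq_len(k), each = 10) + runif(60, -0.2, 0.2)
  expect_equal(shannon_weaver_index(vals, k), log(k), tolerance = 1e-9)
  # never exceeds log(n_classes)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(50, 0, runif(1, 0.5, 5))
    expect_lte(shannon_weaver_index(x, 10), log(10) + 1e-12)
  }
  expect_error(shannon_weaver_index(1:5, 10), "n_classes")
})

test_that("panel evaluation is exact for identity and scaled panels", {
  set.seed(31)
  core <- data.frame(
    trait = rep(c("t1", "t2", "t3"), each = 60),
    value = c(rnorm(60, 100, 10), rnorm(60, 5, 1), rnorm(60, 700, 90)))
  same <- panel_evaluation(core, core)
  expect_equal(unname(same$summary["md_pct"]), 0)
  expect_equal(unname(same$summary["cr_pct"]), 100)
  expect_equal(unname(same$summary["vr_pct"]), 100)

  # halving every panel range about the trait mean halves CR
  halved <- core
  for (tr in unique(core$trait)) {
    i <- core$trait == tr
    halved$value[i] <- mean(core$value[i]) +
      (core$value[i] - mean(core$value[i])) / 2
  }
  hv <- panel_evaluation(core, halved)
  expect_equal(unname(hv$summary["cr_pct"]), 50)

  flat <- rbind(core, data.frame(trait = "t4", value = rep(1, 60)))
  expect_warning(pe <- panel_evaluation(flat, flat), "zero range")
  expect_false("t4" %in% pe$per_trait$trait)
})

test_that("coincidence rate from printed trait ranges matches a hand mean", {
  tab <- millet_table("trait_ranges")
  cr <- coincidence_rate(tab$max_core - tab$min_core,
                         tab$max_panel - tab$min_panel)
  # 14 identical ranges plus five slightly narrowed ones -> just under 100
  expect_equal(cr, 99.7, tolerance = 0.002)
  expect_error(coincidence_rate(c(1, 0), c(1, 1)), "zero-range")
  expect_equal(coincidence_rate(c(2, 4), c(1, 2)), 50)
})

test_that("Newman-Keuls comparisons separate distant means only", {
  set.seed(12)
  none <- posthoc_mean_comparison(rnorm(30, 10, 1), rep(c("A", "B", "C"), 10))
  expect_false(any(none$significant))

  v <- c(rnorm(10, 0, 1), rnorm(10, 10, 1))
  two <- posthoc_mean_comparison(v, rep(c("A", "B"), each = 10))
  expect_true(all(two$significant))

  # 3-group fixture against a hand studentized-range computation:
  # exact means 0 / 0.5 / 10, every group with within-group SS 2.5, n = 5,
  # so MSe = 7.5/12 = 0.625 and se = sqrt(0.625/5) = 0.3536
  base <- c(-1, -0.5, 0, 0.5, 1)
  y <- c(base, base + 0.5, base + 10)
  g <- rep(c("lo", "mid", "hi"), each = 5)
  res <- posthoc_mean_comparison(y, g)
  se_hand <- sqrt(0.625 / 5)
  row <- res[res$g1 == "lo" & res$g2 == "hi", ]
  expect_equal(row$q, 10 / se_hand, tolerance = 1e-9)
  expect_equal(row$q_crit, qtukey(0.95, 3, 12), tolerance = 1e-9)
  expect_true(row$significant)
  # lo vs mid spans 2 means: q = 0.5/0.3536 = 1.41 < qtukey(0.95, 2, 12)
  expect_false(res$significant[res$g1 == "lo" & res$g2 == "mid"])
  expect_error(posthoc_mean_comparison(1:5, rep("A", 5)), "2 groups")
})
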