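#' Blood-volume models
#'
#' Registered models for estimating total blood volume from anthropometry.
#' `"per_kg"` is the default 65 mL per kg body weight convention for adult
#' women; `"nadler_female"` is the height + weight regression
#' 0.3561 h^3 + 0.03308 w + 0.1833 (h in m, w in kg).
#'
#' @return Named list of model functions taking a subject record.
#' @export
blood_volume_models <- function() {
  list(
    per_kg = function(subject) 0.065 * subject$weight,
    nadler_female = function(subject) {
      if (is.null(subject$height) || !is.finite(subject$height) ||
          subject$height <= 0) {
        stop("nadler_female model requires a positive height (m)",
             call. = FALSE)
      }
      0.3561 * subject$height^3 + 0.03308 * subject$weight + 0.1833
    }
  )
}

#' Estimate total blood volume
#'
#' @param subject A list or one-row data.frame with at least `weight` (kg);
#'   `height` (m) for the regression model.
#' @param model Name of a registered model; see [blood_volume_models()].
#' @return Blood volume in litres.
#' @examples
#' estimate_blood_volume(list(weight = 50.5)) # 3.2825 L
#' @export
estimate_blood_volume <- function(subject, model = "per_kg") {
  models <- blood_volume_models()
  if (!model %in% names(models)) {
    stop("unknown blood-volume model '", model, "'; registered models: ",
         paste(names(models), collapse = ", "), call. = FALSE)
  }
  w <- subject$weight
  if (is.null(w) || !is.finite(w) || w <= 0) {
    stop("subject weight must be a positive number (kg)", call. = FALSE)
  }
  bv <- models[[model]](subject)
  stopifnot(is.finite(bv), bv > 0)
  bv
}

#' Circulating iron mass
#'
#' Total iron bound in circulating haemoglobin: blood volume times Hb
#' concentration times the iron content of haemoglobin.
#'
#' @param blood_volume Litres.
#' @param hb Haemoglobin concentration, g/dL.
#' @param hb_iron mg Fe per g Hb (default 3.47).
#' @return Circulating iron in mg.
#' @examples
#' circulating_iron(3.2825, 13.7) # ~1560.5 mg
#' @export
circulating_iron <- function(blood_volume, hb, hb_iron = 3.47) {
  if (!is.finite(blood_volume) || blood_volume <= 0) {
    stop("blood_volume must be > 0", call. = FALSE)
  }
  if (!is.finite(hb) || hb <= 0) stop("hb must be > 0 (g/dL)", call. = FALSE)
  if (hb_iron <= 0) stop("hb_iron must be > 0", call. = FALSE)
  blood_volume * (hb * 10) * hb_iron
}

#' Forward isotope mixing model
#'
#' Predicts the measured 57Fe/56Fe and 58Fe/56Fe atom ratios of blood iron
#' that is a mixture of the subject's native (natural-composition) iron pool
#' and two enriched labels. The native pool contributes at the subject's
#' baseline ratios when these are supplied (instrument/baseline calibration),
#' otherwise at the natural-abundance ratios.
#'
#' @param n_nat Moles (mmol) of native iron in circulation.
#' @param n57,n58 Moles (mmol) of the 57-enriched and 58-enriched label.
#' @param lab57,lab58 Label `isotope_composition`s.
#' @param natural Natural `isotope_composition`.
#' @param baseline Optional `ratio_pair` of measured baseline ratios.
#' @return A `ratio_pair` of mixture ratios.
#' @export
forward_isotope_ratios <- function(n_nat, n57, n58,
                                   lab57 = label_composition("Fe57"),
                                   lab58 = label_composition("Fe58"),
                                   natural = natural_iron_composition(),
                                   baseline = NULL) {
  stopifnot(n_nat > 0, n57 >= 0, n58 >= 0)
  base <- if (is.null(baseline)) {
    r <- iso_ratios(natural)
    c(r57 = r[["r57"]], r58 = r[["r58"]])
  } else {
    c(r57 = baseline[["r57"]], r58 = baseline[["r58"]])
  }
  n56_nat <- n_nat * natural[["a56"]]
  num57 <- n56_nat * base[["r57"]] + n57 * lab57[["a57"]] + n58 * lab58[["a57"]]
  num58 <- n56_nat * base[["r58"]] + n57 * lab57[["a58"]] + n58 * lab58[["a58"]]
  den   <- n56_nat + n57 * lab57[["a56"]] + n58 * lab58[["a56"]]
  ratio_pair(num57 / den, num58 / den)
}

#' Circulating tracer masses from the isotope-ratio shift
#'
#' Inverts the two-label mixture balance by isotope dilution: with a known
#' native iron pool (from circulating iron) and measured day-20 ratios, the
#' moles of each enriched label are the solution of a 2x2 linear system in
#' which every label contributes to 56Fe, 57Fe and 58Fe according to its full
#' (non-monoisotopic) composition. The subject's measured baseline ratios
#' replace the natural-abundance ratios for the native pool when available.
#'
#' Small negative solutions (within `-1e-6` relative to the native mole pool,
#' i.e. measurement noise around zero enrichment) are clipped to zero with a
#' message; larger negatives indicate inconsistent measurements and raise an
#' error.
#'
#' @param baseline `ratio_pair` measured before dosing, or `NULL` to fall
#'   back on natural-abundance ratios (flagged in the result).
#' @param enriched `ratio_pair` measured after the incorporation period.
#' @param natural Natural `isotope_composition`.
#' @param lab57,lab58 Label `isotope_composition`s.
#' @param circulating_fe Circulating iron, mg.
#' @param refine If `TRUE`, apply one fixed-point refinement subtracting the
#'   solved tracer mass from the native pool and re-solving. The tracer is
#'   well under 1% of circulating iron in meal studies, so this second-order
#'   correction is off by default.
#' @return List with `m57`, `m58` (mg of each label in circulation), `n57`,
#'   `n58` (mmol), `clipped` (logical), `baseline_used` ("measured" or
#'   "natural").
#' @export
tracer_amounts <- function(baseline, enriched, natural, lab57, lab58,
                           circulating_fe, refine = FALSE) {
  stopifnot(inherits(enriched, "ratio_pair"),
            inherits(natural, "isotope_composition"),
            inherits(lab57, "isotope_composition"),
            inherits(lab58, "isotope_composition"))
  if (!is.finite(circulating_fe) || circulating_fe <= 0) {
    stop("circulating_fe must be > 0 (mg)", call. = FALSE)
  }
  baseline_used <- "measured"
  if (is.null(baseline)) {
    r <- iso_ratios(natural)
    baseline <- ratio_pair(r[["r57"]], r[["r58"]])
    baseline_used <- "natural"
  }
  stopifnot(inherits(baseline, "ratio_pair"))

  solve_once <- function(n_nat) {
    n56 <- n_nat * natural[["a56"]]
    A <- matrix(c(
      lab57[["a57"]] - enriched[["r57"]] * lab57[["a56"]],
      lab58[["a57"]] - enriched[["r57"]] * lab58[["a56"]],
      lab57[["a58"]] - enriched[["r58"]] * lab57[["a56"]],
      lab58[["a58"]] - enriched[["r58"]] * lab58[["a56"]]
    ), nrow = 2, byrow = TRUE)
    b <- n56 * c(enriched[["r57"]] - baseline[["r57"]],
                 enriched[["r58"]] - baseline[["r58"]])
    if (!all(is.finite(A)) || abs(det(A)) < 1e-14 || kappa(A) > 1e12) {
      stop("degenerate design: label compositions are isotopically ",
           "indistinct, the mixture balance is singular", call. = FALSE)
    }
    solve(A, b)
  }

  n_nat <- circulating_fe / iso_molar_mass(natural) # mmol (mg / (g/mol))
  n <- solve_once(n_nat)
  if (isTRUE(refine)) {
    m_lab <- max(n[1], 0) * iso_molar_mass(lab57) +
      max(n[2], 0) * iso_molar_mass(lab58)
    n <- solve_once((circulating_fe - m_lab) / iso_molar_mass(natural))
  }

  clipped <- FALSE
  tol <- 1e-6 * n_nat
  for (i in 1:2) {
    if (n[i] < 0) {
      if (n[i] >= -tol) {
        n[i] <- 0
        clipped <- TRUE
        message("tracer_amounts: small negative solved amount clipped to 0")
      } else {
        stop("inconsistent measurement: solved tracer amount is negative ",
             "beyond tolerance (", format(n[i], digits = 6), " mmol)",
             call. = FALSE)
      }
    }
  }

  list(m57 = n[1] * iso_molar_mass(lab57),
       m58 = n[2] * iso_molar_mass(lab58),
       n57 = n[1], n58 = n[2],
       clipped = clipped, baseline_used = baseline_used)
}

#' Fractional iron absorption
#'
#' Fraction of the ingested label dose absorbed, assuming a fixed fraction of
#' absorbed iron is incorporated into erythrocytes by the time of the
#' follow-up blood draw.
#'
#' @param circulating_tracer mg of label measured in circulation.
#' @param dose mg of label ingested (per-meal mass times number of meals).
#' @param incorporation Erythrocyte incorporation fraction, default 0.80.
#' @return Fractional absorption (unitless fraction).
#' @examples
#' fractional_absorption(0.0888, 3) # 0.037
#' @export
fractional_absorption <- function(circulating_tracer, dose,
                                  incorporation = 0.80) {
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("dose must be > 0 (mg)", call. = FALSE)
  }
  if (incorporation <= 0 || incorporation > 1) {
    stop("incorporation must lie in (0, 1]", call. = FALSE)
  }
  if (any(circulating_tracer < 0)) {
    stop("circulating_tracer must be >= 0", call. = FALSE)
  }
  circulating_tracer / (incorporation * dose)
}

#' Atom percent excess of the tracer isotopes
#'
#' Converts measured ratio pairs back to atom fractions (assuming the 54/56
#' ratio stays at its natural value, which holds when only 57- and
#' 58-enriched labels are added) and reports the absolute excess of the 57Fe
#' and 58Fe atom fractions over baseline, in percent. Enrichment slightly
#' below baseline (within numerical tolerance of zero) is clipped to 0 with a
#' warning.
#'
#' @param enriched,baseline `ratio_pair`s.
#' @param natural Natural `isotope_composition` (supplies the 54/56 ratio).
#' @return Named vector `c(ape57, ape58)` in percent.
#' @export
atom_percent_excess <- function(enriched, baseline,
                                natural = natural_iron_composition()) {
  stopifnot(inherits(enriched, "ratio_pair"), inherits(baseline, "ratio_pair"))
  r54 <- natural[["a54"]] / natural[["a56"]]
  frac <- function(rp) {
    den <- r54 + 1 + rp[["r57"]] + rp[["r58"]]
    c(a57 = rp[["r57"]] / den, a58 = rp[["r58"]] / den)
  }
  ape <- 100 * (frac(enriched) - frac(baseline))
  if (any(ape < 0)) {
    if (any(ape < -1e-9)) {
      warning("enriched atom fraction below baseline; clipping excess to 0")
    }
    ape <- pmax(ape, 0)
  }
  c(ape57 = ape[["a57"]], ape58 = ape[["a58"]])
}

#' Geometric mean and range
#'
#' @param values Positive values (e.g. fractional absorptions).
#' @return List with `geo_mean`, `min`, `max`.
#' @examples
#' geometric_mean_summary(c(0.02, 0.074))
#' @export
geometric_mean_summary <- function(values) {
  if (length(values) < 1 || any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  list(geo_mean = exp(mean(log(values))),
       min = min(values), max = max(values))
}

#' Paired t-test on log-transformed values
#'
#' Tests paired positive measurements (e.g. fractional absorption under two
#' meals in a crossover) on the log scale; the back-transformed mean paired
#' log-difference is the fold change, identical to the ratio of geometric
#' means.
#'
#' @param low,high Equal-length vectors of positive values; the test is of
#'   `log(low) - log(high)`.
#' @return List with `t`, `df`, `p`, `fold_change`, `mean_log_diff`,
#'   `undefined` (TRUE when the paired differences have zero variance, in
#'   which case `t` and `p` are `NA` rather than silently zero).
#' @export
paired_log_ttest <- function(low, high) {
  if (length(low) != length(high)) {
    stop("low and high must have equal length", call. = FALSE)
  }
  if (length(low) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(low <= 0) || any(high <= 0)) {
    stop("all values must be > 0 for log transformation", call. = FALSE)
  }
  d <- log(low) - log(high)
  out <- list(t = NA_real_, df = length(d) - 1, p = NA_real_,
              fold_change = exp(mean(d)), mean_log_diff = mean(d),
              undefined = FALSE)
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), 1e-8)) {
    # differences constant to machine precision: the statistic does not exist
    out$undefined <- TRUE
    return(out)
  }
  tt <- stats::t.test(d)
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}

#' Per-subject absorption results for a two-label crossover study
#'
#' Runs the full tracer calculus for every subject: blood volume from
#' anthropometry, circulating iron from haemoglobin, label amounts from the
#' baseline/day-20 isotope-ratio shift, and fractional absorption from the
#' administered dose.
#'
#' @param subjects data.frame with columns `id`, `weight` (kg), `hb` (g/dL),
#'   optionally `height` (m), `ferritin`, `crp`, `age`.
#' @param ratios data.frame with columns `subject_id`,
#'   `timepoint` (`"baseline"` or `"day20"`), `r57`, `r58`.
#' @param doses data.frame with columns `label` (`"Fe57"`/`"Fe58"`), `meal`,
#'   `label_fe_mg_per_meal`, `n_meals`.
#' @param constants An [iron_constants()] bundle.
#' @param lab57,lab58 Label compositions.
#' @return data.frame, one row per subject x label: blood volume, circulating
#'   iron and tracer, dose, incorporation and `fia`.
#' @export
compute_absorption <- function(subjects, ratios, doses,
                               constants = iron_constants(),
                               lab57 = label_composition("Fe57"),
                               lab58 = label_composition("Fe58")) {
  need <- c("subject_id", "timepoint", "r57", "r58")
  if (!all(need %in% names(ratios))) {
    stop("ratios must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  res <- vector("list", nrow(subjects) * nrow(doses))
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    s <- as.list(subjects[i, ])
    bv <- estimate_blood_volume(s, constants$blood_volume_model)
    cfe <- circulating_iron(bv, s$hb, constants$hb_iron)
    rs <- ratios[ratios$subject_id == s$id, ]
    rb <- rs[rs$timepoint == "baseline", ]
    rd <- rs[rs$timepoint == "day20", ]
    if (nrow(rd) != 1) {
      stop("subject ", s$id, ": expected exactly one day20 ratio row",
           call. = FALSE)
    }
    base <- if (nrow(rb) == 1) ratio_pair(rb$r57, rb$r58) else NULL
    amt <- tracer_amounts(base, ratio_pair(rd$r57, rd$r58),
                          constants$natural, lab57, lab58, cfe)
    for (j in seq_len(nrow(doses))) {
      d <- doses[j, ]
      dose <- d$label_fe_mg_per_meal * d$n_meals
      tracer <- if (d$label == "Fe57") amt$m57 else amt$m58
      k <- k + 1L
      res[[k]] <- data.frame(
        subject_id = s$id, label = d$label, meal = d$meal,
        blood_volume = bv, circulating_iron = cfe,
        circulating_tracer = tracer, dose = dose,
        incorporation = constants$incorporation,
        fia = fractional_absorption(tracer, dose, constants$incorporation),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res[seq_len(k)])
}
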