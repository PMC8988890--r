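# draw from Normal(mean, sd) truncated to [lo, hi] by rejection;
# bounds here are wide (>1.9 sd), so acceptance rates are high
.rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# lognormal with given arithmetic mean and sd, truncated
.rlnorm_ms <- function(n, mean, sd, lo = 0, hi = Inf) {
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sqrt(sdlog2))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Configuration for a replicated germplasm trial simulation
#'
#' Defaults reproduce the structure of a large grain phytic acid screening:
#' 623 accessions grown in 3 replicates, genotypic variance 8493.1,
#' environmental variance 245.5, grand mean 738 mg/100 g.
#'
#' @param n_accessions,n_reps Numbers of accessions and replicates.
#' @param gv_true,ev_true True genotypic and environmental variances
#'   (squared trait units).
#' @param grand_mean True grand mean (trait units).
#' @param trait,season Labels written into the simulated table.
#' @return List of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_accessions = 623, n_reps = 3,
                             gv_true = 8493.1, ev_true = 245.5,
                             grand_mean = 738,
                             trait = "gpa", season = "2015") {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (n_accessions < 2) stop("n_accessions must be >= 2", call. = FALSE)
  if (gv_true < 0 || ev_true < 0) stop("variances must be >= 0", call. = FALSE)
  structure(list(n_accessions = n_accessions, n_reps = n_reps,
                 gv_true = gv_true, ev_true = ev_true,
                 grand_mean = grand_mean, trait = trait, season = season),
            class = "trial_sim_config")
}

#' Simulate a replicated accession trial
#'
#' One-way random-effects model: accession effects ~ Normal(0, gv_true),
#' replicate errors ~ Normal(0, ev_true), value = grand_mean + effect +
#' error. Deterministic under a fixed seed.
#'
#' @param config A [trial_sim_config()].
#' @param seed Integer seed (set with `set.seed` when non-NULL).
#' @return data.frame with columns `accession`, `replicate`, `season`,
#'   `trait`, `value`.
#' @export
simulate_trial <- function(config = trial_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "trial_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  eff <- stats::rnorm(config$n_accessions, 0, sqrt(config$gv_true))
  acc <- sprintf("ACC%04d", seq_len(config$n_accessions))
  df <- expand.grid(replicate = seq_len(config$n_reps),
                    accession = acc, stringsAsFactors = FALSE)
  df$value <- config$grand_mean + eff[match(df$accession, acc)] +
    stats::rnorm(nrow(df), 0, sqrt(config$ev_true))
  df$season <- config$season
  df$trait <- config$trait
  df[, c("accession", "replicate", "season", "trait", "value")]
}

#' Configuration for a dual-tracer crossover absorption study simulation
#'
#' Defaults emulate a 10-subject crossover in young adult women with normal
#' iron status: weight N(50.5, 4.2^2) truncated to 41.7-58.4 kg, Hb
#' N(13.7, 0.8^2) truncated to 12.3-15.0 g/dL, serum ferritin lognormal with
#' arithmetic mean 25.2 and SD 10.1 ug/L truncated to the observed 11.7-40.7,
#' CRP lognormal (1.6, 2.1) truncated to 0.1-6.5 mg/L. Each subject eats
#' three low phytic acid meals labelled with a 57Fe tracer and three high
#' phytic acid meals labelled with 58Fe (1 mg label iron per meal).
#'
#' True fractional absorption per subject and meal is lognormal around a
#' ferritin-linked expectation: expected absorption in percent is
#' `geo_mean*100 + slope * (ferritin - 25.2)`, floored at `fia_floor`,
#' multiplied by `exp(Normal(0, fia_log_sd))`. Slopes default to the
#' regression estimates -0.108 (low phytate meal) and -0.060 (high) percent
#' per ug/L; set `ferritin_slope = c(low = 0, high = 0)` to switch the
#' linkage off.
#'
#' `enrichment_noise_rsd` is the relative SD of the measured baseline to
#' day-20 ratio *shift* (the enrichment signal an isotope-ratio MS run
#' quantifies), applied multiplicatively to the shift of each ratio. Zero
#' noise makes the pipeline inversion exact.
#'
#' @param n_subjects Number of subjects.
#' @param fia_geo_mean Named fractions `c(low = , high = )`: target geometric
#'   mean absorption of the two meals.
#' @param fia_log_sd Residual SD of log absorption.
#' @param ferritin_slope Named percent-per-(ug/L) slopes `c(low=, high=)`.
#' @param fia_floor Lower bound on expected absorption (fraction).
#' @param enrichment_noise_rsd Relative SD of the measured enrichment.
#' @param baseline_cal_rsd Relative SD of per-subject baseline ratio offsets
#'   (instrument calibration); the inversion uses the measured baseline, so
#'   this does not bias recovery.
#' @param label_fe_mg_per_meal,n_meals Label dose schedule per meal type.
#' @param lab57,lab58 Label compositions.
#' @param constants [iron_constants()] used by the forward model.
#' @return List of class `isotope_sim_config`.
#' @export
isotope_sim_config <- function(n_subjects = 10,
                               fia_geo_mean = c(low = 0.037, high = 0.013),
                               fia_log_sd = 0.30,
                               ferritin_slope = c(low = -0.108, high = -0.060),
                               fia_floor = 0.0005,
                               enrichment_noise_rsd = 0.005,
                               baseline_cal_rsd = 2e-4,
                               label_fe_mg_per_meal = 1, n_meals = 3,
                               lab57 = label_composition("Fe57"),
                               lab58 = label_composition("Fe58"),
                               constants = iron_constants()) {
  if (any(fia_geo_mean <= 0) || any(fia_geo_mean >= 1)) {
    stop("fia_geo_mean entries must be fractions in (0, 1)", call. = FALSE)
  }
  if (fia_log_sd < 0 || enrichment_noise_rsd < 0 || baseline_cal_rsd < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (n_subjects < 2) stop("need n_subjects >= 2", call. = FALSE)
  structure(list(n_subjects = n_subjects, fia_geo_mean = fia_geo_mean,
                 fia_log_sd = fia_log_sd, ferritin_slope = ferritin_slope,
                 fia_floor = fia_floor,
                 enrichment_noise_rsd = enrichment_noise_rsd,
                 baseline_cal_rsd = baseline_cal_rsd,
                 label_fe_mg_per_meal = label_fe_mg_per_meal,
                 n_meals = n_meals, lab57 = lab57, lab58 = lab58,
                 constants = constants),
            class = "isotope_sim_config")
}

#' Simulate a dual-tracer crossover absorption study
#'
#' Draws a subject table, assigns true per-subject absorption for both meal
#' types, and forward-models the day-20 isotope ratios from the circulating
#' iron pool and the two label doses, adding measurement noise to the
#' enrichment. Rejects configurations that would imply absorption > 1.
#'
#' @param config An [isotope_sim_config()].
#' @param seed Integer seed.
#' @return List with `subjects`, `ratios`, `doses` (the three input tables
#'   the absorption pipeline consumes) and `truth` (per subject x label true
#'   fractional absorption).
#' @export
simulate_isotope_study <- function(config = isotope_sim_config(),
                                   seed = NULL) {
  stopifnot(inherits(config, "isotope_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  cst <- config$constants

  subjects <- data.frame(
    id = sprintf("S%02d", seq_len(n)),
    age = round(stats::runif(n, 20, 30), 1),
    height = round(.rnorm_trunc(n, 1.6, 0.1, 1.4, 1.7), 2),
    weight = round(.rnorm_trunc(n, 50.5, 4.2, 41.7, 58.4), 1),
    hb = round(.rnorm_trunc(n, 13.7, 0.8, 12.3, 15.0), 1),
    ferritin = round(.rlnorm_ms(n, 25.2, 10.1, 11.7, 40.7), 1),
    crp = round(.rlnorm_ms(n, 1.6, 2.1, 0.1, 6.5), 1),
    stringsAsFactors = FALSE)

  true_fia <- function(level) {
    mu_pct <- config$fia_geo_mean[[level]] * 100 +
      config$ferritin_slope[[level]] * (subjects$ferritin - 25.2)
    fia <- pmax(mu_pct / 100, config$fia_floor) *
      exp(stats::rnorm(n, 0, config$fia_log_sd))
    if (any(fia >= 1)) {
      stop("configuration produced fractional absorption >= 1", call. = FALSE)
    }
    fia
  }
  fia_low <- true_fia("low")   # 57Fe-labelled meal
  fia_high <- true_fia("high") # 58Fe-labelled meal

  dose <- config$label_fe_mg_per_meal * config$n_meals
  nat_ratios <- iso_ratios(cst$natural)

  ratio_rows <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    s <- as.list(subjects[i, ])
    bv <- estimate_blood_volume(s, cst$blood_volume_model)
    cfe <- circulating_iron(bv, s$hb, cst$hb_iron)
    n_nat <- cfe / iso_molar_mass(cst$natural)
    # per-subject measured baseline (instrument calibration offset)
    base <- ratio_pair(
      nat_ratios[["r57"]] * (1 + stats::rnorm(1, 0, config$baseline_cal_rsd)),
      nat_ratios[["r58"]] * (1 + stats::rnorm(1, 0, config$baseline_cal_rsd)))
    n57 <- fia_low[i] * cst$incorporation * dose / iso_molar_mass(config$lab57)
    n58 <- fia_high[i] * cst$incorporation * dose / iso_molar_mass(config$lab58)
    day20 <- forward_isotope_ratios(n_nat, n57, n58, config$lab57,
                                    config$lab58, cst$natural, base)
    # measurement noise on the enrichment signal of each ratio
    eps <- stats::rnorm(2, 0, config$enrichment_noise_rsd)
    meas <- ratio_pair(
      base[["r57"]] + (day20[["r57"]] - base[["r57"]]) * (1 + eps[1]),
      base[["r58"]] + (day20[["r58"]] - base[["r58"]]) * (1 + eps[2]))
    ratio_rows[[2 * i - 1]] <- data.frame(
      subject_id = s$id, timepoint = "baseline",
      r57 = base[["r57"]], r58 = base[["r58"]], stringsAsFactors = FALSE)
    ratio_rows[[2 * i]] <- data.frame(
      subject_id = s$id, timepoint = "day20",
      r57 = meas[["r57"]], r58 = meas[["r58"]], stringsAsFactors = FALSE)
  }

  doses <- data.frame(
    label = c("Fe57", "Fe58"),
    meal = c("low_phytate", "high_phytate"),
    label_fe_mg_per_meal = config$label_fe_mg_per_meal,
    n_meals = config$n_meals, stringsAsFactors = FALSE)

  truth <- data.frame(
    subject_id = rep(subjects$id, 2),
    label = rep(c("Fe57", "Fe58"), each = n),
    meal = rep(c("low_phytate", "high_phytate"), each = n),
    fia = c(fia_low, fia_high), stringsAsFactors = FALSE)

  list(subjects = subjects, ratios = do.call(rbind, ratio_rows),
       doses = doses, truth = truth)
}

#' Simulate paired two-laboratory measurements
#'
#' Method A values are drawn from the trait distribution (default: grain
#' phytic acid, mean 738 and SD 92 mg/100 g); method B adds a systematic
#' bias plus Normal random disagreement.
#'
#' @param n Number of paired samples (>= 3).
#' @param bias Systematic difference (B - A).
#' @param sd_diff SD of the random disagreement.
#' @param trait_mean,trait_sd Distribution of the underlying trait.
#' @param seed Integer seed.
#' @return data.frame with columns `id`, `x` (method A), `y` (method B).
#' @export
simulate_two_lab <- function(n = 19, bias = 68, sd_diff = 51,
                             trait_mean = 738, trait_sd = 92, seed = NULL) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n, trait_mean, trait_sd)
  y <- x + stats::rnorm(n, bias, sd_diff)
  data.frame(id = sprintf("ACC%03d", seq_len(n)), x = x, y = y,
             stringsAsFactors = FALSE)
}
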