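#' Descriptive summary of a trait
#'
#' @param values Numeric vector, n >= 2.
#' @return List with `mean`, `min`, `max`, `sd` (sample, n-1), `sem`
#'   (`sd/sqrt(n)`), `cv` (percent, `100*sd/mean`), `n`. CV is `NA` when the
#'   mean is 0.
#' @export
descriptive_summary <- function(values) {
  if (length(values) < 2 || any(!is.finite(values))) {
    stop("need >= 2 finite values", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, min = min(values), max = max(values), sd = s,
       sem = s / sqrt(length(values)),
       cv = if (m == 0) NA_real_ else 100 * s / m,
       n = length(values))
}

#' One-way ANOVA over accessions
#'
#' Standard one-way decomposition with accessions (genotypes) as groups,
#' computed via `stats::anova(stats::lm(...))`. Degenerate layouts are
#' flagged rather than reported as silent zeros: if the within-group mean
#' square is exactly zero the F statistic is `Inf` (or `NA` when the
#' between-group mean square is also zero). Unbalanced designs are accepted
#' with a warning; the effective replicate number is then the mean group
#' size.
#'
#' @param value Numeric observations.
#' @param accession Grouping factor (accession ids).
#' @return List with `ms_geno`, `ms_error`, `f`, `p`, `df_geno`, `df_error`,
#'   `r` (replicates per accession), `grand_mean`, `n_accessions`,
#'   `balanced`, `flag` (`"ok"`, `"zero_error_ms"` or `"undefined"`).
#' @export
oneway_anova <- function(value, accession) {
  accession <- factor(accession)
  if (nlevels(accession) < 2) stop("need >= 2 accessions", call. = FALSE)
  sizes <- table(accession)
  if (any(sizes < 2)) stop("need >= 2 replicates per accession", call. = FALSE)
  balanced <- length(unique(sizes)) == 1
  if (!balanced) {
    warning("unbalanced design: using mean replicate number per accession")
  }
  r <- mean(sizes)

  # exact within-group sum of squares (detects true zero-error layouts that
  # lm() would report as numerical fuzz)
  sse <- sum(tapply(value, accession, function(v) sum((v - mean(v))^2)))
  fit <- stats::lm(value ~ accession)
  aov_tab <- if (sse == 0) {
    # perfect fit: anova.lm warns about unreliable F; we flag it ourselves
    suppressWarnings(stats::anova(fit))
  } else {
    stats::anova(fit)
  }
  ms_geno <- aov_tab[1, "Mean Sq"]
  df_geno <- aov_tab[1, "Df"]
  df_error <- aov_tab[2, "Df"]
  ms_error <- sse / df_error

  if (ms_error == 0) {
    if (ms_geno <= .Machine$double.eps) {
      f <- NA_real_; p <- NA_real_; flag <- "undefined"
    } else {
      f <- Inf; p <- 0; flag <- "zero_error_ms"
    }
  } else {
    f <- ms_geno / ms_error
    p <- stats::pf(f, df_geno, df_error, lower.tail = FALSE)
    flag <- "ok"
  }
  list(ms_geno = ms_geno, ms_error = ms_error, f = f, p = p,
       df_geno = df_geno, df_error = df_error, r = r,
       grand_mean = mean(value), n_accessions = nlevels(accession),
       balanced = balanced, flag = flag)
}

#' Variance components from one-way mean squares
#'
#' Expected-mean-squares estimators: genotypic variance
#' `gv = (ms_geno - ms_error) / r` (floored at zero with a flag),
#' environmental variance `ev = ms_error`, phenotypic variance
#' `pv = gv + ev`.
#'
#' @param ms_geno,ms_error Mean squares from [oneway_anova()].
#' @param r Replicates per accession.
#' @return List with `gv`, `ev`, `pv`, `floored`.
#' @export
variance_components <- function(ms_geno, ms_error, r) {
  if (!is.finite(r) || r < 1) stop("r must be >= 1", call. = FALSE)
  gv <- (ms_geno - ms_error) / r
  floored <- gv < 0
  if (floored) gv <- 0
  ev <- ms_error
  list(gv = gv, ev = ev, pv = gv + ev, floored = floored)
}

#' Genotypic, phenotypic and environmental coefficients of variation
#'
#' `100 * sqrt(variance) / grand_mean` for each component, in percent.
#'
#' @param gv,pv,ev Variance components.
#' @param grand_mean Trait grand mean (> 0).
#' @return Named vector `c(gcv, pcv, ecv)`.
#' @export
genetic_cvs <- function(gv, pv, ev, grand_mean) {
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop("grand_mean must be > 0", call. = FALSE)
  }
  if (any(c(gv, pv, ev) < 0)) stop("variances must be >= 0", call. = FALSE)
  100 * sqrt(c(gcv = gv, pcv = pv, ecv = ev)) / grand_mean
}

#' Broad-sense heritability
#'
#' Genotypic share of phenotypic variance, in percent: `100 * gv / pv`.
#'
#' @param gv,pv Genotypic and phenotypic variance (`pv > 0`).
#' @return h2 in percent.
#' @export
heritability_broad <- function(gv, pv) {
  if (!is.finite(pv) || pv <= 0) stop("pv must be > 0", call. = FALSE)
  if (gv < 0 || gv > pv) stop("gv must lie in [0, pv]", call. = FALSE)
  min(100 * (gv / pv), 100)
}

#' Genetic advance over mean
#'
#' Expected selection response as a percent of the grand mean:
#' `100 * k * h2 * sqrt(pv) / grand_mean`, with selection intensity
#' `k = 2.06` (5% selection) by default.
#'
#' @param h2 Broad-sense heritability as a *fraction* in \[0, 1\].
#' @param pv Phenotypic variance.
#' @param grand_mean Trait grand mean (> 0).
#' @param k Selection intensity.
#' @return GAM in percent.
#' @export
genetic_advance_over_mean <- function(h2, pv, grand_mean, k = 2.06) {
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop("grand_mean must be > 0", call. = FALSE)
  }
  if (pv < 0) stop("pv must be >= 0", call. = FALSE)
  if (h2 < 0 || h2 > 1) stop("h2 must be a fraction in [0, 1]", call. = FALSE)
  100 * k * h2 * sqrt(pv) / grand_mean
}

#' Full genetic-parameter chain for one trait/season
#'
#' Convenience wrapper: one-way ANOVA over accessions, variance components,
#' coefficients of variation, broad-sense heritability and genetic advance.
#'
#' @param value,accession Observations and accession ids.
#' @param trait,season Labels carried into the output.
#' @param k Selection intensity for GAM.
#' @return One-row data.frame with the ANOVA and derived statistics.
#' @export
genetic_parameters <- function(value, accession, trait = NA_character_,
                               season = NA_character_, k = 2.06) {
  a <- oneway_anova(value, accession)
  vc <- variance_components(a$ms_geno, a$ms_error, a$r)
  cvs <- genetic_cvs(vc$gv, vc$pv, vc$ev, a$grand_mean)
  h2 <- heritability_broad(vc$gv, vc$pv)
  gam <- genetic_advance_over_mean(h2 / 100, vc$pv, a$grand_mean, k)
  data.frame(trait = trait, season = season,
             n_accessions = a$n_accessions, n_reps = a$r,
             grand_mean = a$grand_mean,
             ms_geno = a$ms_geno, ms_error = a$ms_error, f = a$f, p = a$p,
             gv = vc$gv, ev = vc$ev, pv = vc$pv,
             gcv = cvs[["gcv"]], pcv = cvs[["pcv"]], ecv = cvs[["ecv"]],
             h2 = h2, gam = gam, stringsAsFactors = FALSE)
}

#' Shannon-Weaver diversity index of a quantitative trait
#'
#' Bins the values into `n_classes` equal-width classes over the observed
#' range and computes `H' = -sum(p_i * log(p_i))` over non-empty classes.
#' A constant trait has zero diversity by definition.
#'
#' @param values Numeric vector, length >= `n_classes`.
#' @param n_classes Number of equal-width classes (default 10).
#' @param base Logarithm base (default natural log).
#' @return H' (never exceeds `log(n_classes, base)`).
#' @export
shannon_weaver_index <- function(values, n_classes = 10, base = exp(1)) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (length(values) < n_classes) {
    stop("need at least n_classes values", call. = FALSE)
  }
  rng <- range(values)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_classes + 1)
  counts <- table(cut(values, breaks, include.lowest = TRUE))
  p <- counts[counts > 0] / length(values)
  -sum(p * log(p, base = base))
}

#' Coincidence rate between two sets of trait ranges
#'
#' CR% = mean over traits of `100 * range_subset / range_parent`: how much of
#' the parent collection's trait range a subset retains. Ranges may be given
#' as widths or as (min, max) columns.
#'
#' @param range_parent,range_subset Numeric vectors of range widths, matched
#'   by trait.
#' @return CR in percent.
#' @export
coincidence_rate <- function(range_parent, range_subset) {
  if (length(range_parent) != length(range_subset)) {
    stop("range vectors must be matched by trait", call. = FALSE)
  }
  if (any(range_parent <= 0)) {
    stop("parent ranges must be > 0; drop zero-range traits first",
         call. = FALSE)
  }
  mean(100 * range_subset / range_parent)
}

#' Evaluate how well a selected panel represents its parent collection
#'
#' Per trait: means, ranges, CVs and a Welch two-sample test between the
#' parent (core) collection and the selected panel, plus Shannon-Weaver
#' diversity of both. Summary statistics follow the standard core-collection
#' evaluation triplet: MD% (percent of traits with a significant mean
#' difference at `alpha`), CR% (mean range retention) and VR% (mean CV
#' ratio). Traits with zero range in the core are excluded with a warning.
#'
#' @param core,panel data.frames with columns `trait` and `value`
#'   (accession-level trait values).
#' @param alpha Significance level for the mean-difference count.
#' @param n_classes Classes for the Shannon-Weaver index.
#' @return List with `per_trait` (data.frame) and `summary` (named vector
#'   `md_pct`, `cr_pct`, `vr_pct`, `h_core`, `h_panel`).
#' @export
panel_evaluation <- function(core, panel, alpha = 0.05, n_classes = 10) {
  traits <- intersect(unique(core$trait), unique(panel$trait))
  if (length(traits) == 0) stop("no shared traits", call. = FALSE)
  rows <- lapply(traits, function(tr) {
    x <- core$value[core$trait == tr]
    y <- panel$value[panel$trait == tr]
    if (diff(range(x)) == 0) {
      warning("trait '", tr, "' has zero range in the core; excluded")
      return(NULL)
    }
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) 1
         else stats::t.test(x, y)$p.value
    cv <- function(v) 100 * stats::sd(v) / mean(v)
    data.frame(trait = tr,
               mean_core = mean(x), mean_panel = mean(y), p_value = p,
               range_core = diff(range(x)), range_panel = diff(range(y)),
               cv_core = cv(x), cv_panel = cv(y),
               h_core = shannon_weaver_index(x, n_classes),
               h_panel = shannon_weaver_index(y, n_classes),
               stringsAsFactors = FALSE)
  })
  per_trait <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_trait) || nrow(per_trait) == 0) {
    stop("no evaluable traits", call. = FALSE)
  }
  summary <- c(
    md_pct = 100 * mean(per_trait$p_value < alpha),
    cr_pct = coincidence_rate(per_trait$range_core, per_trait$range_panel),
    vr_pct = mean(100 * per_trait$cv_panel / per_trait$cv_core),
    h_core = mean(per_trait$h_core),
    h_panel = mean(per_trait$h_panel))
  list(per_trait = per_trait, summary = summary)
}

#' Student-Newman-Keuls post-hoc mean comparisons
#'
#' Stepwise studentized-range comparisons after a one-way ANOVA: group means
#' are ordered and each pair is tested against the critical range for the
#' number of means it spans, with the usual non-testing rule (a pair inside a
#' non-significant stretch is declared non-significant without testing).
#' Balanced groups are assumed; the harmonic mean group size is used
#' otherwise.
#'
#' @param value,group Observations and group labels.
#' @param alpha Family significance level (default 0.05).
#' @return data.frame of pairwise comparisons: `g1`, `g2`, `diff`, `span`,
#'   `q` (studentized range statistic), `q_crit`, `p`, `significant`.
#' @export
posthoc_mean_comparison <- function(value, group, alpha = 0.05) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  a <- oneway_anova(value, group)
  means <- sort(tapply(value, group, mean))
  n_h <- 1 / mean(1 / table(group)) # harmonic mean group size
  se <- sqrt(a$ms_error / n_h)

  pairs <- utils::combn(k, 2)
  out <- data.frame(
    g1 = names(means)[pairs[1, ]], g2 = names(means)[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    span = pairs[2, ] - pairs[1, ] + 1L,
    q = NA_real_, q_crit = NA_real_, p = NA_real_, significant = FALSE,
    stringsAsFactors = FALSE, row.names = NULL)

  if (a$ms_error == 0) {
    # degenerate: any non-zero difference is significant, ties are not
    out$q <- ifelse(out$diff == 0, 0, Inf)
    out$p <- ifelse(out$diff == 0, 1, 0)
    out$significant <- out$diff != 0
    return(out)
  }

  out$q <- abs(out$diff) / se
  out$q_crit <- stats::qtukey(1 - alpha, out$span, a$df_error)
  out$p <- stats::ptukey(out$q, out$span, a$df_error, lower.tail = FALSE)

  # stepwise non-testing rule, widest spans first
  blocked <- matrix(FALSE, k, k)
  for (sp in sort(unique(out$span), decreasing = TRUE)) {
    idx <- which(out$span == sp)
    for (i in idx) {
      lo <- match(out$g1[i], names(means))
      hi <- match(out$g2[i], names(means))
      if (blocked[lo, hi]) next
      if (out$q[i] >= out$q_crit[i]) {
        out$significant[i] <- TRUE
      } else {
        # block all sub-ranges
        for (l in lo:hi) for (h in l:hi) blocked[l, h] <- TRUE
      }
    }
  }
  out
}
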