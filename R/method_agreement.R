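#' Pearson correlation between paired measurements
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return List with `r`, `r2`, `p`, `n`, `undefined` (TRUE when either
#'   vector is constant, in which case `r`/`p` are `NA`).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = length(x),
                undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x), undefined = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of `y - x`), SD of the differences, 1.96-SD limits of
#' agreement, and the correlation of the differences with the pair means
#' (the check that disagreement does not grow with the magnitude of the
#' measurement).
#'
#' @param x Measurements by method A (direction: differences are B - A).
#' @param y Measurements by method B.
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `r_diff_mean`, `p_diff_mean`, `n`, `direction`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- y - x
  m <- (x + y) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  trend <- if (stats::sd(d) == 0 || stats::sd(m) == 0) {
    list(r = NA_real_, p = NA_real_)
  } else {
    ct <- stats::cor.test(d, m)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(bias = bias, sd_diff = sdd,
       loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       r_diff_mean = trend$r, p_diff_mean = trend$p,
       n = length(x), direction = "B - A")
}
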