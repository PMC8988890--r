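#' Iron isotope compositions and study constants
#'
#' An `isotope_composition` holds the atom fractions of the four stable iron
#' isotopes (54, 56, 57, 58). Fractions must lie in \[0, 1\], sum to 1 within
#' 1e-9, and the 56Fe fraction must be positive because all measured ratios
#' are expressed relative to 56Fe.
#'
#' @param a54,a56,a57,a58 Atom fractions of 54Fe, 56Fe, 57Fe and 58Fe.
#' @return An object of class `isotope_composition` (named numeric vector).
#' @examples
#' natural_iron_composition()
#' isotope_composition(0.001, 0.020, 0.960, 0.019)
#' @export
isotope_composition <- function(a54, a56, a57, a58) {
  a <- c(a54 = a54, a56 = a56, a57 = a57, a58 = a58)
  if (anyNA(a) || !is.numeric(a)) {
    stop("isotope fractions must be numeric and non-missing", call. = FALSE)
  }
  if (any(a < 0) || any(a > 1)) {
    stop("isotope fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(a) - 1) > 1e-9) {
    stop("isotope fractions must sum to 1 (within 1e-9), got ",
         format(sum(a), digits = 12), call. = FALSE)
  }
  if (a[["a56"]] <= 0) {
    stop("a56 must be > 0: ratios are expressed relative to 56Fe",
         call. = FALSE)
  }
  structure(a, class = "isotope_composition")
}

# atomic masses of the stable iron isotopes (g/mol), CODATA/AME values
.FE_ISOTOPE_MASS <- c(a54 = 53.93961, a56 = 55.93494,
                      a57 = 56.93539, a58 = 57.93328)

#' Natural iron isotopic composition
#'
#' IUPAC representative atom fractions for natural iron:
#' 54Fe 0.05845, 56Fe 0.91754, 57Fe 0.02119, 58Fe 0.00282.
#'
#' @return An `isotope_composition`.
#' @export
natural_iron_composition <- function() {
  isotope_composition(0.05845, 0.91754, 0.02119, 0.00282)
}

#' Enriched label compositions
#'
#' Default isotopic compositions of the enriched FeSO4 labels used in
#' dual-tracer feeding studies: a ~96% 57Fe label and a ~99% 58Fe label.
#' Commercial enrichments vary between batches; real analyses should supply
#' the certificate values instead.
#'
#' @param label `"Fe57"` or `"Fe58"`.
#' @return An `isotope_composition`.
#' @export
label_composition <- function(label = c("Fe57", "Fe58")) {
  label <- match.arg(label)
  switch(label,
    Fe57 = isotope_composition(0.001, 0.020, 0.960, 0.019),
    Fe58 = isotope_composition(0.001, 0.002, 0.004, 0.993)
  )
}

#' Mean molar mass of an isotope mixture
#'
#' @param composition An `isotope_composition`.
#' @return Molar mass in g/mol (fraction-weighted isotope masses).
#' @export
iso_molar_mass <- function(composition) {
  stopifnot(inherits(composition, "isotope_composition"))
  sum(unclass(composition) * .FE_ISOTOPE_MASS)
}

#' Isotope ratios of a composition
#'
#' @param composition An `isotope_composition`.
#' @return Named vector `c(r54, r57, r58)` of atom ratios to 56Fe.
#' @export
iso_ratios <- function(composition) {
  stopifnot(inherits(composition, "isotope_composition"))
  c(r54 = composition[["a54"]] / composition[["a56"]],
    r57 = composition[["a57"]] / composition[["a56"]],
    r58 = composition[["a58"]] / composition[["a56"]])
}

#' A pair of measured iron isotope ratios
#'
#' Thermal-ionisation MS of blood iron reports the atom ratios 57Fe/56Fe and
#' 58Fe/56Fe. Both must be positive.
#'
#' @param r57 57Fe/56Fe atom ratio.
#' @param r58 58Fe/56Fe atom ratio.
#' @return A `ratio_pair` (named numeric vector).
#' @export
ratio_pair <- function(r57, r58) {
  if (!is.numeric(r57) || !is.numeric(r58) || anyNA(c(r57, r58)) ||
      r57 <= 0 || r58 <= 0) {
    stop("isotope ratios must be positive numbers", call. = FALSE)
  }
  structure(c(r57 = r57, r58 = r58), class = "ratio_pair")
}

#' Study constants for the tracer calculus
#'
#' Bundles the fixed quantities entering the absorption calculation:
#' the haemoglobin iron content (mg Fe per g Hb), the assumed erythrocyte
#' incorporation of absorbed iron, the blood-volume model name, the natural
#' iron composition, and molar masses of phytic acid and iron. All are
#' overridable per run.
#'
#' @param hb_iron mg Fe per g haemoglobin (default 3.47, standard
#'   stoichiometry of the haem groups).
#' @param incorporation Fraction of absorbed iron assumed incorporated into
#'   erythrocytes 14 days after dosing (default 0.80).
#' @param blood_volume_model Name of a registered blood-volume model; see
#'   [estimate_blood_volume()].
#' @param natural Natural iron `isotope_composition`.
#' @param pa_molar_mass Molar mass of phytic acid, g/mol.
#' @param fe_molar_mass Molar mass of natural iron, g/mol.
#' @return A list of class `iron_constants`.
#' @export
iron_constants <- function(hb_iron = 3.47,
                           incorporation = 0.80,
                           blood_volume_model = "per_kg",
                           natural = natural_iron_composition(),
                           pa_molar_mass = 660.04,
                           fe_molar_mass = 55.845) {
  if (hb_iron <= 0) stop("hb_iron must be > 0", call. = FALSE)
  if (incorporation <= 0 || incorporation > 1) {
    stop("incorporation must lie in (0, 1]", call. = FALSE)
  }
  structure(list(hb_iron = hb_iron,
                 incorporation = incorporation,
                 blood_volume_model = blood_volume_model,
                 natural = natural,
                 pa_molar_mass = pa_molar_mass,
                 fe_molar_mass = fe_molar_mass,
                 abundance_source = "IUPAC representative values"),
            class = "iron_constants")
}
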