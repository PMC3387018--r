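# Exact arithmetic between observed m/z and neutral monoisotopic mass under
# adduct / isotope / charge annotations, plus ppm tolerance matching.

# Charge-carrier mass shifts in Da per charge event, relative to the neutral.
# Values follow the adduct table printed by CAMERA so that neutral-mass
# estimates in its output round-trip exactly; the Na/K shifts are the cation
# masses (atom minus one electron).
.PROTON <- 1.00727646688
.NA_DELTA <- 22.98921822
.K_DELTA <- 38.96315791
.H2O <- 18.01056468
.ISO_DELTA <- 1.00335484 # 13C - 12C spacing

.ADDUCTS_POS <- c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+H-H2O]+")
.ADDUCTS_NEG <- c("[M-H]-")

#' Supported adduct species
#'
#' The positive-mode species are the protonated ion, its sodium and potassium
#' adducts and the in-source water-loss fragment; negative mode supports the
#' deprotonated ion only. Doubly charged ions are interpreted as
#' `[M+2H]2+`, i.e. `adduct = "[M+H]+"` with `charge = 2`.
#'
#' @param polarity `"positive"`, `"negative"`, or `NULL` for both.
#' @return Character vector of adduct codes.
#' @export
#' @examples
#' adducts()
#' adducts("negative")
adducts <- function(polarity = NULL) {
  if (is.null(polarity)) return(c(.ADDUCTS_POS, .ADDUCTS_NEG))
  switch(match.arg(polarity, c("positive", "negative")),
    positive = .ADDUCTS_POS,
    negative = .ADDUCTS_NEG
  )
}

.check_annotation <- function(adduct, charge, isotope_order) {
  ok <- adduct %in% c(.ADDUCTS_POS, .ADDUCTS_NEG)
  if (!all(ok)) {
    rlang::abort(paste0("unknown adduct code: ", unique(adduct[!ok])[1]))
  }
  if (!all(charge %in% c(1L, 2L))) {
    rlang::abort("charge must be 1 or 2")
  }
  if (any(charge == 2L & adduct != "[M+H]+")) {
    rlang::abort("doubly charged ions are supported as [M+2H]2+ only (adduct \"[M+H]+\", charge 2)")
  }
  if (!all(isotope_order %in% 0:4)) {
    rlang::abort("isotope_order must be an integer in 0..4")
  }
  invisible(TRUE)
}

#' Mass shift of an adduct species
#'
#' Signed difference in Da between the singly charged ion and its neutral,
#' per charge-carrier event.
#'
#' @param adduct Adduct code, one of [adducts()].
#' @return Numeric vector of mass shifts in Da.
#' @export
#' @examples
#' adduct_delta("[M+H]+")   #  +1.00727647
#' adduct_delta("[M-H]-")   #  -1.00727647
adduct_delta <- function(adduct) {
  .check_annotation(adduct, 1L, 0L)
  unname(c(
    "[M+H]+" = .PROTON,
    "[M+Na]+" = .NA_DELTA,
    "[M+K]+" = .K_DELTA,
    "[M+H-H2O]+" = .PROTON - .H2O,
    "[M-H]-" = -.PROTON
  )[adduct])
}

#' Neutral monoisotopic mass from an observed m/z
#'
#' Inverts the ion formation: `M = z * mz - z * delta(adduct) - n * iso`,
#' where `iso` is the 13C-12C spacing and `n` the isotope order.
#'
#' @param mz Observed m/z (> 0). Vectorised.
#' @param adduct Adduct code, see [adducts()].
#' @param charge Ion charge, 1 or 2 (2 only as `[M+2H]2+`).
#' @param isotope_order Isotopologue order, 0 (monoisotopic) to 4.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' neutral_mass(624.3401, "[M-H]-")            # 625.34738
#' neutral_mass(313.17742, "[M+H]+", charge = 2)
neutral_mass <- function(mz, adduct = "[M+H]+", charge = 1L, isotope_order = 0L) {
  stopifnot(is.numeric(mz))
  if (any(mz <= 0)) rlang::abort("mz must be positive")
  .check_annotation(adduct, charge, isotope_order)
  m <- charge * mz - charge * adduct_delta(adduct) - isotope_order * .ISO_DELTA
  if (any(m <= 0)) {
    rlang::abort(paste0(
      "infeasible annotation: implied neutral mass ", format(min(m)),
      " Da is not positive"
    ))
  }
  m
}

#' Observed m/z of a neutral mass under an ion annotation
#'
#' Forward direction of [neutral_mass()]:
#' `mz = (M + z * delta(adduct) + n * iso) / z`.
#'
#' @param neutral Neutral monoisotopic mass in Da (> 0). Vectorised.
#' @inheritParams neutral_mass
#' @return m/z value.
#' @export
#' @examples
#' mz_of(625.34738, "[M-H]-")                     # 624.34010
#' mz_of(625.34738, "[M+H]+", isotope_order = 1)  # 627.35801
mz_of <- function(neutral, adduct = "[M+H]+", charge = 1L, isotope_order = 0L) {
  stopifnot(is.numeric(neutral))
  if (any(neutral <= 0)) rlang::abort("neutral mass must be positive")
  .check_annotation(adduct, charge, isotope_order)
  (neutral + charge * adduct_delta(adduct) + isotope_order * .ISO_DELTA) / charge
}

#' ppm mass match
#'
#' Relative tolerance match with the second argument as the reference
#' (database) mass: masses match when
#' `|mass_a - mass_b| / mass_b <= tol_ppm * 1e-6`. The signed error is
#' `(mass_a - mass_b) / mass_b * 1e6` ppm.
#'
#' @param mass_a Query mass in Da (> 0). Vectorised with `mass_b`.
#' @param mass_b Reference mass in Da (> 0).
#' @param tol_ppm Tolerance in parts per million (>= 0); 10 ppm is the usual
#'   setting for Q-TOF accuracy.
#' @return A tibble with columns `match` (logical) and `ppm_error` (signed).
#' @export
#' @examples
#' ppm_match(100.0005, 100, 10)  # match, +5 ppm
#' ppm_match(100.0011, 100, 10)  # no match, +11 ppm
ppm_match <- function(mass_a, mass_b, tol_ppm = 10) {
  stopifnot(is.numeric(mass_a), is.numeric(mass_b), tol_ppm >= 0)
  if (any(mass_a <= 0) || any(mass_b <= 0)) rlang::abort("masses must be positive")
  err <- (mass_a - mass_b) / mass_b * 1e6
  tibble::tibble(match = abs(err) <= tol_ppm, ppm_error = err)
}

#' The (de)protonated adduct for an ionization mode
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return `"[M+H]+"` or `"[M-H]-"`.
#' @export
protonation_adduct <- function(polarity) {
  switch(match.arg(polarity, c("positive", "negative")),
    positive = "[M+H]+",
    negative = "[M-H]-"
  )
}
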