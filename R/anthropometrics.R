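#' Body surface area (Du Bois formula)
#'
#' Computes body surface area from weight and height using the Du Bois and
#' Du Bois formula, `BSA = 0.007184 * weight^0.425 * height^0.725`, with
#' weight in kilograms and height in centimetres. The constant 0.007184 is
#' the centimetre form of the formula; with typical adult anthropometrics
#' (62 kg, 165 cm) it yields about 1.68 m^2.
#'
#' @param weight_kg Body weight in kilograms (> 0). Vectorized.
#' @param height_cm Body height in centimetres (> 0). Vectorized.
#' @return Body surface area in square metres.
#' @examples
#' compute_bsa(62, 165)   # ~1.68
#' compute_bsa(80, 180)
#' @export
compute_bsa <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("compute_bsa: 'weight_kg' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("compute_bsa: 'height_cm' must be finite and > 0", call. = FALSE)
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Body mass index
#'
#' Weight divided by height squared, with height converted from centimetres
#' to metres.
#'
#' @inheritParams compute_bsa
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(62, 165)   # ~22.77
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("compute_bmi: 'weight_kg' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("compute_bmi: 'height_cm' must be finite and > 0", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' Age-correction policy
#'
#' The healthy reference population contains very few elderly subjects, so
#' for a novelty detector advanced age by itself becomes a reason to flag a
#' subject. The age correction compresses the upper end of the age scale with
#' a saturating transform
#' \deqn{C = P \left(1 - \left(\frac{K - \min(A, K)}{K}\right)^2\right)}
#' where `A` is chronological age, `K` the cap age (default 90 years) and
#' `P` the plateau (default 75 years). The corrected age is used in place of
#' chronological age both when training and when scoring, whenever the policy
#' is enabled. Default is disabled: raw age is used.
#'
#' @param enabled Logical; apply the correction at fit and score time.
#' @param cap_age Age (years) at which the transform saturates; default 90.
#' @param plateau Corrected-age value reached at `cap_age`; default 75.
#' @return An object of class `age_policy`.
#' @seealso [correct_age()]
#' @export
age_policy <- function(enabled = FALSE, cap_age = 90, plateau = 75) {
  stopifnot(is.logical(enabled), length(enabled) == 1L)
  if (!is.numeric(cap_age) || cap_age <= 0)
    stop("age_policy: 'cap_age' must be > 0", call. = FALSE)
  if (!is.numeric(plateau) || plateau <= 0)
    stop("age_policy: 'plateau' must be > 0", call. = FALSE)
  structure(list(enabled = enabled, cap_age = cap_age, plateau = plateau),
            class = "age_policy")
}

#' @export
print.age_policy <- function(x, ...) {
  cat(sprintf("Age-correction policy: %s (cap %g y, plateau %g y)\n",
              if (x$enabled) "enabled" else "disabled", x$cap_age, x$plateau))
  invisible(x)
}

#' Corrected age
#'
#' Evaluates the saturating age correction of [age_policy()]. The mapping is
#' continuous, non-decreasing, 0 at age 0 and constant (equal to the plateau,
#' 75 years by default) for ages at or above the cap (90 years by default);
#' e.g. age 45 maps to 56.25 and age 90 to 75 under the defaults.
#'
#' @param age Chronological age in years (>= 0). Vectorized.
#' @param policy An [age_policy()]. The correction formula is applied
#'   regardless of `policy$enabled`; the enabled flag governs whether model
#'   fitting/scoring calls this at all.
#' @return Corrected age in years.
#' @export
correct_age <- function(age, policy = age_policy()) {
  if (any(!is.finite(age)) || any(age < 0))
    stop("correct_age: 'age' must be finite and >= 0", call. = FALSE)
  K <- policy$cap_age
  policy$plateau * (1 - ((K - pmin(age, K)) / K)^2)
}

# Age as used by a model under a policy: corrected when enabled, raw otherwise.
effective_age <- function(age, policy) {
  if (isTRUE(policy$enabled)) correct_age(age, policy) else age
}
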