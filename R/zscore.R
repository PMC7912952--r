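#' Fit the per-level linear diameter model
#'
#' One ordinary-least-squares model per aortic level, trained on all
#' available healthy subjects at once (all ages, both sexes): diameter (mm)
#' regressed on age and BSA — each divided by its training-cohort maximum —
#' and a female indicator (female = 1). The residual scale `sigma` is the
#' root mean squared training residual, i.e. the variance is estimated from
#' training MSE under a homoscedasticity assumption; no variance modelling is
#' attempted. Z-scores are then `(observed - predicted) / sigma`.
#'
#' @param cohort An `aorta_cohort`; rows with the level's diameter missing
#'   are dropped.
#' @param level One of `"AAn"`, `"SoV"`, `"SJ"`, `"PAA"`.
#' @param adults_only If `TRUE`, fit only on subjects with age > 15 years.
#' @param policy An [age_policy()]; when enabled, corrected age replaces raw
#'   age at fit and prediction time (the stored `age_max` is then the
#'   corrected-age training maximum).
#' @return An object of class `diameter_lm` with fields `level`, `intercept`,
#'   `coef_age`, `coef_bsa`, `coef_female` (mm scale), `age_max`, `bsa_max`,
#'   `sigma` (mm), `n_train`, `adults_only`, `age_policy`.
#' @export
fit_linear_model <- function(cohort, level, adults_only = FALSE,
                             policy = age_policy()) {
  level <- match.arg(level, AORTIC_LEVELS)
  data <- as.data.frame(cohort)
  if (adults_only) data <- data[data$age > 15, , drop = FALSE]
  d <- data[[diameter_col(level)]]
  data <- data[!is.na(d), , drop = FALSE]
  if (nrow(data) < 10L)
    stop("fit_linear_model: need >= 10 records with ", level,
         " measured", call. = FALSE)
  age <- effective_age(data$age, policy)
  bsa <- cohort_bsa(data)
  female <- is_female(data$sex)
  if (length(unique(female)) < 2L)
    stop("fit_linear_model: single-sex cohort gives a rank-deficient design",
         call. = FALSE)
  age_max <- max(age)
  bsa_max <- max(bsa)
  df <- data.frame(y = data[[diameter_col(level)]],
                   age_n = age / age_max, bsa_n = bsa / bsa_max,
                   female = female)
  fit <- stats::lm(y ~ age_n + bsa_n + female, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("fit_linear_model: rank-deficient design for level ", level,
         call. = FALSE)
  structure(list(
    level = level,
    intercept = unname(cf["(Intercept)"]),
    coef_age = unname(cf["age_n"]),
    coef_bsa = unname(cf["bsa_n"]),
    coef_female = unname(cf["female"]),
    age_max = age_max, bsa_max = bsa_max,
    sigma = sqrt(mean(stats::residuals(fit)^2)),
    n_train = nrow(df),
    adults_only = adults_only,
    age_policy = policy
  ), class = "diameter_lm")
}

#' Fit the four per-level linear models at once
#'
#' @inheritParams fit_linear_model
#' @return Named list of [fit_linear_model()] results, one per level.
#' @export
fit_linear_models <- function(cohort, adults_only = FALSE,
                              policy = age_policy()) {
  models <- lapply(AORTIC_LEVELS, function(lv)
    fit_linear_model(cohort, lv, adults_only = adults_only, policy = policy))
  names(models) <- AORTIC_LEVELS
  models
}

#' @export
print.diameter_lm <- function(x, ...) {
  cat(sprintf(
    "Linear diameter model [%s]%s: n=%d, sigma=%.3f mm\n", x$level,
    if (x$adults_only) " (adults only)" else "", x$n_train, x$sigma))
  cat(sprintf(
    "  d = %.3f + %.3f*(age/%.4g) + %.3f*(BSA/%.4g) + %.3f*female\n",
    x$intercept, x$coef_age, x$age_max, x$coef_bsa, x$bsa_max,
    x$coef_female))
  invisible(x)
}

#' Predicted diameter for a subject
#'
#' @param model A [fit_linear_model()] result.
#' @param record One-row data frame (or cohort rows) with `age`, `sex`,
#'   `height_cm`, `weight_kg`.
#' @return Predicted diameter(s) in mm.
#' @export
predict_diameter <- function(model, record) {
  record <- as.data.frame(record)
  needed <- c("age", "sex", "height_cm", "weight_kg")
  if (!all(needed %in% names(record)) ||
      anyNA(record[, needed]))
    stop("predict_diameter: record must supply age, sex, height_cm, weight_kg",
         call. = FALSE)
  age <- effective_age(record$age, model$age_policy)
  bsa <- cohort_bsa(record)
  model$intercept +
    model$coef_age * (age / model$age_max) +
    model$coef_bsa * (bsa / model$bsa_max) +
    model$coef_female * is_female(record$sex)
}

#' Z-score of an observed diameter
#'
#' `(observed - predicted) / sigma`. Under the model's homoscedastic
#' Gaussian assumption a one-sided Z of 2 corresponds to roughly the 2.3rd
#' upper percentile; a level is called abnormal when Z > 2.
#'
#' @inheritParams predict_diameter
#' @param observed Observed diameter in mm (> 0).
#' @return Z-score(s).
#' @export
z_score <- function(model, record, observed) {
  if (any(!is.finite(observed)) || any(observed <= 0))
    stop("z_score: 'observed' must be finite and > 0", call. = FALSE)
  if (model$sigma <= 0)
    stop("z_score: degenerate model (sigma = 0)", call. = FALSE)
  (observed - predict_diameter(model, record)) / model$sigma
}

#' Per-level and global Z-score report
#'
#' Scores every measured level of one subject with its level's model. The
#' global statistic is the maximum Z over measured levels, operationalizing
#' "abnormal in at least one segment" as a continuous quantity; the global
#' abnormal flag is equivalent to any level exceeding 2.
#'
#' @param models Named list of the four [fit_linear_model()] results
#'   (names `AAn`, `SoV`, `SJ`, `PAA`).
#' @param record One-row subject data frame; see [subject_record()].
#' @return Object of class `z_report`: data frame `levels` (level, diameter,
#'   z, category), `global_statistic` (max z), `global_abnormal`.
#' @export
z_report <- function(models, record) {
  stopifnot(all(AORTIC_LEVELS %in% names(models)))
  record <- as.data.frame(record)
  stopifnot(nrow(record) == 1L)
  z <- vapply(AORTIC_LEVELS, function(lv) {
    obs <- record[[diameter_col(lv)]]
    if (is.na(obs)) NA_real_ else z_score(models[[lv]], record, obs)
  }, numeric(1))
  if (all(is.na(z)))
    stop("z_report: record has no measured diameter", call. = FALSE)
  diam <- vapply(AORTIC_LEVELS, function(lv) record[[diameter_col(lv)]],
                 numeric(1))
  levels_df <- data.frame(
    level = AORTIC_LEVELS, diameter_mm = diam, z = unname(z),
    category = ifelse(is.na(z), NA_character_,
                      ifelse(z > 2, "abnormal", "normal")),
    stringsAsFactors = FALSE)
  structure(list(levels = levels_df,
                 global_statistic = max(z, na.rm = TRUE),
                 global_abnormal = any(z > 2, na.rm = TRUE)),
            class = "z_report")
}

#' @export
print.z_report <- function(x, ...) {
  cat("Z-score report (abnormal: z > 2)\n")
  df <- x$levels
  df$z <- round(df$z, 2)
  print(df, row.names = FALSE)
  cat(sprintf("Global: max z = %.2f -> %s\n", x$global_statistic,
              if (x$global_abnormal) "ABNORMAL" else "normal"))
  invisible(x)
}

#' Serialize / restore a linear diameter model as JSON
#'
#' @param model A `diameter_lm`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly (`read_linear_model`: the restored model).
#' @export
write_linear_model <- function(model, path) {
  payload <- unclass(model)
  payload$age_policy <- unclass(model$age_policy)
  payload$schema <- "aortanorm/diameter_lm/1"
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "aortanorm/diameter_lm/1"))
    stop("read_linear_model: unrecognized schema in ", path, call. = FALSE)
  payload$schema <- NULL
  payload$age_policy <- do.call(age_policy, payload$age_policy)
  structure(payload, class = "diameter_lm")
}
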