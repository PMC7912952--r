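#' Aortic measurement levels
#'
#' The four thoracic-aorta levels measured by 2D transthoracic
#' echocardiography: aortic annulus (AAn), sinuses of Valsalva (SoV),
#' sinotubular junction (SJ) and proximal ascending aorta (PAA). Diameter
#' columns in a cohort are named `aan_mm`, `sov_mm`, `sj_mm`, `paa_mm`.
#'
#' @format Character vector of length 4.
#' @export
AORTIC_LEVELS <- c("AAn", "SoV", "SJ", "PAA")

diameter_col <- function(level) {
  level <- match.arg(level, AORTIC_LEVELS)
  paste0(tolower(level), "_mm")
}

COHORT_COLUMNS <- c("subject_id", "age", "sex", "height_cm", "weight_kg",
                    "aan_mm", "sov_mm", "sj_mm", "paa_mm", "group")

#' Construct a cohort of subject records
#'
#' A cohort is a data frame with one row per subject and the columns
#' `subject_id`, `age` (years), `sex` (`"F"`/`"M"`), `height_cm`,
#' `weight_kg`, the four diameter columns `aan_mm`, `sov_mm`, `sj_mm`,
#' `paa_mm` (mm; `NA` where a level was not measured) and `group`
#' (`healthy`, `dilated`, `MFS`, `BAV` or `unknown`). Body surface area is
#' derived on demand with [compute_bsa()] and never stored. Validity is
#' checked on construction: unique ids, ages in \[0, 120\], positive
#' anthropometrics, present diameters in (0, 100) mm.
#'
#' @param data A data frame with (at least) the columns above; extra columns
#'   are carried through untouched.
#' @param label Free-text provenance label.
#' @return A data frame of class `aorta_cohort`.
#' @export
as_aorta_cohort <- function(data, label = "") {
  data <- as.data.frame(data)
  missing_cols <- setdiff(COHORT_COLUMNS, names(data))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L)
    stop("cohort must contain at least one record", call. = FALSE)
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id))
    stop("cohort subject_ids must be unique", call. = FALSE)
  data$sex <- toupper(as.character(data$sex))
  if (!all(data$sex %in% c("F", "M")))
    stop("cohort 'sex' must be 'F' or 'M'", call. = FALSE)
  if (any(!is.finite(data$age)) || any(data$age < 0) || any(data$age > 120))
    stop("cohort 'age' must lie in [0, 120] years", call. = FALSE)
  if (any(data$height_cm <= 0) || any(data$weight_kg <= 0))
    stop("cohort 'height_cm' and 'weight_kg' must be > 0", call. = FALSE)
  for (lv in AORTIC_LEVELS) {
    d <- data[[diameter_col(lv)]]
    bad <- !is.na(d) & (d <= 0 | d >= 100)
    if (any(bad))
      stop("cohort '", diameter_col(lv), "' must lie in (0, 100) mm",
           call. = FALSE)
  }
  data$group <- as.character(data$group)
  if (!all(data$group %in% c("healthy", "dilated", "MFS", "BAV", "unknown")))
    stop("cohort 'group' must be one of healthy/dilated/MFS/BAV/unknown",
         call. = FALSE)
  structure(data, label = label,
            class = c("aorta_cohort", "data.frame"))
}

#' Read a cohort CSV
#'
#' Reads the standard cohort table: header
#' `subject_id,age,sex,height_cm,weight_kg,aan_mm,sov_mm,sj_mm,paa_mm,group`,
#' UTF-8, dot decimal separator, empty cells for missing diameters.
#'
#' @param path Path to a CSV file.
#' @param label Provenance label; defaults to the file path.
#' @return An `aorta_cohort`.
#' @export
read_cohort <- function(path, label = path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  as_aorta_cohort(data, label = label)
}

#' Write a cohort CSV
#'
#' @param cohort An `aorta_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, COHORT_COLUMNS],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.aorta_cohort <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Aortic cohort: %d subjects%s\n", nrow(x),
              if (nzchar(lab)) paste0(" (", lab, ")") else ""))
  cat(sprintf("  female: %.1f%%; age %.0f-%.0f y; groups: %s\n",
              100 * mean(x$sex == "F"), min(x$age), max(x$age),
              paste(names(table(x$group)), table(x$group),
                    sep = "=", collapse = ", ")))
  for (lv in AORTIC_LEVELS) {
    d <- x[[diameter_col(lv)]]
    cat(sprintf("  %-3s median %.1f mm (n=%d measured)\n",
                lv, stats::median(d, na.rm = TRUE), sum(!is.na(d))))
  }
  invisible(x)
}

# Numeric sex indicator: female = 1, male = 0 (sign convention under which
# the fitted female coefficients on diameter are negative at AAn/SoV/SJ).
is_female <- function(sex) as.numeric(toupper(as.character(sex)) == "F")

# BSA for every row of a cohort-like data frame.
cohort_bsa <- function(data) compute_bsa(data$weight_kg, data$height_cm)

#' Build a single-subject record
#'
#' One subject as a one-row data frame in the cohort column layout, suitable
#' for [z_report()], [q_score()] and [q_report()]. Diameters not supplied are
#' `NA` (that level is then skipped by local scores and the global Q-score is
#' unavailable).
#'
#' @param age Age in years.
#' @param sex `"F"` or `"M"`.
#' @param height_cm,weight_kg Anthropometrics (cm, kg).
#' @param aan_mm,sov_mm,sj_mm,paa_mm Diameters in mm, `NA` if unmeasured.
#' @param subject_id,group Identifier and group label.
#' @return One-row data frame.
#' @export
subject_record <- function(age, sex, height_cm, weight_kg,
                           aan_mm = NA_real_, sov_mm = NA_real_,
                           sj_mm = NA_real_, paa_mm = NA_real_,
                           subject_id = "subject", group = "unknown") {
  data.frame(subject_id = subject_id, age = age, sex = toupper(sex),
             height_cm = height_cm, weight_kg = weight_kg,
             aan_mm = aan_mm, sov_mm = sov_mm, sj_mm = sj_mm, paa_mm = paa_mm,
             group = group, stringsAsFactors = FALSE)
}
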