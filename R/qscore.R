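#' Percentile grid for the Q-score ensemble
#'
#' The Q-score sweeps a grid of target percentiles nu, one one-class SVM per
#' grid value. The default grid is 0.01, 0.02, ..., 0.30 (1% steps up to
#' 30%), so the smallest reportable Q-score is 1% and subjects inside every
#' fitted support are reported above-grid (">30%").
#'
#' @param values Strictly increasing vector of nu values in (0, 1).
#' @return Object of class `nu_grid`.
#' @export
nu_grid <- function(values = seq(0.01, 0.30, by = 0.01)) {
  if (!is.numeric(values) || length(values) < 1L ||
      any(values <= 0) || any(values >= 1) || is.unsorted(values, strictly = TRUE))
    stop("nu_grid: 'values' must be strictly increasing in (0, 1)",
         call. = FALSE)
  structure(list(values = values), class = "nu_grid")
}

# Scaled-variance bandwidth heuristic (see fit_qscore_ensemble).
default_gamma <- function(x_norm) {
  1 / (ncol(x_norm) * stats::var(as.vector(x_norm)))
}

# Feature names for a scope. All Q-score scopes share age, sex, BSA;
# local adds one diameter, global all four.
qscore_feature_names <- function(scope, level = NULL) {
  if (scope == "global") {
    c("age", "sex", "bsa", vapply(AORTIC_LEVELS, diameter_col, ""))
  } else if (scope == "local") {
    level <- match.arg(level, AORTIC_LEVELS)
    c("age", "sex", "bsa", diameter_col(level))
  } else stop("unknown scope: ", scope, call. = FALSE)
}

# Raw (pre-normalization) feature frame for any feature list. 'age' is the
# policy-effective age, 'sex' the female indicator, 'bsa' Du Bois BSA; any
# *_mm name is taken from the corresponding diameter column.
build_feature_frame <- function(data, features, policy) {
  data <- as.data.frame(data)
  out <- lapply(features, function(f) {
    switch(f,
      age = effective_age(data$age, policy),
      sex = is_female(data$sex),
      bsa = cohort_bsa(data),
      {
        if (is.null(data[[f]]))
          stop("record is missing feature '", f, "'", call. = FALSE)
        data[[f]]
      })
  })
  names(out) <- features
  as.data.frame(out, optional = TRUE)
}

# Fit one RBF one-class SVM per grid nu on an already-normalized matrix and
# keep only what the decision function needs (support vectors, dual
# coefficients, offset). The quadratic program is delegated to e1071/libsvm;
# everything Q-score-specific (grid sweep, min-nu rule, thresholds) is here.
fit_ocsvm_grid <- function(x_norm, grid, gamma) {
  models <- lapply(grid$values, function(nu) {
    fit <- e1071::svm(x_norm, type = "one-classification", nu = nu,
                      kernel = "radial", gamma = gamma, scale = FALSE)
    dv <- ocsvm_decision(list(sv = fit$SV, coefs = as.numeric(fit$coefs),
                              rho = fit$rho, gamma = gamma), x_norm)
    list(nu = nu, sv = unname(fit$SV), coefs = as.numeric(fit$coefs),
         rho = fit$rho, gamma = gamma,
         train_flag_frac = mean(dv < 0))
  })
  names(models) <- sprintf("nu_%02d", round(100 * grid$values))
  models
}

# f(x) = sum_i alpha_i K(sv_i, x) - rho with the Gaussian kernel; sign > 0
# means x lies in the estimated support.
ocsvm_decision <- function(machine, x_norm) {
  x_norm <- as.matrix(x_norm)
  sv <- as.matrix(machine$sv)
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2ab'
  d2 <- outer(rowSums(x_norm^2), rowSums(sv^2), "+") -
    2 * tcrossprod(x_norm, sv)
  d2[d2 < 0] <- 0
  drop(exp(-machine$gamma * d2) %*% machine$coefs) - machine$rho
}

#' Fit a Q-score ensemble of one-class SVMs
#'
#' Estimates the support of the joint distribution of demographics,
#' anthropometrics and aortic diameters in a healthy cohort, at every
#' percentile nu of the grid. Features are age (optionally corrected, see
#' [age_policy()]), sex (female = 1), Du Bois BSA, and either one diameter
#' (`scope = "local"`) or all four (`scope = "global"`); each feature is
#' min-max normalized to \[0, 1\] on the training cohort. One RBF-kernel
#' one-class SVM is trained per grid nu, so that roughly a fraction nu of
#' training subjects falls outside each fitted support.
#'
#' The kernel bandwidth defaults to `gamma = 1 / (d * var(X))` with `d` the
#' feature count and `var(X)` the overall variance of the normalized
#' training matrix — the standard scaled heuristic, exposed as a parameter.
#' Smaller bandwidths improve held-out percentile calibration at the small
#' end of the nu grid but blunt the ensemble's sensitivity to joint-shape
#' abnormalities; the default favours shape sensitivity (see the package
#' vignette for the trade-off).
#'
#' @param cohort An `aorta_cohort`; rows missing any required feature are
#'   dropped, and at least 50 complete rows are required.
#' @param scope `"global"` (all four diameters) or `"local"` (one level).
#' @param level Aortic level, required when `scope = "local"`.
#' @param grid A [nu_grid()].
#' @param policy An [age_policy()]; applied at both fit and score time.
#' @param gamma RBF bandwidth; `NULL` for the scaled heuristic.
#' @param adults_only If `TRUE`, train only on subjects with age > 15 years.
#' @return Object of class `qscore_ensemble`.
#' @export
fit_qscore_ensemble <- function(cohort, scope = c("global", "local"),
                                level = NULL, grid = nu_grid(),
                                policy = age_policy(), gamma = NULL,
                                adults_only = FALSE) {
  scope <- match.arg(scope)
  features <- qscore_feature_names(scope, level)
  data <- as.data.frame(cohort)
  if (adults_only) data <- data[data$age > 15, , drop = FALSE]
  raw <- build_feature_frame(data, features, policy)
  complete <- stats::complete.cases(raw)
  raw <- raw[complete, , drop = FALSE]
  if (nrow(raw) < 50L)
    stop("fit_qscore_ensemble: need >= 50 complete records, got ", nrow(raw),
         call. = FALSE)
  norm <- fit_normalization(raw)
  x_norm <- apply_normalization(norm, raw)
  if (is.null(gamma))
    gamma <- default_gamma(x_norm)
  structure(list(
    scope = scope,
    level = if (scope == "local") match.arg(level, AORTIC_LEVELS) else NULL,
    features = features,
    normalization = norm,
    grid = grid,
    age_policy = policy,
    gamma = gamma,
    n_train = nrow(raw),
    machines = fit_ocsvm_grid(x_norm, grid, gamma)
  ), class = "qscore_ensemble")
}

#' @export
print.qscore_ensemble <- function(x, ...) {
  cat(sprintf(
    "Q-score ensemble [%s%s]: %d one-class SVMs on nu grid %g-%g, n=%d\n",
    x$scope, if (!is.null(x$level)) paste0(":", x$level) else "",
    length(x$machines), min(x$grid$values), max(x$grid$values), x$n_train))
  cat(sprintf("  features: %s; gamma=%.4g; age correction %s\n",
              paste(x$features, collapse = ", "), x$gamma,
              if (x$age_policy$enabled) "on" else "off"))
  invisible(x)
}

# Decision values of every grid machine on records (rows), as an
# n x length(grid) matrix in ascending-nu order.
ensemble_decision_matrix <- function(ensemble, records) {
  raw <- build_feature_frame(records, ensemble$features, ensemble$age_policy)
  if (anyNA(raw))
    stop("q_score: record is missing required feature(s): ",
         paste(names(raw)[colSums(is.na(raw)) > 0], collapse = ", "),
         call. = FALSE)
  x_norm <- apply_normalization(ensemble$normalization, raw)
  dv <- vapply(ensemble$machines, function(m) ocsvm_decision(m, x_norm),
               numeric(nrow(x_norm)))
  matrix(dv, nrow = nrow(x_norm),
         dimnames = list(NULL, names(ensemble$machines)))
}

#' Q-score of one or more subjects
#'
#' The Q-score of a subject is the smallest grid percentile nu at which the
#' nu-level one-class SVM flags the subject (decision function < 0),
#' reported in percent. A subject inside every fitted support is above-grid
#' and reported as `Inf` (displayed ">30%"); above-grid counts as normal.
#' Interpretation thresholds: abnormal when Q < 2%, borderline when
#' 2% <= Q <= 4% (both ends inclusive), normal when Q > 4%.
#'
#' @param ensemble A [fit_qscore_ensemble()] result.
#' @param records One or more subject rows supplying the ensemble's features.
#' @return Numeric vector of Q-scores in percent (`Inf` = above-grid).
#' @export
q_score <- function(ensemble, records) {
  dv <- ensemble_decision_matrix(ensemble, as.data.frame(records))
  # grid values are percents on a 1% lattice; round away representation
  # error so comparisons like q <= 4 are exact
  nu_pct <- round(100 * ensemble$grid$values, 6)
  apply(dv, 1, function(row) {
    hit <- which(row < 0)
    if (length(hit)) nu_pct[min(hit)] else Inf
  })
}

#' Categorize Q-scores
#'
#' @param q Numeric Q-scores in percent (`Inf` = above-grid).
#' @return Character vector: `"abnormal"` (< 2%), `"borderline"`
#'   (2%–4%, inclusive), `"normal"` (> 4%, including above-grid).
#' @export
q_category <- function(q) {
  ifelse(is.na(q), NA_character_,
         ifelse(q < 2, "abnormal",
                ifelse(q <= 4, "borderline", "normal")))
}

# Render a Q-score for display: above-grid as ">30%".
format_q <- function(q, grid_max_pct = 30) {
  ifelse(is.na(q), "n/a",
         ifelse(is.infinite(q), paste0(">", grid_max_pct, "%"),
                paste0(q, "%")))
}

#' Local and global Q-score report for one subject
#'
#' Scores each measured level with its local ensemble and, when all four
#' diameters are present, the whole subject with the global ensemble.
#'
#' @param local_ensembles Named list of four local [fit_qscore_ensemble()]
#'   results (names `AAn`, `SoV`, `SJ`, `PAA`).
#' @param global_ensemble The global ensemble.
#' @param record One-row subject data frame.
#' @return Object of class `q_report`: data frame `levels` (level, diameter,
#'   q, category), `global_q`, `global_category`.
#' @export
q_report <- function(local_ensembles, global_ensemble, record) {
  stopifnot(all(AORTIC_LEVELS %in% names(local_ensembles)))
  record <- as.data.frame(record)
  stopifnot(nrow(record) == 1L)
  if (!identical(global_ensemble$scope, "global"))
    stop("q_report: 'global_ensemble' must have scope 'global'", call. = FALSE)
  pol <- global_ensemble$age_policy
  for (lv in AORTIC_LEVELS) {
    if (!identical(unclass(local_ensembles[[lv]]$age_policy), unclass(pol)))
      stop("q_report: ensembles were trained under different age policies",
           call. = FALSE)
  }
  q <- vapply(AORTIC_LEVELS, function(lv) {
    if (is.na(record[[diameter_col(lv)]])) NA_real_
    else q_score(local_ensembles[[lv]], record)
  }, numeric(1))
  diam <- vapply(AORTIC_LEVELS, function(lv) record[[diameter_col(lv)]],
                 numeric(1))
  gq <- if (any(is.na(diam))) NA_real_ else q_score(global_ensemble, record)
  structure(list(
    levels = data.frame(level = AORTIC_LEVELS, diameter_mm = diam,
                        q = unname(q), category = q_category(unname(q)),
                        stringsAsFactors = FALSE),
    global_q = gq,
    global_category = q_category(gq)
  ), class = "q_report")
}

#' @export
print.q_report <- function(x, ...) {
  cat("Q-score report (abnormal < 2%, borderline 2-4%, normal > 4%)\n")
  df <- x$levels
  df$q <- format_q(df$q)
  print(df, row.names = FALSE)
  cat(sprintf("Global Q = %s -> %s\n", format_q(x$global_q),
              if (is.na(x$global_category)) "n/a" else x$global_category))
  invisible(x)
}

#' Two-diameter Q-score heatmap
#'
#' Fits a diameters-only ensemble on a feature pair (by default PAA vs SoV,
#' no demographics), evaluates the Q-score on a rectangular lattice spanning
#' the training range (with margin), and extracts the 2% and 4% level-set
#' contours plus the guideline dilatation boundary (any diameter > 40 mm).
#'
#' @param cohort Training `aorta_cohort`.
#' @param features Two diameter column names, e.g. `c("paa_mm", "sov_mm")`.
#' @param resolution Lattice points per axis (>= 2).
#' @param margin Fractional range expansion beyond the training min/max.
#' @param grid,gamma Passed to the underlying ensemble fit.
#' @return Object of class `q_heatmap`: `lattice` (long data frame x, y, q),
#'   `contours` (list of polylines at levels 2 and 4), `features`,
#'   `guideline_mm` (40), and the fitted `ensemble`.
#' @export
q_heatmap <- function(cohort, features = c("paa_mm", "sov_mm"),
                      resolution = 50, margin = 0.15,
                      grid = nu_grid(), gamma = NULL) {
  stopifnot(length(features) == 2L)
  if (resolution < 2L)
    stop("q_heatmap: 'resolution' must be >= 2 for contours", call. = FALSE)
  data <- as.data.frame(cohort)
  raw <- build_feature_frame(data, features, age_policy())
  raw <- raw[stats::complete.cases(raw), , drop = FALSE]
  if (nrow(raw) < 50L)
    stop("q_heatmap: need >= 50 complete records", call. = FALSE)
  norm <- fit_normalization(raw)
  x_norm <- apply_normalization(norm, raw)
  if (is.null(gamma))
    gamma <- default_gamma(x_norm)
  ensemble <- structure(list(
    scope = "pair", level = NULL, features = features, normalization = norm,
    grid = grid, age_policy = age_policy(), gamma = gamma,
    n_train = nrow(raw),
    machines = fit_ocsvm_grid(x_norm, grid, gamma)
  ), class = "qscore_ensemble")
  pad <- function(r) diff(r) * margin
  rx <- range(raw[[1]]); ry <- range(raw[[2]])
  xs <- seq(rx[1] - pad(rx), rx[2] + pad(rx), length.out = resolution)
  ys <- seq(ry[1] - pad(ry), ry[2] + pad(ry), length.out = resolution)
  lattice <- expand.grid(xs, ys)
  names(lattice) <- features
  q <- q_score(ensemble, lattice)
  # above-grid points sit just beyond the largest grid percentile so the
  # level sets at 2 and 4 are well defined on the lattice
  zcap <- max(100 * grid$values) + 1
  zmat <- matrix(pmin(q, zcap), nrow = resolution)
  contours <- grDevices::contourLines(xs, ys, zmat, levels = c(2, 4))
  structure(list(
    lattice = data.frame(x = lattice[[1]], y = lattice[[2]], q = q),
    contours = contours, features = features, guideline_mm = 40,
    ensemble = ensemble
  ), class = "q_heatmap")
}

#' @export
print.q_heatmap <- function(x, ...) {
  cat(sprintf("Q-score heatmap over (%s, %s): %d lattice points, %d contour segments\n",
              x$features[1], x$features[2], nrow(x$lattice),
              length(x$contours)))
  cat(sprintf("  flagged (<2%%): %.1f%% of lattice; guideline region: > %g mm\n",
              100 * mean(x$lattice$q < 2), x$guideline_mm))
  invisible(x)
}

#' Serialize / restore a Q-score ensemble as JSON
#'
#' The JSON payload stores the feature order, normalization statistics, nu
#' grid, age policy and, per grid value, the kernel-machine parameters
#' (support vectors, dual coefficients, offset, bandwidth), so a restored
#' ensemble reproduces decision values exactly without refitting.
#'
#' @param ensemble A `qscore_ensemble`.
#' @param path JSON path.
#' @return `path` invisibly (`read_qscore_ensemble`: the ensemble).
#' @export
write_qscore_ensemble <- function(ensemble, path) {
  payload <- list(
    schema = "aortanorm/qscore_ensemble/1",
    scope = ensemble$scope, level = ensemble$level,
    features = ensemble$features,
    normalization = list(features = ensemble$normalization$features,
                         min = as.numeric(ensemble$normalization$min),
                         max = as.numeric(ensemble$normalization$max)),
    grid = ensemble$grid$values,
    age_policy = unclass(ensemble$age_policy),
    gamma = ensemble$gamma, n_train = ensemble$n_train,
    machines = lapply(ensemble$machines, function(m)
      list(nu = m$nu, rho = m$rho, gamma = m$gamma,
           coefs = m$coefs, sv = m$sv,
           train_flag_frac = m$train_flag_frac))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qscore_ensemble
#' @export
read_qscore_ensemble <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "aortanorm/qscore_ensemble/1"))
    stop("read_qscore_ensemble: unrecognized schema in ", path, call. = FALSE)
  norm <- structure(list(features = p$normalization$features,
                         min = stats::setNames(p$normalization$min,
                                               p$normalization$features),
                         max = stats::setNames(p$normalization$max,
                                               p$normalization$features)),
                    class = "normalization_spec")
  machines <- lapply(p$machines, function(m)
    list(nu = m$nu, sv = as.matrix(m$sv), coefs = as.numeric(m$coefs),
         rho = m$rho, gamma = m$gamma, train_flag_frac = m$train_flag_frac))
  structure(list(
    scope = p$scope, level = p$level, features = p$features,
    normalization = norm, grid = nu_grid(p$grid),
    age_policy = do.call(age_policy, as.list(p$age_policy)),
    gamma = p$gamma, n_train = p$n_train, machines = machines
  ), class = "qscore_ensemble")
}
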