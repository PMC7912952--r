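#' Fit a min-max normalization spec
#'
#' Records per-feature training minima and maxima so that features can be
#' mapped affinely into \[0, 1\] on the training cohort. New subjects are
#' deliberately NOT clipped: values outside the training range map outside
#' \[0, 1\], which is exactly the information a novelty detector needs.
#'
#' @param x Numeric matrix or data frame of training features (columns named).
#' @param features Character vector fixing the feature order; defaults to
#'   `colnames(x)`.
#' @return An object of class `normalization_spec` with fields `features`,
#'   `min`, `max`.
#' @export
fit_normalization <- function(x, features = colnames(x)) {
  x <- as.matrix(as.data.frame(x)[, features, drop = FALSE])
  if (nrow(x) < 2L)
    stop("fit_normalization: need at least 2 records", call. = FALSE)
  if (anyNA(x))
    stop("fit_normalization: features must be complete (no NA)", call. = FALSE)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  degenerate <- maxs <= mins
  if (any(degenerate))
    stop("fit_normalization: constant feature(s): ",
         paste(features[degenerate], collapse = ", "), call. = FALSE)
  structure(list(features = features, min = mins, max = maxs),
            class = "normalization_spec")
}

#' Apply (or invert) a normalization spec
#'
#' Maps each feature through `(x - min) / (max - min)` using the training
#' statistics stored in the spec. Values outside the training range pass
#' through the affine map unclipped. `invert_normalization` is the exact
#' inverse.
#'
#' @param spec A [fit_normalization()] result.
#' @param x Matrix or data frame supplying every feature of the spec.
#' @return Numeric matrix in the spec's feature order.
#' @export
apply_normalization <- function(spec, x) {
  x <- as.data.frame(x)
  missing_f <- setdiff(spec$features, names(x))
  if (length(missing_f))
    stop("apply_normalization: record is missing feature(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  x <- as.matrix(x[, spec$features, drop = FALSE])
  if (anyNA(x))
    stop("apply_normalization: features must be complete (no NA)",
         call. = FALSE)
  sweep(sweep(x, 2, spec$min, "-"), 2, spec$max - spec$min, "/")
}

#' @rdname apply_normalization
#' @export
invert_normalization <- function(spec, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(spec$features))
    stop("invert_normalization: column count does not match spec",
         call. = FALSE)
  out <- sweep(sweep(x, 2, spec$max - spec$min, "*"), 2, spec$min, "+")
  colnames(out) <- spec$features
  out
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat("Min-max normalization spec:\n")
  print(data.frame(feature = x$features, min = unname(x$min),
                   max = unname(x$max)), row.names = FALSE)
  invisible(x)
}
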