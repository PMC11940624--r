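#' Radiomic score model
#'
#' A named coefficient map from LASSO-selected features to their
#' weights, plus the penalty that produced it and the ROI scope it was
#' fitted on (\code{radscore1} = tumor-only, \code{radscore2} =
#' tumor+peritumoral). The score is the plain linear combination of the
#' (optionally standardized) feature values -- no intercept: any offset
#' is absorbed by the downstream classifiers.
#'
#' Feature names may be given in canonical or export-mangled form
#' (see [canonical_feature_name()]), so printed coefficient tables can
#' be used directly.
#'
#' @param beta named numeric vector of coefficients (finite).
#' @param lambda the LASSO penalty (NA if external/printed).
#' @param scope \code{"radscore1"} or \code{"radscore2"}.
#' @param center,scale optional named standardization statistics; when
#'   supplied, features are standardized before weighting.
#' @param registry valid feature names to validate against; defaults to
#'   the texture [feature_registry()]. Pass the column names of a
#'   custom feature table when the model is built on one.
#' @return a \code{radscore_model}.
#' @export
radscore_model <- function(beta, lambda = NA_real_,
                           scope = c("radscore1", "radscore2"),
                           center = NULL, scale = NULL,
                           registry = feature_registry()$name) {
  scope <- match.arg(scope)
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    stop("`beta` must be a fully named vector")
  if (any(!is.finite(beta))) stop("coefficients must be finite")
  names(beta) <- canonical_feature_name(names(beta))
  unknown <- setdiff(names(beta), registry)
  if (length(unknown))
    stop("coefficient names not in the feature registry: ",
         paste(unknown, collapse = ", "))
  if (!is.null(center)) names(center) <- canonical_feature_name(names(center))
  if (!is.null(scale)) names(scale) <- canonical_feature_name(names(scale))
  structure(list(beta = beta, lambda = lambda, scope = scope,
                 center = center, scale = scale),
            class = "radscore_model")
}

#' @export
print.radscore_model <- function(x, ...) {
  cat(sprintf("<radscore_model %s, %d features, lambda = %.4g>\n",
              x$scope, length(x$beta), x$lambda))
  print(round(x$beta, 4))
  invisible(x)
}

#' Compute Rad-Scores
#'
#' \eqn{\mathrm{RadScore} = \sum_i \beta_i \tilde x_i}, where
#' \eqn{\tilde x} is the feature value, standardized with the model's
#' statistics when present. Linear in the features; no intercept.
#' Every model feature must be present in the input (by canonical
#' name); a missing feature is an error naming it.
#'
#' @param x named numeric vector, or a matrix / data.frame with named
#'   columns (one score per row).
#' @param model a [radscore_model()].
#' @return numeric scalar or vector of scores.
#' @export
rad_score <- function(x, model) {
  stopifnot(inherits(model, "radscore_model"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (is.null(colnames(x))) stop("feature values must be named")
  colnames(x) <- canonical_feature_name(colnames(x))
  missing <- setdiff(names(model$beta), colnames(x))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "))
  xv <- x[, names(model$beta), drop = FALSE]
  if (!is.null(model$center))
    xv <- sweep(xv, 2, model$center[names(model$beta)], "-")
  if (!is.null(model$scale))
    xv <- sweep(xv, 2, model$scale[names(model$beta)], "/")
  as.numeric(xv %*% model$beta)
}
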