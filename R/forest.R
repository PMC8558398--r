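#' Train a random-forest segment classifier
#'
#' Bootstrapped ensemble of CART trees grown to full splits (unlimited
#' depth, Gini criterion, `mtry = floor(sqrt(p))` candidate features per
#' node).  Implemented inside the package with its own Mersenne-Twister
#' stream, so a fixed seed reproduces the forest bit-identically across
#' platforms.
#'
#' @param x Numeric feature matrix with column names (the schema).
#' @param y Binary labels: 1 = ictal, 0 = non-ictal.
#' @param n_trees Number of trees (500 by default).
#' @param mtry Candidate features per split; default `floor(sqrt(ncol(x)))`.
#' @param seed Integer training seed.
#' @return An object of class `remi_forest`.
#' @export
rf_train <- function(x, y, n_trees = 500, mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x must have column names (feature schema)")
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training error: both classes must be present")
  }
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- rf_train_cpp(x, y, as.integer(n_trees), as.integer(mtry), as.integer(seed))
  structure(
    list(
      trees = fit$trees, inbag = fit$inbag, feature_names = colnames(x),
      n_trees = as.integer(n_trees), mtry = as.integer(mtry),
      seed = as.integer(seed)
    ),
    class = "remi_forest"
  )
}

#' Out-of-bag likelihoods for the training rows
#'
#' Each training row is scored only by the trees whose bootstrap sample
#' excluded it, giving honest (out-of-sample-like) likelihoods for data the
#' forest was trained on.  Used when calibrating the detection threshold on
#' training subjects.
#'
#' @param model A [rf_train()] forest.
#' @param x The training feature matrix, rows aligned with training order.
#' @return Numeric vector of out-of-bag ictal likelihoods.
#' @export
rf_predict_oob <- function(model, x) {
  stopifnot(inherits(model, "remi_forest"))
  x <- as.matrix(x)
  if (nrow(x) != nrow(model$inbag)) {
    stop("x must be the training matrix (row count mismatch)")
  }
  x <- x[, model$feature_names, drop = FALSE]
  p <- rf_predict_oob_cpp(model$trees, x, model$inbag)
  # a row in-bag for every tree has no OOB votes; fall back to the ensemble
  if (anyNA(p)) p[is.na(p)] <- rf_predict_cpp(model$trees, x[is.na(p), , drop = FALSE])
  p
}

#' Ictal class likelihood from a trained forest
#'
#' Columns are matched by name to the training schema (order-independent);
#' the likelihood is the fraction of trees voting ictal, in `[0, 1]`.
#'
#' @param model A [rf_train()] forest.
#' @param x Feature matrix with named columns covering the training schema.
#' @return Numeric vector of likelihoods, one per row of `x`.
#' @export
rf_predict <- function(model, x) {
  stopifnot(inherits(model, "remi_forest"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature error: x must have column names")
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing)) {
    stop(
      "feature error: missing features: ",
      paste(utils::head(missing, 10), collapse = ", "),
      if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10)
    )
  }
  x <- x[, model$feature_names, drop = FALSE]
  rf_predict_cpp(model$trees, x)
}

#' @export
print.remi_forest <- function(x, ...) {
  cat(sprintf(
    "<remi_forest> %d trees, %d features, mtry %d, seed %d\n",
    x$n_trees, length(x$feature_names), x$mtry, x$seed
  ))
  invisible(x)
}
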