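#' Activity class order
#'
#' Fixed order of the activity classes, also used to break exact decision
#' ties (standing < walking < running).
#'
#' @return Character vector of the three class names.
#' @export
activity_levels <- function() c("standing", "walking", "running")

#' Train a one-against-all RBF-kernel SVM activity classifier
#'
#' Fits one binary support-vector machine per activity class (target vs
#' rest), each with a radial-basis-function kernel on features standardised
#' with training statistics.  Prediction takes the class whose machine has
#' the maximal signed decision value.
#'
#' @param x Feature matrix (rows = frame pairs, columns = velocity features,
#'   possibly PCA-reduced).
#' @param labels Per-row activity labels (character or factor with values in
#'   [activity_levels()]).
#' @param cost Soft-margin regularisation parameter C (default 1).
#' @param gamma RBF width; default `1 / (n_features * mean feature variance)`
#'   computed on the standardised features (i.e. `1 / n_features`).
#' @param seed Integer seed (training is deterministic; the seed fixes any
#'   library-internal ordering).
#' @return An object of class `activity_classifier` holding one binary
#'   machine per class present in `labels`.
#' @export
train_activity_classifier <- function(x, labels, cost = 1, gamma = NULL,
                                      seed = 1) {
  x <- unclass(as.matrix(x))
  if (!all(is.finite(x))) {
    stop("features must be finite (no NaN/NA)", call. = FALSE)
  }
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) {
    stop("rows and labels must be aligned", call. = FALSE)
  }
  classes <- intersect(activity_levels(), unique(labels))
  if (length(classes) < 2L) {
    stop("training needs at least 2 classes", call. = FALSE)
  }
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  if (is.null(gamma)) gamma <- 1 / (ncol(xs) * mean(apply(xs, 2, stats::var)))
  machines <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "target", "rest"),
                levels = c("target", "rest"))
    fit <- with_seed(split_seed(seed, "svm", cl),
      e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                 cost = cost, gamma = gamma, scale = FALSE))
    # e1071 orients decision values towards the class met first in the data;
    # record the orientation so "larger = more target-like" always holds.
    dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
               "decision.values")[, 1]
    flip <- mean(dv[y == "target"]) < mean(dv[y == "rest"])
    list(fit = fit, sign = if (flip) -1 else 1)
  })
  names(machines) <- classes
  structure(list(machines = machines, scaler = scaler, classes = classes,
                 cost = cost, gamma = gamma),
            class = "activity_classifier")
}

#' Classify feature rows into activities
#'
#' @param model An [train_activity_classifier()] fit.
#' @param x Feature matrix with the training dimensionality.
#' @return Factor of predicted labels with levels [activity_levels()].
#'   Exact decision-value ties are broken by the fixed class order, with a
#'   warning.
#' @export
classify_activity <- function(model, x) {
  if (!inherits(model, "activity_classifier")) {
    stop("`model` must come from train_activity_classifier()", call. = FALSE)
  }
  x <- unclass(as.matrix(x))
  if (ncol(x) != length(model$scaler$center)) {
    stop(sprintf("feature count %d does not match training (%d)",
                 ncol(x), length(model$scaler$center)), call. = FALSE)
  }
  xs <- apply_scaler(model$scaler, x)
  dv <- vapply(model$machines, function(m) {
    m$sign * attr(stats::predict(m$fit, xs, decision.values = TRUE),
                  "decision.values")[, 1]
  }, numeric(nrow(xs)))
  dv <- matrix(dv, nrow = nrow(xs),
               dimnames = list(NULL, names(model$machines)))
  best <- max.col(dv, ties.method = "first")
  n_ties <- sum(apply(dv, 1L, function(r) sum(r == max(r)) > 1L))
  if (n_ties > 0) {
    warning(sprintf("%d exact decision-value tie(s) broken by class order",
                    n_ties), call. = FALSE)
  }
  factor(colnames(dv)[best], levels = activity_levels())
}

#' Classification accuracy
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction of matching labels in `[0, 1]`.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (!length(truth)) stop("empty input", call. = FALSE)
  mean(as.character(predicted) == as.character(truth))
}

#' Bout-level label by majority vote
#'
#' @param predicted Per-row predicted labels for one bout.
#' @return The most frequent label (ties broken by [activity_levels()]
#'   order).
#' @export
majority_label <- function(predicted) {
  predicted <- factor(as.character(predicted), levels = activity_levels())
  tab <- table(predicted)
  names(tab)[which.max(tab)]
}
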