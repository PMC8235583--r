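#' Default activity-to-model routing
#'
#' The classify-then-route configuration that minimised per-activity error:
#' standing is scored by the CNN on the rear view, walking by the CNN on the
#' side view, and running by the MLP on the rear view; the classifier reads
#' the side view (the view with the best classification accuracy).  All of
#' this is configurable.
#'
#' @return A data frame with columns `activity`, `view`, `family`.
#' @export
default_routing <- function() {
  data.frame(activity = c("standing", "walking", "running"),
             view = c("rear", "side", "rear"),
             family = c("cnn", "cnn", "mlp"),
             stringsAsFactors = FALSE)
}

#' Build a registry of activity-specific MET models
#'
#' Trains one regressor per routing row on the rows of that activity, using
#' the features of the routed camera view.
#'
#' @param features_by_view Named list `view -> feature matrix`; matrices must
#'   have aligned rows (the same frames seen from each view).
#' @param meta Data frame with per-row `activity` and `met` columns.
#' @param routing Routing table as from [default_routing()].
#' @param classifier_view View whose features feed the activity classifier.
#' @param seed Integer seed.
#' @param nn_args List of extra arguments for [train_mlp()]/[train_cnn()]
#'   (e.g. `epochs`).
#' @return An object of class `model_registry`.
#' @export
train_registry <- function(features_by_view, meta, routing = default_routing(),
                           classifier_view = "side", seed = 1,
                           nn_args = list()) {
  models <- list()
  for (i in seq_len(nrow(routing))) {
    act <- routing$activity[i]; vw <- routing$view[i]; fam <- routing$family[i]
    if (!vw %in% names(features_by_view)) {
      stop(sprintf("routing needs view '%s' but it is not available", vw),
           call. = FALSE)
    }
    rows <- which(as.character(meta$activity) == act)
    x <- features_by_view[[vw]][rows, , drop = FALSE]
    y <- meta$met[rows]
    model <- switch(fam,
      lr = train_lr(x, y),
      mlp = do.call(train_mlp, c(list(x = x, y = y,
                                      seed = split_seed(seed, "route", act)),
                                 nn_args)),
      cnn = do.call(train_cnn, c(list(x = x, y = y,
                                      seed = split_seed(seed, "route", act)),
                                 nn_args)),
      stop(sprintf("unknown family '%s'", fam), call. = FALSE))
    models[[act]] <- list(view = vw, family = fam, model = model)
  }
  structure(list(models = models, routing = routing,
                 classifier_view = classifier_view),
            class = "model_registry")
}

#' Hierarchical (classify-then-route) MET prediction
#'
#' Each row is first classified into an activity from the classifier view's
#' features, then scored by the registry model routed for that activity, on
#' that model's view.  Routing is a pure dispatch: it selects a model per row
#' but never alters any model's prediction.
#'
#' @param registry A [train_registry()] object.
#' @param classifier An [train_activity_classifier()] fit.
#' @param features_by_view Named list `view -> feature matrix` with aligned
#'   rows, covering the classifier view and every routed view.
#' @return A list with `met` (per-row predictions) and `label` (per-row
#'   classified activity).
#' @export
hierarchical_predict <- function(registry, classifier, features_by_view) {
  if (!inherits(registry, "model_registry")) {
    stop("`registry` must come from train_registry()", call. = FALSE)
  }
  cv <- registry$classifier_view
  if (!cv %in% names(features_by_view)) {
    stop(sprintf("classifier view '%s' missing from features", cv),
         call. = FALSE)
  }
  labels <- classify_activity(classifier, features_by_view[[cv]])
  n <- nrow(features_by_view[[cv]])
  met <- rep(NA_real_, n)
  for (act in unique(as.character(labels))) {
    entry <- registry$models[[act]]
    if (is.null(entry)) {
      stop(sprintf("no model routed for activity '%s'", act), call. = FALSE)
    }
    if (!entry$view %in% names(features_by_view)) {
      stop(sprintf("routed view '%s' missing from features", entry$view),
           call. = FALSE)
    }
    rows <- which(as.character(labels) == act)
    met[rows] <- predict_met(entry$model,
                             features_by_view[[entry$view]][rows, ,
                                                            drop = FALSE])
  }
  list(met = met, label = labels)
}
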