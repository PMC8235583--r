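#' Simulate a full multi-view feature dataset
#'
#' Runs the generator over every subject x bout x view of the protocol and
#' pushes each sequence through the standard preparation chain (re-centre,
#' smooth, steady-state trim, left-joint selection, velocities).  Rows are
#' aligned across views: row `i` of every view's feature matrix is the same
#' frame pair of the same bout, seen from that view.
#'
#' @param protocol A [default_protocol()] object.
#' @param seed Integer root seed.
#' @param discard_min,keep_min Steady-state trim window, minutes.
#' @param max_rows Optional cap on the number of feature rows; rows are
#'   thinned evenly (the same rows in every view).
#' @return A list with `features` (named list `view -> feature matrix`),
#'   `meta` (data frame: `subject_id`, `activity`, `speed`, `timestamp`,
#'   `met`, `weight`) and `cohort`.
#' @export
simulate_dataset <- function(protocol = default_protocol(), seed = 1,
                             discard_min = 3, keep_min = 2, max_rows = Inf) {
  if (!inherits(protocol, "sim_protocol")) {
    stop("`protocol` must come from default_protocol()", call. = FALSE)
  }
  cohort <- sample_cohort(protocol$n_subjects, protocol$cohort, seed)
  view_names <- names(protocol$views)
  feats <- stats::setNames(vector("list", length(view_names)), view_names)
  metas <- list()
  for (s in seq_len(nrow(cohort))) {
    subject <- cohort[s, , drop = FALSE]
    for (bout in protocol$bouts) {
      per_view <- lapply(protocol$views, function(vw) {
        generate_sequence(subject, bout, vw, protocol$motion, seed,
                          protocol$met)
      })
      fm <- lapply(per_view, function(g) {
        joint_velocities(select_joints(preprocess_sequence(
          g$sequence, discard_min = discard_min, keep_min = keep_min)))
      })
      for (v in view_names) feats[[v]] <- c(feats[[v]], list(fm[[v]]))
      f1 <- fm[[1]]
      metas[[length(metas) + 1L]] <- data.frame(
        subject_id = subject$subject_id, activity = bout$activity,
        speed = bout$speed, timestamp = attr(f1, "timestamps"),
        met = met_targets_for(f1, per_view[[1]]$met),
        weight = subject$weight, stringsAsFactors = FALSE)
    }
  }
  features <- lapply(feats, function(lst) do.call(rbind, lst))
  meta <- do.call(rbind, metas)
  meta$activity <- factor(meta$activity, levels = activity_levels())
  rownames(meta) <- NULL
  n <- nrow(meta)
  if (is.finite(max_rows) && n > max_rows) {
    keep <- unique(round(seq(1, n, length.out = max_rows)))
    features <- lapply(features, function(m) m[keep, , drop = FALSE])
    meta <- meta[keep, , drop = FALSE]
    rownames(meta) <- NULL
  }
  list(features = features, meta = meta, cohort = cohort)
}

#' Experiment configuration
#'
#' Describes a full evaluation run: which camera views, regressor families
#' and PCA settings to cross over, the cross-validation depth, and the
#' simulation protocol supplying the data.
#'
#' @param protocol A [default_protocol()] object.
#' @param views Views to evaluate (subset of the protocol's views).
#' @param families Regressor families to evaluate.
#' @param pca Logical vector of PCA settings to run (e.g.
#'   `c(FALSE, TRUE)`).
#' @param folds Cross-validation folds (default 10, >= 2).
#' @param seed Integer root seed.
#' @param discard_min,keep_min Steady-state trim window, minutes.
#' @param max_rows Row cap passed to [simulate_dataset()].
#' @param nn_args Extra arguments for the neural trainers (e.g. `epochs`).
#' @param routing Routing table for the hierarchical stage.
#' @param general_view,general_family The single-camera general model used as
#'   the hierarchical stage's comparator (default: MLP on the side view).
#' @param test_fraction Held-out fraction for the hierarchical comparison.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(protocol = default_protocol(),
                              views = names(protocol$views),
                              families = c("lr", "mlp", "cnn"),
                              pca = c(FALSE, TRUE), folds = 10, seed = 1,
                              discard_min = 3, keep_min = 2, max_rows = Inf,
                              nn_args = list(), routing = default_routing(),
                              general_view = "side", general_family = "mlp",
                              test_fraction = 0.3) {
  stop_if_not_number(folds, "folds", min = 2)
  if (!length(views) || !length(families)) {
    stop("at least one view and one family are required", call. = FALSE)
  }
  structure(list(protocol = protocol, views = views, families = families,
                 pca = pca, folds = folds, seed = seed,
                 discard_min = discard_min, keep_min = keep_min,
                 max_rows = max_rows, nn_args = nn_args, routing = routing,
                 general_view = general_view,
                 general_family = general_family,
                 test_fraction = test_fraction),
            class = "experiment_config")
}

#' Run the full evaluation grid
#'
#' Produces the four report stages of the evaluation design:
#' (i) general-model error per view x family x PCA setting, (ii) activity
#' classification accuracy per view x PCA setting, (iii) per-activity error
#' per activity x view x family, and (iv) the hierarchical
#' (classify-then-route) vs general comparison on a held-out split.  Every
#' emitted error report passes [validate_report()].
#'
#' @param config An [experiment_config()].
#' @param dataset Optionally a pre-built [simulate_dataset()] result (or a
#'   user-supplied list with the same shape); simulated from the config's
#'   protocol otherwise.
#' @param stages Which stages to run (subset of `"general"`,
#'   `"classification"`, `"per_activity"`, `"hierarchical"`).
#' @return A list with elements `general`, `classification`, `per_activity`,
#'   `hierarchical` (those requested) plus `config`.
#' @export
run_experiment <- function(config = experiment_config(), dataset = NULL,
                           stages = c("general", "classification",
                                      "per_activity", "hierarchical")) {
  if (!inherits(config, "experiment_config")) {
    stop("`config` must come from experiment_config()", call. = FALSE)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(dataset)) {
    dataset <- simulate_dataset(config$protocol, config$seed,
                                config$discard_min, config$keep_min,
                                config$max_rows)
  }
  missing_views <- setdiff(config$views, names(dataset$features))
  if (length(missing_views)) {
    stop(sprintf("no data for requested view(s): %s",
                 paste(missing_views, collapse = ", ")), call. = FALSE)
  }
  meta <- dataset$meta
  out <- list(config = config)

  if ("general" %in% stages) {
    rows <- list()
    for (vw in config$views) for (fam in config$families)
      for (p in config$pca) {
        # the CNN architecture is fixed to 18 inputs, so its with-PCA cell
        # zero-pads the reduced features back to full width
        pl <- do.call(met_pipeline,
                      c(list(family = fam, use_pca = p,
                             pad_pca = fam == "cnn" && p,
                             seed = split_seed(config$seed, "gen", vw, fam)),
                        config$nn_args))
        rows[[length(rows) + 1L]] <- kfold_cv(
          dataset$features[[vw]], meta$met, pl, k = config$folds,
          seed = config$seed, stratify = meta$activity, view = vw,
          family = fam, activity = "general", pca = p)
      }
    out$general <- validate_report(do.call(rbind, rows))
  }

  if ("classification" %in% stages) {
    rows <- list()
    for (vw in config$views) for (p in config$pca) {
      acc <- kfold_classification(dataset$features[[vw]], meta$activity,
                                  k = config$folds, seed = config$seed,
                                  use_pca = p)
      rows[[length(rows) + 1L]] <- data.frame(view = vw, pca = p,
                                              accuracy = as.numeric(acc))
    }
    out$classification <- do.call(rbind, rows)
  }

  if ("per_activity" %in% stages) {
    rows <- list()
    for (act in levels(meta$activity)) {
      sel <- meta$activity == act
      for (vw in config$views) for (fam in config$families) {
        pl <- do.call(met_pipeline,
                      c(list(family = fam, use_pca = FALSE,
                             seed = split_seed(config$seed, "act", act, vw,
                                               fam)),
                        config$nn_args))
        rows[[length(rows) + 1L]] <- kfold_cv(
          dataset$features[[vw]][sel, , drop = FALSE], meta$met[sel], pl,
          k = config$folds, seed = config$seed, view = vw, family = fam,
          activity = act, pca = FALSE)
      }
    }
    out$per_activity <- validate_report(do.call(rbind, rows))
  }

  if ("hierarchical" %in% stages) {
    out$hierarchical <- hierarchical_comparison(dataset, config)
  }
  out
}

# Held-out comparison of the classify-then-route system against the
# single-camera general model, per true activity.
hierarchical_comparison <- function(dataset, config) {
  meta <- dataset$meta
  n <- nrow(meta)
  folds <- make_folds(n, k = max(2L, round(1 / config$test_fraction)),
                      seed = split_seed(config$seed, "holdout"),
                      stratify = meta$activity)
  test <- folds == 1L
  tr_feats <- lapply(dataset$features, function(m) m[!test, , drop = FALSE])
  te_feats <- lapply(dataset$features, function(m) m[test, , drop = FALSE])
  mtr <- meta[!test, , drop = FALSE]; mte <- meta[test, , drop = FALSE]

  cview <- if ("side" %in% names(tr_feats)) "side" else names(tr_feats)[1]
  classifier <- train_activity_classifier(
    tr_feats[[cview]], mtr$activity,
    seed = split_seed(config$seed, "clf"))
  registry <- train_registry(tr_feats, mtr, config$routing,
                             classifier_view = cview,
                             seed = config$seed, nn_args = config$nn_args)
  hier <- hierarchical_predict(registry, classifier, te_feats)

  gen_pl <- do.call(met_pipeline,
                    c(list(family = config$general_family, use_pca = FALSE,
                           seed = split_seed(config$seed, "general_model")),
                      config$nn_args))
  gen_fit <- gen_pl$fit(tr_feats[[config$general_view]], mtr$met)
  gen_pred <- gen_pl$predict(gen_fit, te_feats[[config$general_view]])

  rows <- lapply(levels(mte$activity), function(act) {
    sel <- mte$activity == act
    data.frame(activity = act,
               rmse_hierarchical = rmse(hier$met[sel], mte$met[sel]),
               rmse_general = rmse(gen_pred[sel], mte$met[sel]),
               n = sum(sel), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "classifier_accuracy") <-
    classification_accuracy(hier$label, mte$activity)
  res
}

#' Render, save and reload report tables
#'
#' `render_table()` formats a report as an aligned plain-text table with
#' 2-decimal rounding (machine-readable CSVs keep full precision);
#' `write_report()`/`read_report()` round-trip a report through CSV.
#'
#' @param report A metrics report data frame.
#' @param digits Decimal places for rendering.
#' @return `render_table()`: a character vector of lines.
#' @export
render_table <- function(report, digits = 2) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n"
  df[num] <- lapply(df[num], function(v) sprintf(paste0("%.", digits, "f"), v))
  utils::capture.output(print(df, row.names = FALSE))
}

#' @rdname render_table
#' @param path File path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname render_table
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  class(df) <- c("metrics_report", "data.frame")
  df
}
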