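#' The six left-side joints used for feature extraction
#'
#' Treadmill activities are periodic and approximately left-right symmetric,
#' so the pipeline analyses only the left-side shoulder, elbow, wrist, hip,
#' knee and ankle, in this fixed order.
#'
#' @return Character vector of 6 joint names.
#' @export
left_joints <- function() {
  c("shoulder_left", "elbow_left", "wrist_left",
    "hip_left", "knee_left", "ankle_left")
}

#' Restrict a sequence to the selected joints
#'
#' @param x A [skeleton_sequence()].
#' @param joints Joints to keep, in the order they should appear
#'   (default [left_joints()]).
#' @return The `skeleton_sequence` restricted to `joints`.  Idempotent when
#'   the sequence already holds exactly these joints.
#' @export
select_joints <- function(x, joints = left_joints()) {
  if (!inherits(x, "skeleton_sequence")) {
    stop("`x` must be a skeleton_sequence", call. = FALSE)
  }
  missing <- setdiff(joints, joint_names(x))
  if (length(missing)) {
    stop(sprintf("sequence lacks joint(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x$coords <- x$coords[, joints, , drop = FALSE]
  x
}

#' Per-frame joint velocities
#'
#' The velocity feature of frame `k` is the finite difference of consecutive
#' smoothed positions divided by the actual timestamp gap,
#' `(p*_k - p*_(k-1)) / (t_k - t_(k-1))`, per joint and axis.  A sequence of
#' `N` frames yields `N - 1` feature rows; with the six selected joints each
#' row has 18 columns ordered joint-major as
#' `<joint>_vx, <joint>_vy, <joint>_vz`.
#'
#' @param x A [skeleton_sequence()] with at least 2 frames.
#' @return A numeric matrix of class `feature_matrix` (m/s) with attributes
#'   `timestamps` (the later frame of each pair), `view`, `subject_id`,
#'   `activity` and `speed` copied from the sequence.
#' @export
joint_velocities <- function(x) {
  if (!inherits(x, "skeleton_sequence")) {
    stop("`x` must be a skeleton_sequence", call. = FALSE)
  }
  n <- n_frames(x)
  if (n < 2L) stop("velocities need at least 2 frames", call. = FALSE)
  dt <- diff(x$timestamps)
  if (any(dt <= 0)) {
    stop("duplicate or non-increasing timestamps: cannot divide by a zero time step",
         call. = FALSE)
  }
  joints <- joint_names(x)
  flat <- matrix(aperm(x$coords, c(1L, 3L, 2L)), nrow = n)  # cols: (x,y,z) per joint
  v <- diff(flat) / dt
  colnames(v) <- as.vector(t(outer(joints, c("vx", "vy", "vz"), paste,
                                   sep = "_")))
  structure(v, class = c("feature_matrix", class(v)),
            timestamps = x$timestamps[-1], view = x$view,
            subject_id = x$subject_id, activity = x$activity, speed = x$speed)
}

#' Number of principal components needed to reach a variance threshold
#'
#' @param explained Vector of explained-variance ratios (non-negative,
#'   summing to 1 over all components).
#' @param threshold Cumulative variance to reach (default 0.90).
#' @return The smallest `m` whose first `m` ratios sum to at least
#'   `threshold`.
#' @export
pca_retained_count <- function(explained, threshold = 0.90) {
  if (!length(explained) || any(explained < -1e-12)) {
    stop("`explained` must be non-negative ratios", call. = FALSE)
  }
  cum <- cumsum(explained) / sum(explained)
  which(cum >= threshold - 1e-12)[1]
}

#' Fit a principal-component reduction on training features
#'
#' Fits PCA on the training rows and retains the smallest number of leading
#' components whose cumulative explained variance reaches
#' `variance_threshold`.  Always fit on training folds only and applied to
#' held-out rows with [apply_pca()], so no test statistics leak into the
#' transform.
#'
#' @param x A feature matrix (rows = frames, columns = velocity features).
#' @param variance_threshold Cumulative explained-variance target
#'   (default 0.90).
#' @param center,scale. Passed to [stats::prcomp()]; the pipeline
#'   standardises features beforehand, so the default only centres.
#' @return An object of class `pca_transform` with elements `rotation`
#'   (p x m loadings), `explained` (all p ratios), `retained`, `center`,
#'   `scale`.
#' @export
fit_pca <- function(x, variance_threshold = 0.90, center = TRUE,
                    scale. = FALSE) {
  x <- unclass(as.matrix(x))
  if (nrow(x) < 2L || ncol(x) < 1L) {
    stop("PCA needs at least 2 rows and 1 column", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  p <- stats::prcomp(x, center = center, scale. = scale.)
  tot <- sum(p$sdev^2)
  if (tot < .Machine$double.eps) {
    stop("zero-variance input: no component explains any variance",
         call. = FALSE)
  }
  explained <- p$sdev^2 / tot
  m <- pca_retained_count(explained, variance_threshold)
  structure(
    list(rotation = p$rotation[, seq_len(m), drop = FALSE],
         explained = explained, retained = m,
         center = if (isTRUE(center)) p$center else rep(0, ncol(x)),
         scale = if (isTRUE(scale.)) p$scale else rep(1, ncol(x)),
         threshold = variance_threshold, n_features = ncol(x)),
    class = "pca_transform")
}

#' @rdname fit_pca
#' @param transform A `pca_transform` from `fit_pca()`.
#' @return `apply_pca()`: the rows of `x` projected onto the retained
#'   components (`retained` columns).
#' @export
apply_pca <- function(transform, x) {
  if (!inherits(transform, "pca_transform")) {
    stop("`transform` must come from fit_pca()", call. = FALSE)
  }
  x <- unclass(as.matrix(x))
  if (ncol(x) != transform$n_features) {
    stop(sprintf("feature count %d does not match the fitted space (%d)",
                 ncol(x), transform$n_features), call. = FALSE)
  }
  xc <- sweep(sweep(x, 2L, transform$center, "-"), 2L, transform$scale, "/")
  out <- xc %*% transform$rotation
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}

#' Serialise a PCA transform as JSON
#'
#' @param transform A `pca_transform`.
#' @param path File path.
#' @export
write_pca_json <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = transform$rotation, explained = transform$explained,
         retained = transform$retained, center = transform$center,
         scale = transform$scale, threshold = transform$threshold,
         n_features = transform$n_features),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(rotation = matrix(obj$rotation, ncol = obj$retained),
         explained = as.numeric(obj$explained),
         retained = as.integer(obj$retained),
         center = as.numeric(obj$center), scale = as.numeric(obj$scale),
         threshold = obj$threshold, n_features = as.integer(obj$n_features)),
    class = "pca_transform")
}

#' Align a MET trace with feature rows
#'
#' Ground-truth METs arrive per breath; features arrive per frame pair.  Each
#' feature row takes the most recent breath value at or before its timestamp
#' (previous-value step interpolation; the first breath value is used for any
#' earlier frames).
#'
#' @param features A `feature_matrix` (or a numeric vector of timestamps).
#' @param trace A [met_trace()].
#' @return Numeric vector of MET targets, one per feature row.
#' @export
met_targets_for <- function(features, trace) {
  t <- if (is.numeric(features) && is.null(dim(features))) features
       else attr(features, "timestamps")
  if (is.null(t)) {
    stop("`features` must carry timestamps (or be a timestamp vector)",
         call. = FALSE)
  }
  if (nrow(trace) == 1L) return(rep(trace$met, length(t)))
  stats::approx(trace$timestamp_s, trace$met, xout = t, method = "constant",
                rule = 2)$y
}
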