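#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derived from a root seed and a path of labels.
# Streams are keyed by content (subject id, activity, speed, view), so adding
# a bout or view never perturbs the stream of an existing one.
split_seed <- function(seed, ...) {
  parts <- paste(c(format(seed), vapply(list(...), format, character(1))),
                 collapse = "/")
  h <- 0
  for (cp in utf8ToInt(parts)) h <- (h * 31 + cp) %% 2147483629
  as.integer(h)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_if_not_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

# Column-wise standardisation statistics fitted on training data only.
fit_scaler <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}
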