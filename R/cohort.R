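#' Cohort anthropometric parameters
#'
#' Means and standard deviations of the simulated cohort's anthropometrics,
#' defaulting to a young-adult treadmill cohort of 21 subjects (10 men,
#' 11 women; weight 60.20 +/- 7.60 kg, age 21.90 +/- 1.55 y, body fat
#' 20.69 +/- 7.37 %).  Field distributions are normals truncated at broad
#' physiological bounds.
#'
#' @param weight_mean,weight_sd Body mass, kg.
#' @param age_mean,age_sd Age, years.
#' @param body_fat_mean,body_fat_sd Body-fat percentage.
#' @param male_fraction Fraction of male subjects (default 10/21).
#' @param weight_bounds,age_bounds,body_fat_bounds Truncation bounds for the
#'   respective fields.
#'
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(weight_mean = 60.20, weight_sd = 7.60,
                          age_mean = 21.90, age_sd = 1.55,
                          body_fat_mean = 20.69, body_fat_sd = 7.37,
                          male_fraction = 10 / 21,
                          weight_bounds = c(35, 150),
                          age_bounds = c(16, 90),
                          body_fat_bounds = c(3, 60)) {
  for (nm in c("weight_sd", "age_sd", "body_fat_sd")) {
    stop_if_not_number(get(nm), nm, min = 0)
  }
  if (male_fraction < 0 || male_fraction > 1) {
    stop("`male_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(weight_mean = weight_mean, weight_sd = weight_sd,
         age_mean = age_mean, age_sd = age_sd,
         body_fat_mean = body_fat_mean, body_fat_sd = body_fat_sd,
         male_fraction = male_fraction,
         weight_bounds = weight_bounds, age_bounds = age_bounds,
         body_fat_bounds = body_fat_bounds),
    class = "cohort_params")
}

# Truncated-normal draws by vectorised rejection; with sd = 0 the mean is
# returned (the mean must lie inside the bounds).
rtruncnorm <- function(n, mean, sd, bounds) {
  if (mean < bounds[1] || mean > bounds[2]) {
    stop("distribution mean lies outside its truncation bounds", call. = FALSE)
  }
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < bounds[1] | x > bounds[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < bounds[1] | x[bad] > bounds[2]]
  }
  x
}

#' Sample a subject cohort
#'
#' Draws `n` subject profiles from the truncated-normal field distributions in
#' `params`.  Deterministic for a fixed seed.
#'
#' @param n Number of subjects (>= 1).
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#' @param sex Optional explicit character vector of length `n` with values
#'   `"male"`/`"female"`; by default the split is the rounded
#'   `male_fraction` (10 M / 11 F at the defaults with `n = 21`).
#'
#' @return A data frame with columns `subject_id`, `sex`, `age`, `weight`
#'   (kg) and `body_fat` (%), one row per subject.
#' @export
sample_cohort <- function(n, params = cohort_params(), seed = 1, sex = NULL) {
  stop_if_not_number(n, "n", min = 1)
  if (!inherits(params, "cohort_params")) {
    stop("`params` must come from cohort_params()", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.null(sex)) {
    n_male <- round(n * params$male_fraction)
    sex <- rep(c("male", "female"), c(n_male, n - n_male))
  }
  if (length(sex) != n || !all(sex %in% c("male", "female"))) {
    stop("`sex` must be length n with values 'male'/'female'", call. = FALSE)
  }
  with_seed(split_seed(seed, "cohort"), {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = sex,
      age = rtruncnorm(n, params$age_mean, params$age_sd, params$age_bounds),
      weight = rtruncnorm(n, params$weight_mean, params$weight_sd,
                          params$weight_bounds),
      body_fat = rtruncnorm(n, params$body_fat_mean, params$body_fat_sd,
                            params$body_fat_bounds),
      stringsAsFactors = FALSE)
  })
}
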