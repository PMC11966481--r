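#' Simulation configuration for a synthetic regional cohort
#'
#' Defines a two-group cohort with a planted per-region standardized
#' effect pattern, additive age/sex covariate effects, Gaussian regional
#' noise, and case-only severity ratings correlated with each case's
#' expression of the planted pattern. Scalars are recycled across
#' regions.
#'
#' The generative model for subject i, region j is
#' \deqn{x_{ij} = \mu_j + \beta^{age}_j age_i + \beta^{sex}_j sex_i +
#'       dx_i d_j \sigma_j + \epsilon_{ij}, \epsilon_{ij} \sim N(0, \sigma_j^2)}
#' with ages Uniform(20, 70) (cases optionally shifted by
#' `age_shift_cases` to create confounding) and sex Bernoulli(0.5)
#' coded 0/1.
#'
#' @param n_cases,n_controls Group sizes (each >= 2).
#' @param region_count Number of regions (default 34 bilateral regions).
#' @param planted_d Per-region standardized case-control effect
#'   (case - control; deficits negative).
#' @param beta_age Per-region age slope (measure units per year).
#' @param beta_sex Per-region sex offset (measure units).
#' @param region_mean,region_sd Per-region noise mean and SD (SD > 0).
#' @param severity_link Target correlation between case severity and the
#'   case's pattern-expression burden, in \[-1, 1\].
#' @param age_shift_cases Years added to case ages (0 = no confounding).
#' @param region_names Optional region column names.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases, n_controls, region_count = 34L,
                       planted_d = 0, beta_age = 0, beta_sex = 0,
                       region_mean = 0, region_sd = 1,
                       severity_link = 0.4, age_shift_cases = 0,
                       region_names = NULL, seed = 1L) {
  region_count <- as.integer(region_count)
  rc <- function(v) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- rep(v, region_count)
    if (length(v) != region_count)
      stop("per-region parameter has length ", length(v),
           ", expected 1 or ", region_count)
    v
  }
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              region_count = region_count,
              planted_d = rc(planted_d), beta_age = rc(beta_age),
              beta_sex = rc(beta_sex), region_mean = rc(region_mean),
              region_sd = rc(region_sd), severity_link = severity_link,
              age_shift_cases = as.numeric(age_shift_cases),
              region_names = region_names %||%
                sprintf("region_%02d", seq_len(region_count)),
              seed = as.integer(seed))
  if (cfg$n_cases < 2L || cfg$n_controls < 2L)
    stop("need at least 2 cases and 2 controls")
  if (any(cfg$region_sd <= 0)) stop("region_sd must be strictly positive")
  if (!all(is.finite(cfg$planted_d))) stop("planted_d must be finite")
  if (abs(severity_link) > 1) stop("severity_link must lie in [-1, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate a regional cohort with a planted deficit pattern
#'
#' Draws the cohort described by a [sim_config]: covariates, diagnosis,
#' regional measures with the planted standardized effect, and case-only
#' severity ratings. Severity is a noisy linear (hence monotone)
#' function of each case's pattern burden
#' \eqn{b_i = \sum_j d_j z_{ij}} (z computed against the generative
#' mean/SD), standardized and mixed with Gaussian noise to hit the
#' configured burden-severity correlation, then mapped to a rating-like
#' scale (20 + 8 z). Controls get missing severity.
#'
#' @param config A [sim_config].
#' @return A [regional_table].
#' @export
simulate_regional_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases + config$n_controls
  R <- config$region_count
  withr::with_seed(config$seed, {
    dx <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
    age <- stats::runif(n, 20, 70) + dx * config$age_shift_cases
    sex <- stats::rbinom(n, 1L, 0.5)
    eps <- matrix(stats::rnorm(n * R), n, R) %*% diag(config$region_sd, R)
    x <- matrix(config$region_mean, n, R, byrow = TRUE) +
      outer(age, config$beta_age) + outer(sex, config$beta_sex) +
      outer(dx, config$planted_d * config$region_sd) + eps
    colnames(x) <- config$region_names

    # pattern-expression burden per case, against the generative reference
    mu0 <- matrix(config$region_mean, n, R, byrow = TRUE) +
      outer(age, config$beta_age) + outer(sex, config$beta_sex)
    z <- sweep(x - mu0, 2L, config$region_sd, "/")
    burden <- as.numeric(z %*% config$planted_d)
    severity <- rep(NA_real_, n)
    case <- which(dx == 1L)
    rho <- config$severity_link
    b <- burden[case]
    bstd <- if (stats::sd(b) > 0) (b - mean(b)) / stats::sd(b) else rep(0, length(b))
    severity[case] <- 20 + 8 * (rho * bstd +
                                  sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(case)))
  })
  subjects <- data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                         age = age, sex = sex, dx = dx, severity = severity,
                         stringsAsFactors = FALSE)
  regional_table(subjects, x, measure_name = "synthetic")
}

#' Simulate 4-D BOLD-like data with controllable local coherence
#'
#' Each voxel time series in region j is
#' \eqn{\sqrt{c_j} s_j(t) + \sqrt{1 - c_j} e_v(t)}, scaled by
#' `noise_sd`, where \eqn{s_j} is a region-shared standard Gaussian
#' signal and \eqn{e_v} is voxel-private standard Gaussian noise; the
#' coherence \eqn{c_j \in [0, 1)} therefore sets the pairwise temporal
#' correlation of neighboring voxels (0 = independent). Background
#' voxels get independent noise and the mask is `atlas > 0`.
#'
#' @param atlas A [parcellation_atlas].
#' @param n_timepoints Number of time points (>= 10).
#' @param coherence Scalar or per-region coherence in \[0, 1).
#' @param noise_sd Positive scale of the series.
#' @param voxel_dims Voxel dimensions in mm.
#' @param seed Integer seed.
#' @return A [volume_time_series].
#' @export
simulate_bold <- function(atlas, n_timepoints, coherence = 0.3,
                          noise_sd = 1, voxel_dims = c(2, 2, 2), seed = 1L) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  R <- nrow(atlas$regions)
  if (length(coherence) == 1L) coherence <- rep(coherence, R)
  if (length(coherence) != R)
    stop("coherence must be a scalar or one value per region")
  if (any(coherence < 0 | coherence >= 1))
    stop("coherence must lie in [0, 1)")
  dims <- dim(atlas$labels)
  Tn <- as.integer(n_timepoints)
  lab <- as.integer(atlas$labels)
  withr::with_seed(as.integer(seed), {
    dat <- matrix(stats::rnorm(prod(dims) * Tn), prod(dims), Tn)
    shared <- matrix(stats::rnorm(R * Tn), R, Tn)
    for (k in seq_len(R)) {
      id <- atlas$regions$id[k]
      v <- which(lab == id)
      cj <- coherence[k]
      if (cj > 0 && length(v))
        dat[v, ] <- sqrt(cj) * matrix(shared[k, ], length(v), Tn, byrow = TRUE) +
          sqrt(1 - cj) * dat[v, , drop = FALSE]
    }
  })
  dat <- noise_sd * dat
  volume_time_series(array(dat, c(dims, Tn)),
                     mask = array(lab > 0L, dims),
                     voxel_dims = voxel_dims)
}
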