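#' Simulate design-of-experiments responses from a known surface
#'
#' Evaluates a full second-order polynomial (the "truth") at every run of a
#' coded design and adds independent Gaussian noise. Coefficients are given
#' as a named vector using the same term labels as [fit_surface()]
#' coefficients — `"(Intercept)"`, `"x1"`, `"x1:x2"`, `"I(x1^2)"`, ... —
#' so a noise-free simulation is recovered exactly by fitting the
#' second-order class. Unnamed terms default to 0.
#'
#' @param design A `doe_design`, data frame, or matrix of coded settings
#'   (columns are renamed `x1..xk`).
#' @param coefficients Named numeric vector of true coefficients.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Seed; identical seeds give identical tables.
#' @param response Name of the generated response column.
#' @return Data frame with the coded columns plus the response.
#' @examples
#' d <- ccd_design(list(factor_spec("a", center = 0, step = 1),
#'                      factor_spec("b", center = 0, step = 1)))
#' sim_doe_responses(d, c("(Intercept)" = 150, x1 = 20, "I(x1^2)" = 10),
#'                   noise_sd = 2, seed = 1)
#' @export
sim_doe_responses <- function(design, coefficients, noise_sd = 0,
                              seed = NULL, response = "y") {
  m <- as_coded_matrix(design)
  k <- ncol(m)
  dat <- as.data.frame(m)
  names(dat) <- paste0("x", seq_len(k))
  X <- stats::model.matrix(
    stats::reformulate(rsm_terms("second_order", names(dat))), dat)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(coefficients), names(beta))
  if (length(unknown))
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  beta[names(coefficients)] <- coefficients
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dat[[response]] <- as.vector(X %*% beta) +
    stats::rnorm(nrow(dat), sd = noise_sd)
  dat
}

#' Simulate a release curve from the Crank sphere model
#'
#' Generates replicate release profiles from [release_fraction()] plus
#' Gaussian noise, clipped to \[0, 1.05\]. Defaults mirror a 24-h dialysis
#' release study read in sextuplicate with a membrane-induced lag.
#'
#' @param K,t_lag True model parameters (h^-1, h).
#' @param times Sampling times in hours.
#' @param noise_sd Noise SD on the fraction scale.
#' @param n_rep Number of replicate profiles.
#' @param seed Seed; identical seeds give identical curves.
#' @param label,initial_mass Passed to [release_curve()].
#' @return A [release_curve()].
#' @export
sim_release_curve <- function(K = 0.033, t_lag = 0.2,
                              times = c(0.25, 0.5, 1, 2, 3, 4, 6, 8, 24),
                              noise_sd = 0.02, n_rep = 6, seed = NULL,
                              label = "simulated", initial_mass = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  truth <- release_fraction(times, K, t_lag)
  f <- matrix(truth, length(times), n_rep) +
    matrix(stats::rnorm(length(times) * n_rep, sd = noise_sd),
           length(times), n_rep)
  f <- pmin(pmax(f, 0), 1.05)
  release_curve(times, f, label = label, initial_mass = initial_mass)
}

#' Simulate replicate measurements
#'
#' Seeded Gaussian draws around a true mean, e.g. to emulate triplicate
#' size / PDI / Z-potential readings.
#'
#' @param mean,sd True mean and standard deviation (sd >= 0).
#' @param n Number of replicates.
#' @param seed Seed.
#' @return Numeric vector of length `n`.
#' @export
sim_replicates <- function(mean, sd, n, seed = NULL) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean, sd)
}
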