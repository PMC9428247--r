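#' Construct a release curve
#'
#' Container for an in-vitro release profile: sampling times (hours) and the
#' cumulative fraction released `M_t / M_inf` per replicate. Percent input
#' (values above 1.5) is detected and divided by 100. A small experimental
#' overshoot above 1 (up to 1.05) is tolerated.
#'
#' @param times Sampling times in hours, strictly increasing, >= 0.
#' @param fractions Numeric vector (single profile) or matrix / data frame
#'   with one column per replicate.
#' @param label Optional curve label.
#' @param initial_mass Optional initial drug mass (mg); informational only —
#'   fractional release from the diffusion model is dose-independent.
#' @return Object of class `release_curve`.
#' @export
release_curve <- function(times, fractions, label = "",
                          initial_mass = NULL) {
  times <- as.numeric(times)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  f <- as.matrix(fractions)
  if (nrow(f) != length(times))
    stop("fractions must have one row per time point", call. = FALSE)
  if (max(f, na.rm = TRUE) > 1.5) f <- f / 100   # percent input
  if (any(f < -1e-9) || any(f > 1.05 + 1e-9))
    stop("fractions must lie in [0, 1.05]", call. = FALSE)
  fbar <- rowMeans(f)
  if (any(diff(fbar) < -0.1))
    warning("mean release profile decreases by more than the noise ",
            "tolerance", call. = FALSE)
  structure(list(times = times, fractions = f, mean_fraction = fbar,
                 label = label, initial_mass = initial_mass,
                 n_replicates = ncol(f)),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve%s: %d time points, %d replicate(s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), x$n_replicates))
  print(data.frame(time_h = x$times, mean_fraction = round(x$mean_fraction, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Crank monolithic-sphere release model
#'
#' Diffusion-controlled release from a sphere with uniformly dispersed drug,
#' parameterized by the rate constant `K` (per hour) and a lag time (hours)
#' applied as a time shift: nothing is released before `t_lag`.
#'
#' @param K Rate constant, h^-1, > 0.
#' @param t_lag Lag time, h, >= 0 (default 0).
#' @return Object of class `crank_model`.
#' @export
crank_model <- function(K, t_lag = 0) {
  if (!(K > 0)) stop("K must be positive", call. = FALSE)
  if (t_lag < 0) stop("t_lag must be non-negative", call. = FALSE)
  structure(list(K = K, t_lag = t_lag), class = "crank_model")
}

#' @export
print.crank_model <- function(x, ...) {
  cat(sprintf("Crank sphere model: K = %.4g /h, lag = %.3g h\n",
              x$K, x$t_lag))
  invisible(x)
}

#' Early- and late-time release fractions
#'
#' `release_early()` is the early-time approximation
#' `F = 6 sqrt(K tau / pi) - 3 K tau` (valid up to about 40 percent released);
#' `release_late()` is the late-time approximation
#' `F = 1 - (6/pi^2) exp(-pi^2 K tau)` (valid from about 60 percent released);
#' both with the shifted time `tau = max(t - t_lag, 0)`.
#' `release_fraction()` joins them continuously: pure early branch while the
#' early expression is below 0.4 (its validity bound), pure late branch once
#' it exceeds 0.6, and a linear blend of the two across the gap. (A hard
#' switch cannot be used: the two approximations never cross, the late branch
#' sitting about 0.05 above the early one at mid-release, so any abrupt
#' change of branch would put a visible step in the curve.)
#'
#' Each branch result carries a logical `valid` attribute flagging the points
#' inside its own validity range.
#'
#' @param t Times, hours.
#' @param K Rate constant h^-1, or a [crank_model()] (then `t_lag` is taken
#'   from it).
#' @param t_lag Lag time, hours.
#' @return Fractions released; `release_early`/`release_late` attach a
#'   `valid` attribute.
#' @examples
#' release_fraction(c(0.5, 2, 8), K = 0.033, t_lag = 0.2)
#' @export
release_early <- function(t, K, t_lag = 0) {
  if (inherits(K, "crank_model")) { t_lag <- K$t_lag; K <- K$K }
  tau <- pmax(t - t_lag, 0)
  f <- 6 * sqrt(K * tau / pi) - 3 * K * tau
  attr(f, "valid") <- f <= 0.4
  f
}

#' @rdname release_early
#' @export
release_late <- function(t, K, t_lag = 0) {
  if (inherits(K, "crank_model")) { t_lag <- K$t_lag; K <- K$K }
  tau <- pmax(t - t_lag, 0)
  f <- 1 - (6 / pi^2) * exp(-pi^2 * K * tau)
  attr(f, "valid") <- f >= 0.6
  f
}

# reduced time x = K*tau at which the (rising) early branch reaches
# fraction f: solve 6 sqrt(x/pi) - 3x = f for the smaller root
crank_early_x <- function(f) {
  u <- (6 - sqrt(36 - 12 * pi * f)) / (6 * pi)
  pi * u^2
}
.crank_x_lo <- crank_early_x(0.4)   # early branch valid below this
.crank_x_hi <- crank_early_x(0.6)   # late branch used above this

#' @rdname release_early
#' @export
release_fraction <- function(t, K, t_lag = 0) {
  if (inherits(K, "crank_model")) { t_lag <- K$t_lag; K <- K$K }
  x <- K * pmax(t - t_lag, 0)
  e <- as.numeric(release_early(t, K, t_lag))
  l <- as.numeric(release_late(t, K, t_lag))
  w <- pmin(1, pmax(0, (x - .crank_x_lo) / (.crank_x_hi - .crank_x_lo)))
  (1 - w) * e + w * l
}

#' Late-time estimate of the release rate constant
#'
#' Linearizes the late-time branch: over points with mean fraction at or
#' above `threshold` (and below 1), `log(1 - F)` is linear in `t` with slope
#' `-pi^2 K`, so `K` is estimated as `-slope / pi^2` by least squares.
#' Replicates are averaged before the linearization. A lag time does not
#' affect the slope, so this estimate is valid with or without lag.
#'
#' The regression is weighted by `(1 - F)^2`, the delta-method variance
#' factor of the log transform: with additive noise on the fraction scale,
#' the scatter of `log(1 - F)` blows up as `F` approaches 1, and unweighted
#' least squares would let near-complete-release points dominate the slope.
#' The weights are immaterial for noise-free data.
#'
#' @param curve A [release_curve()].
#' @param threshold Minimum mean fraction for a point to qualify
#'   (default 0.6).
#' @param from_time Optionally also require `t >= from_time` hours.
#' @return Estimated `K` (h^-1).
#' @export
fit_release_late <- function(curve, threshold = 0.6, from_time = NULL) {
  stopifnot(inherits(curve, "release_curve"))
  fbar <- curve$mean_fraction
  sel <- fbar >= threshold & fbar < 1
  if (!is.null(from_time)) sel <- sel & curve$times >= from_time
  if (sum(sel) < 2)
    stop("insufficient data: fewer than 2 points at or above the ",
         threshold, " release threshold", call. = FALSE)
  slope <- stats::coef(stats::lm(log(1 - fbar[sel]) ~ curve$times[sel],
                                 weights = (1 - fbar[sel])^2))[2]
  K <- -unname(slope) / pi^2
  if (K <= 0) stop("fit failure: non-positive rate constant", call. = FALSE)
  K
}

#' Fit the Crank sphere model with lag time
#'
#' Two-stage procedure: (1) `K` from the late-time linearization
#' ([fit_release_late()]); (2) lag time by least squares of the piecewise
#' model against all observed points with `K` held fixed, searched over
#' `[0, first sampling time]`. With `joint = TRUE` a third stage refines
#' `(K, t_lag)` jointly by Nelder-Mead. R-squared and MSE are reported over
#' all observed points (every replicate).
#'
#' @inheritParams fit_release_late
#' @param joint Jointly refine `(K, t_lag)` after the two stages?
#' @return Object of class `release_fit`: `model` ([crank_model()]),
#'   `r_squared`, `mse`, `points_used` (late-time indices), `threshold`,
#'   `joint`.
#' @examples
#' cv <- sim_release_curve(K = 0.033, t_lag = 0.2, noise_sd = 0, n_rep = 1)
#' fit_release(cv)$model
#' @export
fit_release <- function(curve, threshold = 0.6, from_time = NULL,
                        joint = FALSE) {
  stopifnot(inherits(curve, "release_curve"))
  K <- fit_release_late(curve, threshold, from_time)
  obs <- as.vector(curve$fractions)
  tt <- rep(curve$times, times = ncol(curve$fractions))
  sse <- function(K., tl) sum((obs - release_fraction(tt, K., tl))^2)
  lag_hi <- min(curve$times)
  t_lag <- stats::optimize(function(tl) sse(K, tl), c(0, lag_hi))$minimum
  # a boundary solution at ~0 is genuinely 0 lag
  if (sse(K, 0) <= sse(K, t_lag) + 1e-12) t_lag <- 0
  if (joint) {
    pen <- function(par) {
      if (par[1] <= 0 || par[2] < 0 || par[2] > lag_hi) return(Inf)
      sse(par[1], par[2])
    }
    ref <- nelder_mead(pen, c(K, max(t_lag, 1e-3)), step = 0.05)
    if (is.finite(ref$value) && ref$value <= sse(K, t_lag)) {
      K <- ref$par[1]
      t_lag <- max(ref$par[2], 0)
    }
  }
  res <- sse(K, t_lag)
  fbar <- curve$mean_fraction
  structure(list(model = crank_model(K, t_lag),
                 r_squared = 1 - res / sum((obs - mean(obs))^2),
                 mse = res / length(obs),
                 points_used = which(fbar >= threshold & fbar < 1),
                 threshold = threshold, joint = joint),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  R2 = %.3f, MSE = %.4g (%d late-time points, threshold %g)\n",
              x$r_squared, x$mse, length(x$points_used), x$threshold))
  invisible(x)
}

#' Pointwise difference between two release profiles
#'
#' Interpolates the mean profiles of two curves linearly onto the shared part
#' of their time grids and reports the pointwise difference
#' (reference - test) in percentage points of drug released.
#'
#' @param test,reference [release_curve()] objects.
#' @return List with `table` (time, reference and test percentages, difference in
#'   percentage points) and `max_difference_pct`.
#' @export
profile_difference <- function(test, reference) {
  stopifnot(inherits(test, "release_curve"),
            inherits(reference, "release_curve"))
  lo <- max(min(test$times), min(reference$times))
  hi <- min(max(test$times), max(reference$times))
  if (lo > hi) stop("no overlap between the two time ranges", call. = FALSE)
  grid <- sort(unique(c(test$times, reference$times)))
  grid <- grid[grid >= lo & grid <= hi]
  ft <- stats::approx(test$times, test$mean_fraction, grid)$y
  fr <- stats::approx(reference$times, reference$mean_fraction, grid)$y
  tab <- data.frame(time_h = grid, reference_pct = 100 * fr,
                    test_pct = 100 * ft,
                    difference_pct = 100 * (fr - ft))
  list(table = tab, max_difference_pct = max(tab$difference_pct))
}
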