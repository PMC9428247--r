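#' Smaller-is-better desirability
#'
#' Derringer-Suich transform for a response that should be minimized:
#' `d = 1` at or below `low`, `d = 0` at or above `high`, and
#' `d = ((high - y)/(high - low))^scale` in between.
#'
#' @param y Response value(s).
#' @param low Fully desirable bound (d = 1 at or below).
#' @param high Unacceptable bound (d = 0 at or above); must exceed `low`.
#' @param scale Shape exponent `s > 0` (1 = linear).
#' @return Desirability value(s) in \[0, 1\].
#' @examples
#' d_smaller(c(140, 180, 220), low = 144.2, high = 219.2)
#' @export
d_smaller <- function(y, low, high, scale = 1) {
  if (!(high > low)) stop("high must exceed low", call. = FALSE)
  if (!(scale > 0)) stop("scale must be positive", call. = FALSE)
  d <- pmin(1, pmax(0, (high - y) / (high - low)))^scale
  d[y <= low] <- 1
  d[y >= high] <- 0
  d
}

#' Desirability specifications for a set of responses
#'
#' `desirability_spec()` builds one smaller-is-better specification;
#' `specs_from_data()` derives the bounds from the observed range of each
#' response column (the default convention of this package), and
#' `specs_from_surfaces()` from the range of the fitted surfaces over a fine
#' grid of the coded design region.
#'
#' @param response Response name.
#' @param low,high,scale As in [d_smaller()].
#' @return A `desirability_spec`, or a named list of them.
#' @export
desirability_spec <- function(response, low, high, scale = 1) {
  if (!(high > low)) stop("high must exceed low", call. = FALSE)
  if (!(scale > 0)) stop("scale must be positive", call. = FALSE)
  structure(list(response = response, low = low, high = high, scale = scale),
            class = "desirability_spec")
}

#' @rdname desirability_spec
#' @param data Data frame of observed responses.
#' @param responses Response column names.
#' @export
specs_from_data <- function(data, responses, scale = 1) {
  out <- lapply(responses, function(r)
    desirability_spec(r, min(data[[r]]), max(data[[r]]), scale))
  names(out) <- responses
  out
}

#' @rdname desirability_spec
#' @param surfaces Named list of [fit_surface()] objects.
#' @param radius Coded radius of the design region (default sqrt(2)).
#' @param n_grid Grid resolution per axis.
#' @export
specs_from_surfaces <- function(surfaces, radius = sqrt(2), n_grid = 201,
                                scale = 1) {
  grid <- region_grid(surfaces[[1]]$coded_cols, radius, n_grid)
  out <- lapply(surfaces, function(s) {
    p <- predict(s, grid)
    desirability_spec(s$response, min(p), max(p), scale)
  })
  names(out) <- vapply(surfaces, `[[`, "", "response")
  out
}

# grid of coded points covering the disk of given radius (k = 2) or the
# hypercube [-radius, radius]^k filtered to the ball for k > 2
region_grid <- function(coded_cols, radius, n_grid = 201) {
  k <- length(coded_cols)
  ax <- seq(-radius, radius, length.out = n_grid)
  g <- as.matrix(expand.grid(rep(list(ax), k)))
  g <- g[rowSums(g^2) <= radius^2 + 1e-12, , drop = FALSE]
  g <- as.data.frame(g)
  names(g) <- coded_cols
  g
}

#' Overall (composite) desirability at coded points
#'
#' Evaluates every fitted surface at the given coded point(s), converts each
#' prediction with its smaller-is-better specification, and combines them as
#' the geometric mean `D = (d_1 ... d_m)^(1/m)`.
#'
#' @param points Numeric vector (one point) or data frame / matrix of coded
#'   coordinates.
#' @param surfaces Named list of [fit_surface()] objects (names = responses).
#' @param specs Named list of [desirability_spec()]s covering the same
#'   responses.
#' @return Numeric vector of overall desirabilities in \[0, 1\].
#' @export
overall_desirability <- function(points, surfaces, specs) {
  resp <- vapply(surfaces, `[[`, "", "response")
  if (!setequal(resp, vapply(specs, `[[`, "", "response")))
    stop("configuration error: surfaces and specs cover different responses",
         call. = FALSE)
  if (is.numeric(points) && is.null(dim(points))) {
    points <- as.data.frame(as.list(points))
    names(points) <- surfaces[[1]]$coded_cols
  }
  points <- as.data.frame(points)
  specs <- specs[resp]
  d <- matrix(NA_real_, nrow(points), length(surfaces))
  for (i in seq_along(surfaces)) {
    sp <- specs[[i]]
    d[, i] <- d_smaller(predict(surfaces[[i]], points), sp$low, sp$high,
                        sp$scale)
  }
  apply(d, 1, function(row) prod(row)^(1 / length(row)))
}

#' Nelder-Mead simplex minimizer
#'
#' Derivative-free simplex search with the standard reflection, expansion,
#' contraction and shrink coefficients (1, 2, 0.5, 0.5). Converges when the
#' simplex diameter drops below `tol` or after `maxit` iterations.
#'
#' @param fn Objective function of a numeric vector, to be minimized.
#' @param x0 Starting point.
#' @param step Initial simplex edge length (default 0.25).
#' @param tol Simplex-size convergence tolerance (default 1e-8).
#' @param maxit Iteration cap (default 500).
#' @return List with `par`, `value`, `iterations`, `converged`.
#' @examples
#' nelder_mead(function(x) sum((x - c(1, 2))^2), c(0, 0))$par
#' @export
nelder_mead <- function(fn, x0, step = 0.25, tol = 1e-8, maxit = 500) {
  n <- length(x0)
  simplex <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) simplex[i + 1, i] <- simplex[i + 1, i] + step
  fv <- apply(simplex, 1, fn)
  a <- 1; g <- 2; r <- 0.5; s <- 0.5   # reflect / expand / contract / shrink
  iter <- 0
  repeat {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    size <- max(sqrt(rowSums((simplex[-1, , drop = FALSE] -
                              matrix(simplex[1, ], n, n, byrow = TRUE))^2)))
    if (size < tol || iter >= maxit) break
    iter <- iter + 1
    cen <- colMeans(simplex[seq_len(n), , drop = FALSE])
    xr <- cen + a * (cen - simplex[n + 1, ])
    fr <- fn(xr)
    if (fr < fv[1]) {
      xe <- cen + g * (xr - cen)
      fe <- fn(xe)
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xc <- if (fr < fv[n + 1]) cen + r * (xr - cen)
            else cen + r * (simplex[n + 1, ] - cen)
      fc <- fn(xc)
      if (fc < min(fr, fv[n + 1])) {
        simplex[n + 1, ] <- xc; fv[n + 1] <- fc
      } else {
        for (i in 2:(n + 1))
          simplex[i, ] <- simplex[1, ] + s * (simplex[i, ] - simplex[1, ])
        fv[-1] <- apply(simplex[-1, , drop = FALSE], 1, fn)
      }
    }
  }
  list(par = simplex[1, ], value = fv[1], iterations = iter,
       converged = iter < maxit)
}

#' Maximize the overall desirability over the design region
#'
#' Multi-start Nelder-Mead maximization of the composite desirability. Starts
#' are the design points of the first surface's data plus seeded random
#' points inside the region; points outside the region are penalized to
#' `D = 0`. The region is either a coded disk (`list(type = "disk",
#' radius = r)`, the CCD's support) or a box (`list(type = "box", lower = ...,
#' upper = ...)`).
#'
#' @inheritParams overall_desirability
#' @param region Design region; default the coded disk of radius sqrt(2).
#' @param n_random Number of random extra starts (default 10).
#' @param seed Seed for the random starts.
#' @param factors Optional list of [factor_spec()] to decode the optimum to
#'   natural units.
#' @param tol,maxit Nelder-Mead controls.
#' @return Object of class `desirability_opt`: `optimum_coded`,
#'   `optimum_natural` (if `factors` given), `individual_d`, `overall_D`,
#'   and the per-start `trace`.
#' @export
maximize_desirability <- function(surfaces, specs,
                                  region = list(type = "disk",
                                                radius = sqrt(2)),
                                  n_random = 10, seed = NULL, factors = NULL,
                                  tol = 1e-8, maxit = 500) {
  coded_cols <- surfaces[[1]]$coded_cols
  k <- length(coded_cols)
  inside <- function(x) {
    if (identical(region$type, "disk")) sum(x^2) <= region$radius^2 + 1e-12
    else all(x >= region$lower - 1e-12) && all(x <= region$upper + 1e-12)
  }
  Dfun <- function(x) {
    if (!inside(x)) return(0)
    overall_desirability(x, surfaces, specs)
  }
  starts <- unique(as.matrix(surfaces[[1]]$data[coded_cols]))
  starts <- starts[apply(starts, 1, inside), , drop = FALSE]
  if (n_random > 0) {
    if (!is.null(seed)) set.seed(seed)
    rnd <- matrix(NA_real_, n_random, k)
    for (i in seq_len(n_random)) {
      repeat {
        x <- if (identical(region$type, "disk"))
          stats::runif(k, -region$radius, region$radius)
        else stats::runif(k, region$lower, region$upper)
        if (inside(x)) break
      }
      rnd[i, ] <- x
    }
    starts <- rbind(starts, rnd)
  }
  res <- lapply(seq_len(nrow(starts)), function(i)
    nelder_mead(function(x) -Dfun(x), starts[i, ], tol = tol, maxit = maxit))
  vals <- -vapply(res, `[[`, 0, "value")
  if (all(vals <= 0))
    warning("flat desirability: every start collapsed to D = 0; ",
            "inspect the bounds with overall_desirability() on a grid",
            call. = FALSE)
  best <- res[[which.max(vals)]]
  opt <- best$par
  names(opt) <- coded_cols
  resp <- vapply(surfaces, `[[`, "", "response")
  ind <- vapply(seq_along(surfaces), function(i) {
    sp <- specs[resp][[i]]
    d_smaller(predict(surfaces[[i]], opt), sp$low, sp$high, sp$scale)
  }, 0)
  names(ind) <- resp
  trace <- data.frame(start = seq_len(nrow(starts)), D = vals,
                      iterations = vapply(res, `[[`, 0, "iterations"))
  structure(list(optimum_coded = opt,
                 optimum_natural = if (!is.null(factors))
                   to_natural(matrix(opt, 1), factors) else NULL,
                 individual_d = ind, overall_D = max(vals),
                 region = region, trace = trace),
            class = "desirability_opt")
}

#' @export
print.desirability_opt <- function(x, ...) {
  cat(sprintf("Overall desirability D = %.4f at coded (%s)\n", x$overall_D,
              paste(signif(x$optimum_coded, 4), collapse = ", ")))
  if (!is.null(x$optimum_natural)) {
    cat("  natural units: ")
    cat(paste(names(x$optimum_natural),
              signif(unlist(x$optimum_natural), 6), collapse = ", "), "\n")
  }
  cat("  individual d:",
      paste(names(x$individual_d), round(x$individual_d, 3),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
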