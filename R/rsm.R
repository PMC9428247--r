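#' @rdname fit_surface
#' @export
rsm_model_classes <- c("first_order", "first_order_interactions",
                       "pure_quadratic", "second_order")

# term labels on coded variables for one model class
rsm_terms <- function(model_class, vars) {
  k <- length(vars)
  two_fi <- if (k >= 2)
    apply(utils::combn(vars, 2), 2, paste, collapse = ":") else character(0)
  squares <- paste0("I(", vars, "^2)")
  switch(model_class,
         first_order = vars,
         first_order_interactions = c(vars, two_fi),
         pure_quadratic = c(vars, squares),
         second_order = c(vars, two_fi, squares),
         stop("unknown model class '", model_class, "'", call. = FALSE))
}

find_coded_cols <- function(data, coded_cols) {
  if (!is.null(coded_cols)) return(coded_cols)
  cc <- grep("^x[0-9]+$", names(data), value = TRUE)
  if (!length(cc))
    stop("no coded columns found (expected names like x1, x2); ",
         "use the coded_cols argument", call. = FALSE)
  cc
}

#' Fit a response-surface model on coded variables
#'
#' Ordinary least squares fit of one of four nested polynomial model classes
#' to a response over a coded design: first-order, first-order with two-factor
#' interactions, pure quadratic (linear + squared terms), or full second-order.
#' Fitting is always on coded variables; decode for display with
#' [to_natural()].
#'
#' @param data Data frame holding coded factor columns and the response.
#' @param response Name of the response column.
#' @param model_class One of `"first_order"`, `"first_order_interactions"`,
#'   `"pure_quadratic"`, `"second_order"`.
#' @param coded_cols Names of the coded factor columns; defaults to all
#'   columns named `x1`, `x2`, ...
#' @return Object of class `rsm_surface` wrapping the `lm` fit, with
#'   `coefficients`, `r_squared`, `adj_r_squared`, `residual_sd`, `n_params`
#'   and the coded design radius.
#' @seealso [select_model()], [predict.rsm_surface()]
#' @export
fit_surface <- function(data, response,
                        model_class = c("second_order", "pure_quadratic",
                                        "first_order_interactions",
                                        "first_order"),
                        coded_cols = NULL) {
  model_class <- match.arg(model_class)
  coded_cols <- find_coded_cols(data, coded_cols)
  if (!response %in% names(data))
    stop("response column '", response, "' not found", call. = FALSE)
  terms <- rsm_terms(model_class, coded_cols)
  n_params <- length(terms) + 1L
  if (nrow(data) <= n_params)
    stop("not enough runs (", nrow(data), ") for ", n_params,
         " parameters", call. = FALSE)
  fml <- stats::reformulate(terms, response = response)
  fit <- stats::lm(fml, data = data)
  if (fit$rank < n_params)
    stop("rank error: design cannot estimate the ", model_class,
         " model", call. = FALSE)
  # noise-free interpolation is legitimate here; silence summary.lm's
  # perfect-fit caveat only
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  radius <- sqrt(max(rowSums(as.matrix(data[coded_cols])^2)))
  structure(list(fit = fit, model_class = model_class, response = response,
                 coded_cols = coded_cols, coefficients = stats::coef(fit),
                 r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 residual_sd = s$sigma, n_params = n_params,
                 design_radius = radius, data = data),
            class = "rsm_surface")
}

#' @export
print.rsm_surface <- function(x, ...) {
  cat(sprintf("Response surface for '%s' (%s): R2 = %.4f, adj R2 = %.4f, s = %.4g\n",
              x$response, x$model_class, x$r_squared, x$adj_r_squared,
              x$residual_sd))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Select the best-fitting response-surface model class
#'
#' Fits all four nested classes and keeps the one with the highest adjusted
#' R-squared; exact ties go to the class with fewer parameters. The ordinary
#' R-squared is reported alongside. (The four classes are nested, so ordinary
#' R-squared alone would always pick the full second-order model; the adjusted
#' criterion penalizes parameters that do not earn their keep.)
#'
#' @inheritParams fit_surface
#' @return Object of class `rsm_selection`: `model_class`, `surface` (the
#'   winning [fit_surface()] object), and `candidates` (per-class R-squared
#'   table).
#' @export
select_model <- function(data, response, coded_cols = NULL) {
  fits <- lapply(rsm_model_classes, function(cl)
    fit_surface(data, response, cl, coded_cols))
  names(fits) <- rsm_model_classes
  cand <- data.frame(
    model_class = rsm_model_classes,
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    adj_r_squared = vapply(fits, `[[`, 0, "adj_r_squared"),
    row.names = NULL)
  crit <- cand$adj_r_squared
  best <- which(crit > max(crit) - 1e-10)
  best <- best[which.min(cand$n_params[best])]
  structure(list(model_class = rsm_model_classes[best],
                 surface = fits[[best]], candidates = cand),
            class = "rsm_selection")
}

#' @export
print.rsm_selection <- function(x, ...) {
  cat("Model selection for '", x$surface$response, "':\n", sep = "")
  print(transform(x$candidates, r_squared = round(r_squared, 4),
                  adj_r_squared = round(adj_r_squared, 4)),
        row.names = FALSE)
  cat("Selected:", x$model_class, "\n")
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' Evaluates the fitted surface at new coded points. With `se = TRUE` the
#' standard error for a *new observation* is returned,
#' `s_pred = residual_sd * sqrt(1 + leverage)`, together with the relative
#' prediction error `rsd_pred_pct = 100 * s_pred / |fit|`. Points outside the
#' coded design region trigger an extrapolation warning, not an error.
#'
#' @param object An `rsm_surface`.
#' @param newdata Data frame with the coded columns, or a numeric vector for
#'   a single point.
#' @param se Return prediction standard errors? Default `FALSE`.
#' @param ... Unused.
#' @return Numeric vector of predictions, or (with `se = TRUE`) a data frame
#'   with columns `fit`, `s_pred`, `rsd_pred_pct`.
#' @export
predict.rsm_surface <- function(object, newdata, se = FALSE, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
    names(newdata) <- object$coded_cols
  }
  newdata <- as.data.frame(newdata)
  r <- sqrt(max(rowSums(as.matrix(newdata[object$coded_cols])^2)))
  if (r > object$design_radius + 1e-8)
    warning("prediction outside the coded design region (radius ",
            signif(r, 4), " > ", signif(object$design_radius, 4), ")",
            call. = FALSE)
  if (!se) return(unname(stats::predict(object$fit, newdata)))
  p <- stats::predict(object$fit, newdata, se.fit = TRUE)
  s_pred <- sqrt(p$se.fit^2 + object$residual_sd^2)
  data.frame(fit = unname(p$fit), s_pred = unname(s_pred),
             rsd_pred_pct = unname(100 * s_pred / abs(p$fit)))
}
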