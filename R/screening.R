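#' Estimate factor effects from a two-level design
#'
#' For each coded -1/+1 factor column the effect is the mean response at the
#' high level minus the mean at the low level; the regression coefficient on
#' the coded scale is half the effect. Requires a balanced design (equal
#' numbers of runs at each level of every factor).
#'
#' @param design A `doe_design`, data frame, or matrix of coded -1/+1
#'   settings.
#' @param response Numeric vector, one value per run.
#' @return Data frame with columns `factor`, `effect`, `coefficient`.
#' @examples
#' d <- ffd_design(5, 1)
#' y <- 100 + 20 * d$runs$X1 + rnorm(16)
#' estimate_effects(d, y)
#' @export
estimate_effects <- function(design, response) {
  m <- as_coded_matrix(design)
  if (!all(m %in% c(-1, 1)))
    stop("design must be two-level coded -1/+1", call. = FALSE)
  if (length(response) != nrow(m))
    stop("need one response value per run", call. = FALSE)
  if (any(colSums(m) != 0))
    stop("balance error: unequal numbers of runs at the two levels",
         call. = FALSE)
  eff <- vapply(seq_len(ncol(m)), function(j)
    mean(response[m[, j] == 1]) - mean(response[m[, j] == -1]), 0)
  data.frame(factor = colnames(m), effect = eff, coefficient = eff / 2,
             row.names = NULL)
}

#' Main-effects ANOVA for factor screening
#'
#' Decomposes the response variation of a balanced two-level design into one
#' single-degree-of-freedom sum of squares per main effect plus a residual,
#' and selects the factors whose F test falls below the significance level.
#' The sums of squares are computed from the orthogonal contrasts
#' (`SS_j = n * coefficient_j^2`), which for these designs equals the
#' sequential regression sum of squares in any fitting order.
#'
#' @inheritParams estimate_effects
#' @param alpha Significance level for factor selection (default 0.01).
#' @return Object of class `screening_anova`: `table` (factor, effect,
#'   coefficient, sum_sq, df, F, p_value), `residual` (ss, df), `total_ss`,
#'   `alpha`, and `selected` (names of significant factors).
#' @examples
#' d <- ffd_design(5, 1)
#' y <- 100 + 20 * d$runs$X1 + rnorm(16, sd = 5)
#' screen_anova(d, y)
#' @export
screen_anova <- function(design, response, alpha = 0.01) {
  eff <- estimate_effects(design, response)
  m <- as_coded_matrix(design)
  n <- nrow(m)
  k <- ncol(m)
  df_res <- n - 1L - k
  if (df_res < 1)
    stop("saturated model: no residual degrees of freedom; pool ",
         "negligible terms before testing", call. = FALSE)
  ss_fac <- n * eff$coefficient^2
  ss_tot <- sum((response - mean(response))^2)
  ss_res <- ss_tot - sum(ss_fac)
  ms_res <- ss_res / df_res
  Fval <- ss_fac / ms_res
  pval <- stats::pf(Fval, 1, df_res, lower.tail = FALSE)
  tab <- cbind(eff, data.frame(sum_sq = ss_fac, df = 1L, F = Fval,
                               p_value = pval))
  structure(list(table = tab,
                 residual = list(ss = ss_res, df = df_res),
                 total_ss = ss_tot, alpha = alpha,
                 selected = tab$factor[tab$p_value < alpha]),
            class = "screening_anova")
}

#' @export
print.screening_anova <- function(x, ...) {
  cat("Main-effects screening ANOVA\n")
  tab <- x$table
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: SS = %.4g on %d df\n", x$residual$ss,
              x$residual$df))
  cat(sprintf("Selected at alpha = %g: %s\n", x$alpha,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  invisible(x)
}
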