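#' Specify a process factor
#'
#' A factor specification holds the natural-unit levels of one process factor
#' and the coding convention used to map it onto the dimensionless coded scale.
#' Two-level screening factors are given as `low`/`high` (coded -1/+1); central
#' composite factors are given as `center`/`step`, so that a coded value `x`
#' corresponds to the natural value `center + x * step`.
#'
#' @param name Factor name (e.g. `"X1"` or `"lipid"`).
#' @param low,high Natural-unit levels mapped to coded -1 and +1. Optional if
#'   `center` and `step` are supplied.
#' @param center,step Center point and step (half-range) of the coding.
#'   Optional if `low` and `high` are supplied.
#' @param unit Unit label (mg, ul, min, percent), kept for display only.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("lipid", center = 500, step = 250, unit = "mg")
#' factor_spec("X1", low = 100, high = 400, unit = "mg")
#' @export
factor_spec <- function(name, low = NULL, high = NULL, center = NULL,
                        step = NULL, unit = "") {
  if (is.null(center) || is.null(step)) {
    if (is.null(low) || is.null(high))
      stop("factor '", name, "': give either low/high or center/step",
           call. = FALSE)
    center <- (low + high) / 2
    step <- (high - low) / 2
  } else {
    if (is.null(low)) low <- center - step
    if (is.null(high)) high <- center + step
  }
  if (!(high > low)) stop("factor '", name, "': high must exceed low",
                          call. = FALSE)
  if (!(step > 0)) stop("factor '", name, "': step must be positive",
                        call. = FALSE)
  structure(list(name = as.character(name), low = low, high = high,
                 center = center, step = step, unit = unit),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s: center %g, step %g %s (coded -1/+1 = %g/%g)\n",
              x$name, x$center, x$step, x$unit, x$low, x$high))
  invisible(x)
}

## ---- generator algebra (words over base-factor letters) --------------------

# symmetric difference of two effect words, e.g. "ABCE" * "AB" = "CE"
word_product <- function(a, b) {
  u <- c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  keep <- names(which(table(u) %% 2 == 1))
  paste(sort(keep), collapse = "")
}

parse_generator <- function(generator, k, p) {
  all_letters <- LETTERS[seq_len(k)]
  derived <- LETTERS[seq(k - p + 1, k)]
  base <- setdiff(all_letters, derived)
  parts <- unlist(strsplit(generator, ";|,"))
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) != p)
    stop("invalid generator: need ", p, " defining word(s), got ",
         length(parts), call. = FALSE)
  out <- list()
  for (g in parts) {
    m <- regmatches(g, regexec("^([A-Z])\\s*=\\s*([A-Z]+)$", g))[[1]]
    if (length(m) != 3)
      stop("invalid generator '", g, "': expected form 'E=ABCD'",
           call. = FALSE)
    lhs <- m[2]; rhs <- strsplit(m[3], "")[[1]]
    if (!(lhs %in% derived))
      stop("invalid generator '", g, "': '", lhs,
           "' is not a derived factor (expected one of ",
           paste(derived, collapse = ", "), ")", call. = FALSE)
    if (lhs %in% rhs)
      stop("invalid generator '", g, "': derived factor references itself",
           call. = FALSE)
    if (!all(rhs %in% base))
      stop("invalid generator '", g, "': right-hand side must use base ",
           "factors ", paste(base, collapse = ""), call. = FALSE)
    out[[lhs]] <- rhs
  }
  if (anyDuplicated(names(out)))
    stop("invalid generator: a derived factor is defined twice", call. = FALSE)
  out
}

# full defining-contrast subgroup (without I) from the p generator words
defining_words <- function(gens) {
  words <- vapply(names(gens), function(lhs)
    paste(sort(c(lhs, gens[[lhs]])), collapse = ""), "")
  sub <- ""
  for (w in words) sub <- unique(c(sub, vapply(sub, word_product, "", b = w)))
  setdiff(sub, "")
}

#' Generate a two-level (fractional) factorial design
#'
#' Builds the canonical standard-order `2^(k-p)` design. The `p` derived
#' factors are defined by generator words such as `"E=ABCD"`; the defining
#' relation, design resolution and alias structure follow from them. With
#' `p = 0` the full factorial is returned.
#'
#' @param k Total number of factors.
#' @param p Number of factors generated from interactions (`0 <= p < k`).
#' @param generator Defining relation, e.g. `"E=ABCD"`, or several words
#'   separated by commas for `p > 1`. Defaults (for `p = 1`) to aliasing the
#'   last factor with the interaction of all base factors, which gives the
#'   standard highest-resolution half fraction (resolution V for `k = 5`).
#' @param factor_names Optional column names; defaults to `X1..Xk`.
#' @param randomize,seed If `randomize = TRUE`, a seeded random run order is
#'   stored in `$run_order`; the `$runs` table itself stays in standard order.
#' @return An object of class `c("ffd_design", "doe_design")` with elements
#'   `runs` (data frame of coded -1/+1 settings), `generator`,
#'   `defining_words`, `resolution` and `run_order`.
#' @examples
#' d <- ffd_design(k = 5, p = 1)   # 16-run resolution-V half fraction
#' d$resolution
#' @export
ffd_design <- function(k, p = 0, generator = NULL, factor_names = NULL,
                       randomize = FALSE, seed = NULL) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (p < 0 || p >= k) stop("need 0 <= p < k", call. = FALSE)
  base_k <- k - p
  letters_all <- LETTERS[seq_len(k)]
  levels_list <- rep(list(c(-1, 1)), base_k)
  names(levels_list) <- letters_all[seq_len(base_k)]
  runs <- expand.grid(levels_list, KEEP.OUT.ATTRS = FALSE)
  gens <- NULL
  dwords <- character(0)
  if (p > 0) {
    if (is.null(generator)) {
      if (p > 1)
        stop("invalid generator: explicit generator required for p > 1",
             call. = FALSE)
      generator <- paste0(letters_all[k], "=",
                          paste(letters_all[seq_len(base_k)], collapse = ""))
    }
    gens <- parse_generator(generator, k, p)
    for (lhs in letters_all[seq(base_k + 1, k)]) {
      if (is.null(gens[[lhs]]))
        stop("invalid generator: no word defines factor ", lhs, call. = FALSE)
      runs[[lhs]] <- Reduce(`*`, runs[gens[[lhs]]])
    }
    dwords <- defining_words(gens)
  }
  if (is.null(factor_names)) factor_names <- paste0("X", seq_len(k))
  names(runs) <- factor_names
  n <- nrow(runs)
  run_order <- seq_len(n)
  if (randomize) {
    if (!is.null(seed)) set.seed(seed)
    run_order <- sample.int(n)
  }
  structure(list(runs = runs, factor_names = factor_names,
                 design_kind = "ffd", generator = generator,
                 letters = letters_all, defining_words = dwords,
                 resolution = if (length(dwords)) min(nchar(dwords)) else Inf,
                 alpha = NA_real_, n_center = 0L, run_order = run_order),
            class = c("ffd_design", "doe_design"))
}

#' Alias structure of a fractional factorial design
#'
#' Enumerates, for every main effect (and optionally low-order interactions),
#' the effects it is aliased with under the design's defining relation.
#'
#' @param design An `ffd_design`.
#' @param max_order Highest interaction order listed as an "effect of
#'   interest" (default 2: main effects and two-factor interactions).
#' @return Named list: for each effect word, the character vector of its
#'   aliases (in base-letter notation).
#' @export
alias_structure <- function(design, max_order = 2) {
  stopifnot(inherits(design, "ffd_design"))
  if (!length(design$defining_words)) return(list())
  k <- length(design$factor_names)
  effects <- unlist(lapply(seq_len(max_order), function(ord)
    apply(utils::combn(design$letters[seq_len(k)], ord), 2, paste,
          collapse = "")))
  out <- lapply(effects, function(e)
    sort(unname(vapply(design$defining_words, word_product, "", a = e)),
         method = "radix"))
  names(out) <- effects
  out
}

#' Generate a central composite design
#'
#' Standard-order CCD for `k` factors: `2^k` factorial points at coded
#' +-1, `2k` axial points at coded +-alpha, and `n_center` center replicates
#' at the origin. With `alpha = "rotatable"` the axial distance is
#' `(2^k)^(1/4)` (sqrt(2) for two factors), which puts all non-center points
#' of a 2-factor design on a circle of radius sqrt(2).
#'
#' @param factors List of [factor_spec()] objects (supplies names and the
#'   center/step coding).
#' @param alpha Axial distance, or `"rotatable"` (default).
#' @param n_center Number of center replicates (default 5).
#' @param randomize,seed As in [ffd_design()].
#' @return Object of class `c("ccd_design", "doe_design")`.
#' @examples
#' ccd_design(list(factor_spec("lipid", center = 500, step = 250, unit = "mg"),
#'                 factor_spec("surfactant", center = 700, step = 200,
#'                             unit = "mg")))
#' @export
ccd_design <- function(factors, alpha = "rotatable", n_center = 5,
                       randomize = FALSE, seed = NULL) {
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop("factors must be a list of factor_spec objects", call. = FALSE)
  k <- length(factors)
  if (k < 2) stop("dimension error: a CCD needs at least 2 factors",
                  call. = FALSE)
  if (identical(alpha, "rotatable")) alpha <- (2^k)^(1 / 4)
  if (!(is.numeric(alpha) && alpha > 0))
    stop("alpha must be positive", call. = FALSE)
  if (n_center < 1) stop("n_center must be at least 1", call. = FALSE)
  fnames <- vapply(factors, `[[`, "", "name")
  cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2 * k, k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -alpha
    axial[2 * i, i] <- alpha
  }
  centers <- matrix(0, n_center, k)
  runs <- as.data.frame(rbind(cube, axial, centers))
  names(runs) <- fnames
  rownames(runs) <- NULL
  n <- nrow(runs)
  run_order <- seq_len(n)
  if (randomize) {
    if (!is.null(seed)) set.seed(seed)
    run_order <- sample.int(n)
  }
  structure(list(runs = runs, factor_names = fnames, design_kind = "ccd",
                 factors = factors, alpha = alpha,
                 n_center = as.integer(n_center), run_order = run_order),
            class = c("ccd_design", "doe_design"))
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("%s design: %d runs x %d factors\n",
              toupper(x$design_kind), nrow(x$runs), length(x$factor_names)))
  if (x$design_kind == "ffd" && !is.null(x$generator))
    cat("  generator:", x$generator, " resolution:",
        as.character(x$resolution), "\n")
  if (x$design_kind == "ccd")
    cat(sprintf("  alpha = %.4f, %d center replicates\n", x$alpha,
                x$n_center))
  print(x$runs)
  invisible(x)
}

# coerce a design / data frame / matrix to a numeric coded matrix
as_coded_matrix <- function(design) {
  if (inherits(design, "doe_design")) design <- design$runs
  m <- as.matrix(design)
  if (!is.numeric(m)) stop("design must be numeric", call. = FALSE)
  m
}

#' Convert between coded and natural units
#'
#' `to_natural()` maps coded settings to natural units via
#' `X = center + x * step`; `to_coded()` is the inverse. Axial levels of the
#' worked example's lipid factor (center 500 mg, step 250 mg) decode to
#' 853.6 / 146.4 mg at 1 decimal.
#'
#' @param design A `doe_design`, data frame, or matrix of coded settings.
#' @param factors List of [factor_spec()]; taken from a `ccd_design`
#'   automatically.
#' @param digits Optional rounding (display convention; the coding itself is
#'   exact).
#' @return Data frame in natural units (or coded units for `to_coded`).
#' @export
to_natural <- function(design, factors = NULL, digits = NULL) {
  if (is.null(factors) && inherits(design, "ccd_design"))
    factors <- design$factors
  if (is.null(factors))
    stop("configuration error: factor specs with center/step required",
         call. = FALSE)
  m <- as_coded_matrix(design)
  if (ncol(m) != length(factors))
    stop("dimension error: ", ncol(m), " design columns vs ",
         length(factors), " factor specs", call. = FALSE)
  for (j in seq_along(factors))
    m[, j] <- factors[[j]]$center + m[, j] * factors[[j]]$step
  if (!is.null(digits)) m <- round(m, digits)
  out <- as.data.frame(m)
  names(out) <- vapply(factors, `[[`, "", "name")
  out
}

#' @rdname to_natural
#' @export
to_coded <- function(design, factors) {
  m <- as.matrix(as.data.frame(design))
  if (ncol(m) != length(factors))
    stop("dimension error: ", ncol(m), " columns vs ",
         length(factors), " factor specs", call. = FALSE)
  for (j in seq_along(factors))
    m[, j] <- (m[, j] - factors[[j]]$center) / factors[[j]]$step
  out <- as.data.frame(m)
  names(out) <- paste0("x", seq_along(factors))
  out
}

#' Code a two-level natural-unit table to -1/+1
#'
#' Convenience for screening tables printed in natural units: each selected
#' column must take exactly two distinct values; the lower maps to -1 and the
#' higher to +1.
#'
#' @param data Data frame.
#' @param cols Columns (names or indices) holding the factors.
#' @return Data frame of coded columns (same names).
#' @export
code_two_level <- function(data, cols) {
  out <- lapply(data[cols], function(v) {
    lev <- sort(unique(v))
    if (length(lev) != 2)
      stop("column is not two-level: found ", length(lev), " levels",
           call. = FALSE)
    ifelse(v == lev[1], -1, 1)
  })
  as.data.frame(out)
}
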