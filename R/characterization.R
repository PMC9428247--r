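#' Entrapment efficiency
#'
#' Percentage of the initial drug mass not found free in the dispersion
#' medium: `EE = (W0 - C_FR * V_f) / W0 * 100`.
#'
#' @param w0 Initial drug mass added to the formulation, mg (> 0).
#' @param c_fr Free (non-encapsulated) drug concentration, mg/ml.
#' @param v_f Final formulation volume, ml.
#' @return EE in percent. A negative result (free drug exceeding the input
#'   mass) is reported with a measurement warning.
#' @examples
#' entrapment_efficiency(w0 = 50, c_fr = 0.045, v_f = 20)  # 98.2
#' @export
entrapment_efficiency <- function(w0, c_fr, v_f) {
  if (!(w0 > 0)) stop("undefined: w0 must be positive", call. = FALSE)
  if (c_fr < 0 || v_f < 0) stop("negative input", call. = FALSE)
  ee <- (w0 - c_fr * v_f) / w0 * 100
  if (ee < 0)
    warning("free drug exceeds the initial mass; check the measurement",
            call. = FALSE)
  ee
}

#' Lipid-phase mass
#'
#' Total lipid-phase mass in mg: solid lipid plus the oil mass obtained from
#' its volume and density (1 ul * density g/ml = density mg).
#'
#' @param solid_mg Solid lipid mass, mg.
#' @param oil_ul Oil volume, ul (default 0).
#' @param oil_density Oil density, g/ml (default 0.95).
#' @return Mass in mg.
#' @export
lipid_phase_mass <- function(solid_mg, oil_ul = 0, oil_density = 0.95) {
  solid_mg + oil_ul * oil_density
}

#' Drug loading
#'
#' Encapsulated drug mass per lipid-phase mass:
#' `DL = (W0 - C_FR * V_f) / lipid_mass * 100`.
#'
#' @inheritParams entrapment_efficiency
#' @param lipid_mass Lipid-phase mass, mg (> 0); see [lipid_phase_mass()].
#' @return DL in percent.
#' @examples
#' drug_loading(50, 0.045, 20, lipid_phase_mass(616.9, oil_ul = 24))  # 7.7
#' @export
drug_loading <- function(w0, c_fr, v_f, lipid_mass) {
  if (!(lipid_mass > 0))
    stop("undefined: lipid_mass must be positive", call. = FALSE)
  (w0 - c_fr * v_f) / lipid_mass * 100
}

#' Crystallinity index
#'
#' Melting enthalpy of the lipid in the nanoparticle dispersion relative to
#' the bulk lipid at the stated lipid-phase concentration:
#' `CI = dH_dispersion / (dH_ref * C%) * 100`.
#'
#' @param dh Melting heat of the lipid in the dispersion, J/g.
#' @param c_lipid_pct Lipid-phase concentration, percent w/v.
#' @param dh_ref Melting heat of the pure bulk lipid, J/g; default 241.91
#'   (myristyl myristate).
#' @return CI in percent.
#' @examples
#' crystallinity_index(91.6, 3.0)  # 12.6
#' crystallinity_index(96.7, 3.0)  # 13.3
#' @export
crystallinity_index <- function(dh, c_lipid_pct, dh_ref = 241.91) {
  if (!(dh_ref > 0 && c_lipid_pct > 0))
    stop("undefined: reference enthalpy and concentration must be positive",
         call. = FALSE)
  dh / (dh_ref * c_lipid_pct) * 100
}

#' Bragg d-spacing from a powder-diffraction peak
#'
#' First-order Bragg inversion `d = lambda / (2 sin(theta))` with
#' `theta = two_theta / 2` converted to radians internally.
#' `bragg_two_theta()` is the inverse.
#'
#' @param two_theta Peak position 2-theta in degrees, in (0, 180).
#' @param wavelength X-ray wavelength in nm (default 0.154, Cu K-alpha).
#' @return d-spacing in the wavelength's unit (nm by default).
#' @examples
#' bragg_d_spacing(21.67)  # 0.41 nm
#' bragg_d_spacing(19.13)  # 0.46 nm
#' @export
bragg_d_spacing <- function(two_theta, wavelength = 0.154) {
  if (any(two_theta <= 0) || any(two_theta >= 180))
    stop("domain error: two_theta must lie in (0, 180) degrees",
         call. = FALSE)
  wavelength / (2 * sin(two_theta / 2 * pi / 180))
}

#' @rdname bragg_d_spacing
#' @param d d-spacing in the wavelength's unit.
#' @export
bragg_two_theta <- function(d, wavelength = 0.154) {
  2 * asin(wavelength / (2 * d)) * 180 / pi
}

#' Replicate summary
#'
#' Mean, sample standard deviation (n - 1 denominator) and relative standard
#' deviation of a set of replicate measurements.
#'
#' @param values Numeric vector, n >= 1 (n >= 2 for the SD).
#' @return Object of class `replicate_summary` with `values`, `n`, `mean`,
#'   `sd`, `rsd_pct`.
#' @examples
#' replicate_summary(c(180.1, 175.0, 180.6))
#' @export
replicate_summary <- function(values) {
  if (!length(values)) stop("empty replicate set", call. = FALSE)
  m <- mean(values)
  s <- if (length(values) >= 2) stats::sd(values) else NA_real_
  structure(list(values = values, n = length(values), mean = m, sd = s,
                 rsd_pct = 100 * s / abs(m)),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("n = %d: mean %.4g, sd %.3g, RSD %.3g%%\n", x$n, x$mean,
              x$sd, x$rsd_pct))
  invisible(x)
}

#' Two-sample t test statistic
#'
#' Closed-form two-sample comparison, pooled-variance (classical Student) or
#' Welch, two-sided. When both groups have zero variance and equal means the
#' conventional `p = 1` is returned.
#'
#' @param a,b Numeric vectors (n >= 2 each) or [replicate_summary()] objects.
#' @param mode `"welch"` (default) or `"pooled"`.
#' @return List with `statistic`, `df`, `p_value`, `mean_difference`.
#' @export
two_sample_t <- function(a, b, mode = c("welch", "pooled")) {
  mode <- match.arg(mode)
  if (inherits(a, "replicate_summary")) a <- a$values
  if (inherits(b, "replicate_summary")) b <- b$values
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (v1 == 0 && v2 == 0) {
    if (dm == 0)
      return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1,
                  mean_difference = 0))
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  if (mode == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- dm / se
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       mean_difference = dm)
}
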