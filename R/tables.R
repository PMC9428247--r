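## Packaged study tables -----------------------------------------------------
##
## The five CSVs under inst/extdata transcribe the printed study tables of the
## worked phenobarbital-NLC example. Decimal commas in the printed originals
## ("150,2") were normalized to decimal points at transcription time and
## Unicode minus signs to ASCII; no values were imputed.

qbd_table_schemas <- list(
  table1 = c("run", "lipid_mg", "surfactant_mg", "oil_ul", "sonication_min",
             "power_pct", "size_nm", "pdi", "zeta_mv"),
  table2 = c("run", "lipid_mg", "surfactant_mg", "size_nm", "pdi", "zeta_mv"),
  table3 = c("response", "rep1", "rep2", "rep3"),
  table4 = c("sample", "tm_c", "dh_j_g", "ci_pct"),
  table5 = c("sample", "two_theta_deg", "theta_deg", "d_spacing_a")
)

#' Read a study table or a user CSV
#'
#' Loads one of the packaged study tables (`"table1"` .. `"table5"`) or any
#' CSV given by path. Unicode minus signs are normalized to ASCII; files
#' using `;` as separator are read with decimal commas. Packaged tables are
#' validated against their known schema and a parse error names the first
#' offending column.
#'
#' @param id Table id (`"table1"` .. `"table5"`) or a file path.
#' @return Data frame. `table1` is the 16-run two-level screening design with
#'   its three measured responses; `table2` the 13-run central composite
#'   design; `table3` replicate measurements of the optimized formulation;
#'   `table4` calorimetry records; `table5` diffraction peak positions.
#' @examples
#' head(qbd_table("table2"))
#' @export
qbd_table <- function(id) {
  packaged <- id %in% names(qbd_table_schemas)
  path <- if (packaged)
    system.file("extdata", paste0(id, ".csv"), package = "nlcqbd",
                mustWork = TRUE)
  else id
  if (!file.exists(path)) stop("no such table or file: ", id, call. = FALSE)
  # a user file named like a packaged table is held to the same schema
  schema_id <- sub("\\.csv$", "", basename(path))
  known <- schema_id %in% names(qbd_table_schemas)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- gsub("−", "-", lines)
  semi <- grepl(";", lines[1])
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        sep = if (semi) ";" else ",",
                        dec = if (semi) "," else ".",
                        stringsAsFactors = FALSE)
  if (known) {
    want <- qbd_table_schemas[[schema_id]]
    missing <- setdiff(want, names(df))
    if (length(missing))
      stop("parse error in ", schema_id, ": missing column '", missing[1],
           "'", call. = FALSE)
    df <- df[want]
  }
  df
}

# factor specs behind the central composite table (centers 500/700 mg,
# steps 250/200 mg forced by its printed natural levels)
table2_factors <- function() {
  list(factor_spec("lipid_mg", center = 500, step = 250, unit = "mg"),
       factor_spec("surfactant_mg", center = 700, step = 200, unit = "mg"))
}

#' Coded central composite table
#'
#' Returns the packaged 13-run CCD table with the factor columns coded as
#' `x1 = (lipid - 500)/250` and `x2 = (surfactant - 700)/200`, ready for
#' [fit_surface()].
#'
#' @return Data frame with columns `x1`, `x2`, `size_nm`, `pdi`, `zeta_mv`.
#' @export
qbd_ccd_table <- function() {
  t2 <- qbd_table("table2")
  cbind(to_coded(t2[c("lipid_mg", "surfactant_mg")], table2_factors()),
        t2[c("size_nm", "pdi", "zeta_mv")])
}

#' Run the full screening-to-optimization chain on the packaged tables
#'
#' Deterministic end-to-end pipeline: (1) main-effects screening ANOVA of the
#' 16-run two-level design for each of the three responses; (2) model
#' selection and response-surface fits on the 13-run CCD; (3) multi-response
#' smaller-is-better desirability optimization over the coded disk of radius
#' sqrt(2) with data-range bounds; (4) characterization numbers
#' (crystallinity indices, d-spacings, replicate summaries).
#'
#' @param alpha Screening significance level (default 0.01).
#' @param seed Seed for the optimizer's random restarts.
#' @return Object of class `qbd_report`.
#' @export
run_qbd_pipeline <- function(alpha = 0.01, seed = 1) {
  t1 <- qbd_table("table1")
  fac_cols <- c("lipid_mg", "surfactant_mg", "oil_ul", "sonication_min",
                "power_pct")
  coded1 <- code_two_level(t1, fac_cols)
  screening <- lapply(c(size_nm = "size_nm", pdi = "pdi", zeta_mv = "zeta_mv"),
                      function(r) screen_anova(coded1, t1[[r]], alpha))

  tab <- qbd_ccd_table()
  selections <- lapply(c(size_nm = "size_nm", pdi = "pdi",
                         zeta_mv = "zeta_mv"),
                       function(r) select_model(tab, r))
  surfaces <- lapply(selections, `[[`, "surface")
  specs <- specs_from_data(tab, names(surfaces))
  opt <- maximize_desirability(surfaces, specs, seed = seed,
                               factors = table2_factors())

  t4 <- qbd_table("table4")
  nlc <- t4[t4$sample %in% c("NLC-vehicle", "NLC-PB"), ]
  ci <- stats::setNames(crystallinity_index(nlc$dh_j_g, 3.0), nlc$sample)
  t5 <- qbd_table("table5")
  dspace <- data.frame(sample = t5$sample, two_theta_deg = t5$two_theta_deg,
                       d_nm = bragg_d_spacing(t5$two_theta_deg))
  t3 <- qbd_table("table3")
  reps <- lapply(stats::setNames(seq_len(nrow(t3)), t3$response), function(i)
    replicate_summary(as.numeric(t3[i, c("rep1", "rep2", "rep3")])))

  structure(list(alpha = alpha, seed = seed, screening = screening,
                 selections = selections, optimization = opt,
                 crystallinity = ci, d_spacings = dspace,
                 replicates = reps),
            class = "qbd_report")
}

#' @export
print.qbd_report <- function(x, ...) {
  cat("== QbD formulation pipeline report ==\n\n")
  cat("Screening (alpha =", x$alpha, "): selected factors\n")
  for (r in names(x$screening))
    cat(sprintf("  %-8s: %s\n", r,
                if (length(x$screening[[r]]$selected))
                  paste(x$screening[[r]]$selected, collapse = ", ")
                else "(none)"))
  cat("\nResponse-surface model selection\n")
  for (r in names(x$selections)) {
    s <- x$selections[[r]]$surface
    cat(sprintf("  %-8s: %-24s R2 = %.2f\n", r, s$model_class, s$r_squared))
  }
  cat("\n")
  print(x$optimization)
  cat("\nCrystallinity index (%):",
      paste(names(x$crystallinity), round(x$crystallinity, 1), sep = " = ",
            collapse = ", "), "\n")
  cat("Replicate means:",
      paste(names(x$replicates),
            vapply(x$replicates, function(r) signif(r$mean, 4), 0),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
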