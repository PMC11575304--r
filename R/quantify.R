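#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies/uL) over a serial dilution of
#' a spacer-containing plasmid standard. Amplification efficiency is derived
#' from the slope as `(10^(-1/slope) - 1) * 100`; a perfect doubling per
#' cycle gives slope -3.3219 and 100% efficiency.
#'
#' @param points Data frame with columns `copies_per_ul` (> 0) and `cq`.
#' @param loq_copies_per_ul Limit of quantification; defaults to the lowest
#'   standard concentration.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency_pct`, `loq_copies_per_ul`.
#' @export
#' @examples
#' std <- tibble::tibble(copies_per_ul = 10^(6:2),
#'                       cq = 20 + 3.3219 * (0:4))
#' glance(fit_standard_curve(std))
fit_standard_curve <- function(points, loq_copies_per_ul = NULL) {
  stopifnot(all(c("copies_per_ul", "cq") %in% names(points)))
  if (any(points$copies_per_ul <= 0)) {
    abort("standard-curve copies_per_ul must be positive")
  }
  if (length(unique(points$copies_per_ul)) < 3) {
    abort("standard curve needs at least 3 distinct concentrations")
  }
  log_copies <- log10(points$copies_per_ul)
  fit <- lm(cq ~ log_copies, data = tibble(cq = points$cq, log_copies = log_copies))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- cor(points$cq, log_copies)^2
  structure(
    list(
      slope = slope,
      intercept = intercept,
      r_squared = r2,
      efficiency_pct = (10^(-1 / slope) - 1) * 100,
      loq_copies_per_ul = loq_copies_per_ul %||% min(points$copies_per_ul),
      n_points = nrow(points),
      fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n",
      sprintf("  Cq = %.4f + %.4f * log10(copies/uL)\n", x$intercept, x$slope),
      sprintf("  r^2 = %.4f, efficiency = %.1f%%, LOQ = %g copies/uL\n",
              x$r_squared, x$efficiency_pct, x$loq_copies_per_ul),
      sep = "")
  invisible(x)
}

#' Convert Cq values to spacer copies/uL
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept)/slope)`.
#' Replicate reactions are averaged on the copies (linear) scale. A sample
#' whose replicates all failed to amplify (all `NA`) is reported as ND;
#' results below the curve's LOQ keep their value but are flagged.
#'
#' @param cq_tbl Data frame with columns `sample_id`, `cq` (NA = no
#'   amplification) and optionally `locus`.
#' @param curve A [fit_standard_curve()] result.
#' @param qc_threshold Copies/uL required to pass QC (default 100).
#' @return A tibble with one row per sample (x locus): `copies_per_ul`,
#'   `nd`, `below_loq`, `qc_pass`.
#' @export
copies_from_cq <- function(cq_tbl, curve, qc_threshold = 100) {
  stopifnot(inherits(curve, "standard_curve"),
            all(c("sample_id", "cq") %in% names(cq_tbl)))
  if (any(cq_tbl$cq <= 0, na.rm = TRUE)) {
    abort("Cq values must be positive")
  }
  if (!"locus" %in% names(cq_tbl)) cq_tbl$locus <- NA_character_
  cq_tbl %>%
    mutate(copies = 10^((.data$cq - curve$intercept) / curve$slope)) %>%
    group_by(.data$sample_id, .data$locus) %>%
    summarise(
      copies_per_ul = if (all(is.na(.data$copies))) NA_real_
                      else mean(.data$copies, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      nd = is.na(.data$copies_per_ul),
      below_loq = .data$nd | .data$copies_per_ul < curve$loq_copies_per_ul,
      qc_pass = qc_assess(.data$copies_per_ul, qc_threshold)$qc_pass
    )
}

#' Assess the minimum spacer-load quality gate
#'
#' Reproducible typing requires a minimal template load; the default gate is
#' 10^2 spacer copies/uL. ND (no amplification) always fails.
#'
#' @param copies_per_ul Numeric vector (NA = ND).
#' @param threshold Copies/uL required to pass (default 100).
#' @return A tibble with `qc_pass` and an `advisory` string per value.
#' @export
#' @examples
#' qc_assess(c(362.1, 49.6, NA))
qc_assess <- function(copies_per_ul, threshold = 100) {
  pass <- !is.na(copies_per_ul) & copies_per_ul >= threshold
  advisory <- dplyr::case_when(
    is.na(copies_per_ul) ~ "no amplification: typing unreliable",
    copies_per_ul < threshold ~
      sprintf("below %g copies/uL: typing may be noise-dominated", threshold),
    TRUE ~ "sufficient spacer load"
  )
  tibble(qc_pass = pass, advisory = advisory)
}

#' Mean spacer copies/uL by sample type and locus
#'
#' Arithmetic mean over the matching copy-table rows. ND rows contribute 0
#' with the row kept in the denominator; below-LOQ values enter as printed.
#'
#' @param copy_table A tibble from [read_copy_table()].
#' @param sample_type Sample type to summarise (e.g. `"skin"`, `"saliva"`).
#' @param locus Locus to summarise (e.g. `"CRISPR3"`).
#' @return The mean copies/uL (a single number).
#' @export
summarize_copies <- function(copy_table, sample_type, locus) {
  stopifnot(all(c("sample_type", "locus", "copies_per_ul") %in% names(copy_table)))
  rows <- copy_table[copy_table$sample_type == sample_type &
                     copy_table$locus == locus, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("no copy-table rows for sample_type '%s', locus '%s'",
                  sample_type, locus))
  }
  values <- rows$copies_per_ul
  values[is.na(values)] <- 0
  mean(values)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency_pct = x$efficiency_pct,
         loq_copies_per_ul = x$loq_copies_per_ul, n_points = x$n_points)
}

#' @export
autoplot.standard_curve <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_copies, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = "dashed") +
    ggplot2::labs(x = "log10(copies/uL)", y = "Cq",
                  title = sprintf("Standard curve (eff. %.1f%%, r² = %.3f)",
                                  object$efficiency_pct, object$r_squared))
}
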