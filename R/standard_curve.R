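#' Amplification efficiency from a standard-curve slope
#'
#' For a dilution series fitted as Cq vs log10(template amount), the
#' per-cycle amplification efficiency in percent is
#' `E = (10^(-1/slope) - 1) * 100`; a perfectly doubling assay has slope
#' `-1/log10(2) = -3.3219` and E = 100%.
#'
#' @param slope cycles per log10 unit of template; must be nonzero. A
#'   positive slope (anti-correlated curve) triggers a warning but the
#'   value is still returned.
#' @return efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope == 0) {
    stop("slope must be finite and nonzero")
  }
  if (slope > 0) {
    warning("positive slope: Cq increases with template amount")
  }
  (10^(-1 / slope) - 1) * 100
}

#' Amplification factor from efficiency
#'
#' The fold increase per PCR cycle, `A = 1 + E/100`; 100% efficiency gives
#' perfect doubling (A = 2). This is the base used when converting Cq
#' differences to relative quantities.
#'
#' @param efficiency_percent efficiency E in percent; must exceed -100.
#' @return fold amplification per cycle.
#' @export
amplification_factor <- function(efficiency_percent) {
  if (any(!is.finite(efficiency_percent)) || any(efficiency_percent <= -100)) {
    stop("efficiency_percent must be finite and > -100")
  }
  1 + efficiency_percent / 100
}

#' Fit a dilution-series standard curve
#'
#' Ordinary least squares of Cq on log10 template amount over a serial
#' dilution (classically six 10-fold dilutions, e.g. 1e4..1e9 copies/uL).
#' Reports slope, intercept, the determination coefficient R^2 (squared
#' Pearson correlation, identical to the R^2 of the simple linear
#' regression), and the derived amplification efficiency.
#'
#' @param log10_amount log10 of template copy number per microliter, or a
#'   data.frame with columns `log10_amount` and `cq` (a `gene` column is
#'   carried through if present).
#' @param cq quantification cycles (omit when a data.frame is given).
#' @return object of class `standard_curve_fit`: a list with `slope`,
#'   `intercept`, `r_squared`, `efficiency_percent`, `amplification_factor`,
#'   `n_points` and, when available, `gene`.
#' @export
fit_standard_curve <- function(log10_amount, cq = NULL) {
  gene <- NA_character_
  if (is.data.frame(log10_amount)) {
    df <- log10_amount
    stopifnot(all(c("log10_amount", "cq") %in% names(df)))
    if (!is.null(df$gene)) gene <- as.character(df$gene[1L])
    cq <- df$cq
    log10_amount <- df$log10_amount
  }
  x <- as.numeric(log10_amount)
  y <- as.numeric(cq)
  if (length(x) != length(y)) stop("log10_amount and cq lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite curve points")
  if (length(unique(x)) < 3L) {
    stop("degenerate design: need >= 3 distinct log10_amount values")
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- if (stats::var(y) == 0) 1 else unname(stats::cor(x, y)^2)
  eff <- efficiency_from_slope(slope)
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency_percent = eff,
                 amplification_factor = amplification_factor(eff),
                 n_points = length(x)),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat("Standard curve fit",
      if (!is.na(x$gene)) paste0("(", x$gene, ")"), "\n")
  cat(sprintf("  slope: %.4f cycles/log10  intercept: %.3f  R^2: %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  efficiency: %.1f%%  (amplification factor %.3f)\n",
              x$efficiency_percent, x$amplification_factor))
  invisible(x)
}

#' Fit standard curves for a table of dilution series
#'
#' @param df data.frame with columns `gene`, `log10_amount`, `cq`.
#' @return data.frame with one row per gene: `gene`, `slope`, `intercept`,
#'   `r_squared`, `efficiency_percent`.
#' @export
fit_standard_curves <- function(df) {
  stopifnot(all(c("gene", "log10_amount", "cq") %in% names(df)))
  fits <- lapply(split(df, factor(df$gene, unique(df$gene))), fit_standard_curve)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(gene = f$gene, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared,
               efficiency_percent = f$efficiency_percent,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
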