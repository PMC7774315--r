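# ICH-style method validation: %RSD, linearity, LOD/LOQ, IS recovery.

#' Relative standard deviation in percent
#'
#' `100 * sample SD / mean` of replicate measurements (n-1 denominator,
#' the convention for triplicate repeatability/reproducibility figures).
#'
#' @param values Numeric vector of at least two replicate measurements with
#'   non-zero mean.
#' @return %RSD.
#' @examples
#' rsd_percent(c(9, 10, 11))  # 10
#' @export
rsd_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("at least two non-missing values are required", call. = FALSE)
  }
  m <- mean(values)
  if (abs(m) < .Machine$double.eps * max(1, max(abs(values)))) {
    stop("mean of the replicate values is zero; %RSD is undefined",
         call. = FALSE)
  }
  100 * stats::sd(values) / m
}

#' Construct a calibration series
#'
#' Replicated instrument responses at a ladder of injected amounts. At least
#' three distinct, strictly positive amounts are required for a meaningful
#' linearity assessment; points are sorted by amount.
#'
#' @param amounts Numeric vector of injected amounts (one per row).
#' @param peak_areas Numeric vector of measured peak areas (same length).
#' @param analyte_id Analyte label.
#' @param unit Amount unit label, e.g. `"pg"` or `"ng"`; carried through to
#'   LOD/LOQ so units are always explicit and never converted implicitly.
#' @return A `data.frame` of class `calibration_series` with columns
#'   `amount`, `peak_area`.
#' @export
calibration_series <- function(amounts, peak_areas, analyte_id = "analyte",
                               unit = "pg") {
  stopifnot(length(amounts) == length(peak_areas))
  if (any(amounts <= 0)) {
    stop("calibration amounts must be strictly positive", call. = FALSE)
  }
  if (length(unique(amounts)) < 3L) {
    stop("a calibration series needs at least three distinct amounts",
         call. = FALSE)
  }
  ord <- order(amounts)
  out <- data.frame(amount = amounts[ord], peak_area = peak_areas[ord])
  attr(out, "analyte_id") <- analyte_id
  attr(out, "unit") <- unit
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Linear calibration fit
#'
#' Ordinary least squares of peak area on amount, `y = a + b x`, over all
#' replicate points. `Sa` is by default the OLS standard error of the
#' intercept (the usual ICH reading of "standard deviation of the
#' intercept"); `sa_method = "residual_sd"` substitutes the residual standard
#' deviation, a second common ICH variant.
#'
#' @param series A `calibration_series`, or any `data.frame` with columns
#'   `amount` and `peak_area` (two-point fits are allowed for cross-checks;
#'   `Sa` is then undefined).
#' @param sa_method `"intercept_se"` (default) or `"residual_sd"`.
#' @return An object of class `calibration_fit` with fields `a` (intercept),
#'   `b` (slope), `Sa`, `r_squared`, `n`, `unit`, `analyte_id` and the
#'   underlying `lm` fit.
#' @export
fit_linearity <- function(series, sa_method = c("intercept_se", "residual_sd")) {
  sa_method <- match.arg(sa_method)
  stopifnot(all(c("amount", "peak_area") %in% names(series)))
  if (length(unique(series$amount)) < 2L) {
    stop("all calibration amounts are identical; the fit is singular",
         call. = FALSE)
  }
  fit <- stats::lm(peak_area ~ amount, data = series)
  # noiseless calibrations are a supported degenerate case (Sa = 0, R^2 = 1);
  # summary.lm()'s perfect-fit warning adds nothing there
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  Sa <- if (sa_method == "intercept_se") {
    unname(sm$coefficients["(Intercept)", "Std. Error"])
  } else {
    sm$sigma
  }
  structure(
    list(a = a, b = b, Sa = Sa, r_squared = sm$r.squared,
         n = nrow(series), sa_method = sa_method,
         analyte_id = attr(series, "analyte_id"),
         unit = attr(series, "unit"), fit = fit),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration fit> %s: y = %.6g + %.6g x (n=%d)\nSa (%s) = %.6g; R^2 = %.6f\n",
    if (is.null(x$analyte_id)) "analyte" else x$analyte_id,
    x$a, x$b, x$n, x$sa_method, x$Sa, x$r_squared))
  ll <- lod_loq(x)
  cat(sprintf("LOD = %.6g %s; LOQ = %.6g %s\n", ll[["lod"]], x$unit,
              ll[["loq"]], x$unit))
  invisible(x)
}

#' Limit of detection and quantification from a calibration
#'
#' ICH linear-regression limits: `LOD = 3 Sa / b`, `LOQ = 10 Sa / b`, in the
#' unit of the calibration amounts. By construction `LOQ / LOD = 10 / 3`
#' exactly.
#'
#' @param Sa Standard deviation of the intercept (or a `calibration_fit`,
#'   from which `Sa` and `b` are taken).
#' @param b Calibration slope (must be positive).
#' @return Named numeric vector `c(lod, loq)`.
#' @examples
#' lod_loq(0.2, 60)
#' @export
lod_loq <- function(Sa, b) {
  if (inherits(Sa, "calibration_fit")) {
    b <- Sa$b
    Sa <- Sa$Sa
  }
  if (b <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (Sa < 0) stop("Sa must be non-negative", call. = FALSE)
  c(lod = 3 * Sa / b, loq = 10 * Sa / b)
}

#' Internal-standard recovery
#'
#' Per sample x day, `100 * mean(IS areas in the sample) / mean(IS areas in
#' water)`. The summary reports the min-max range across cells, the figure
#' usually quoted for matrix-effect acceptance.
#'
#' @param samples A `data.frame` with columns `sample_id`, `day`, `peak_area`
#'   (replicate IS areas in samples).
#' @param reference Numeric vector of replicate IS areas in water.
#' @return A list with `per_cell` (sample, day, recovery_pct, flag) and
#'   `range` (min, max). Cells with zero mean are reported as 0% and
#'   flagged.
#' @export
is_recovery <- function(samples, reference) {
  stopifnot(all(c("sample_id", "day", "peak_area") %in% names(samples)))
  if (nrow(samples) == 0L || length(reference) == 0L) {
    stop("empty input", call. = FALSE)
  }
  ref_mean <- mean(reference)
  if (ref_mean <= 0) {
    stop("reference (IS in water) mean must be positive", call. = FALSE)
  }
  groups <- split(samples$peak_area,
                  interaction(samples$sample_id, samples$day, drop = TRUE,
                              sep = "\001"))
  per_cell <- do.call(rbind, lapply(names(groups), function(g) {
    parts <- strsplit(g, "\001", fixed = TRUE)[[1L]]
    m <- mean(groups[[g]])
    flagged <- m <= 0
    if (flagged) {
      warning("IS sample mean is zero for sample ", sQuote(parts[1L]),
              ", day ", parts[2L], call. = FALSE)
    }
    data.frame(sample_id = parts[1L], day = parts[2L],
               recovery_pct = 100 * m / ref_mean, flag = flagged,
               stringsAsFactors = FALSE)
  }))
  list(per_cell = per_cell,
       range = c(min = min(per_cell$recovery_pct),
                 max = max(per_cell$recovery_pct)))
}

#' Assemble a method-validation report
#'
#' One row per analyte with the ICH validation criteria: calibration slope,
#' intercept, Sa, R-squared, LOD, LOQ (in each analyte's own amount unit),
#' intraday %RSD (within-day replicates), interday %RSD (across day-level
#' means) and IS recovery. Any component may be omitted (`NA` in the report).
#'
#' @param calibrations Named list of `calibration_series` (names = analyte).
#' @param intraday Named list of numeric replicate vectors measured within
#'   one day.
#' @param interday Named list of numeric vectors of day-level means.
#' @param recovery Named numeric vector of recovery percentages.
#' @param sa_method Passed to [fit_linearity()].
#' @return A `data.frame` of class `validation_report`, one row per analyte.
#' @export
validation_report <- function(calibrations = list(), intraday = list(),
                              interday = list(), recovery = c(),
                              sa_method = "intercept_se") {
  analytes <- unique(c(names(calibrations), names(intraday), names(interday),
                       names(recovery)))
  if (length(analytes) == 0L) stop("no analytes supplied", call. = FALSE)
  rows <- lapply(analytes, function(id) {
    row <- data.frame(analyte_id = id, slope = NA_real_, intercept = NA_real_,
                      Sa = NA_real_, r_squared = NA_real_, lod = NA_real_,
                      loq = NA_real_, unit = NA_character_,
                      intraday_rsd_pct = NA_real_, interday_rsd_pct = NA_real_,
                      recovery_pct = NA_real_, stringsAsFactors = FALSE)
    if (id %in% names(calibrations)) {
      f <- fit_linearity(calibrations[[id]], sa_method = sa_method)
      ll <- lod_loq(f)
      row$slope <- f$b; row$intercept <- f$a; row$Sa <- f$Sa
      row$r_squared <- f$r_squared
      row$lod <- ll[["lod"]]; row$loq <- ll[["loq"]]
      row$unit <- if (is.null(f$unit)) NA_character_ else f$unit
    }
    if (id %in% names(intraday)) {
      row$intraday_rsd_pct <- rsd_percent(intraday[[id]])
    }
    if (id %in% names(interday)) {
      row$interday_rsd_pct <- rsd_percent(interday[[id]])
    }
    if (id %in% names(recovery)) row$recovery_pct <- recovery[[id]]
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<method validation report> %d analyte(s)\n", nrow(x)))
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

#' Write a validation report as CSV or JSON
#'
#' @param x A `validation_report`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
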