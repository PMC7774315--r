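# Peak-area tables, internal-standard normalisation and relative
# quantification per mg flour.

#' Construct a measurement table
#'
#' Long-format MRM peak areas: one row per sample x replicate x analyte.
#' `analyte_id` is a quantifier peptide sequence, `"IS"` (the spiked internal
#' standard) or `"bLG"` (the beta-lactoglobulin digestion monitor). The
#' extraction metadata describe how much flour one injection represents:
#' `flour_mass_mg` of flour extracted into `extraction_volume_mL` of buffer,
#' `digest_aliquot_mL` of the extract digested and made up to
#' `final_volume_mL`, of which `injected_volume_uL` is injected.
#'
#' @param data A `data.frame` with columns `sample_id`, `replicate`,
#'   `analyte_id`, `peak_area`.
#' @param flour_mass_mg,extraction_volume_mL,digest_aliquot_mL,final_volume_mL,injected_volume_uL
#'   Extraction/dilution metadata (defaults 100 mg, 1 mL, 0.4 mL, 5 mL,
#'   10 uL).
#' @return The validated `data.frame` with class `measurement_table` and the
#'   metadata stored as attributes.
#' @export
measurement_table <- function(data, flour_mass_mg = 100,
                              extraction_volume_mL = 1,
                              digest_aliquot_mL = 0.4,
                              final_volume_mL = 5,
                              injected_volume_uL = 10) {
  required <- c("sample_id", "replicate", "analyte_id", "peak_area")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("measurement table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(data$peak_area)) || any(data$peak_area < 0)) {
    stop("peak_area values must be non-negative and non-missing",
         call. = FALSE)
  }
  if (any(data$replicate < 1L)) {
    stop("replicate indices must be >= 1", call. = FALSE)
  }
  meta <- c(flour_mass_mg = flour_mass_mg,
            extraction_volume_mL = extraction_volume_mL,
            digest_aliquot_mL = digest_aliquot_mL,
            final_volume_mL = final_volume_mL,
            injected_volume_uL = injected_volume_uL)
  if (any(meta <= 0)) {
    stop("all extraction metadata must be positive", call. = FALSE)
  }
  out <- as.data.frame(data, stringsAsFactors = FALSE)
  attr(out, "extraction") <- as.list(meta)
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' @rdname measurement_table
#' @param path CSV path (header required, UTF-8, '.' decimal separator).
#' @param ... Metadata arguments forwarded to [measurement_table()].
#' @export
read_measurement_table <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  measurement_table(df, ...)
}

#' @rdname measurement_table
#' @param x A `measurement_table`.
#' @export
write_measurement_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flour mass represented by one injection
#'
#' The dilution chain `flour_mass_mg * (digest_aliquot_mL /
#' extraction_volume_mL) * (injected_volume_uL / 1000 / final_volume_mL)`
#' converts the extraction metadata into the effective mg of flour whose
#' peptides reach the detector in one injection. Every factor is
#' config-overridable through [measurement_table()].
#'
#' @param table A `measurement_table`.
#' @return Effective flour mass in mg.
#' @export
effective_flour_mg <- function(table) {
  m <- attr(table, "extraction")
  mg <- m$flour_mass_mg * (m$digest_aliquot_mL / m$extraction_volume_mL) *
    (m$injected_volume_uL / 1000 / m$final_volume_mL)
  if (!is.finite(mg) || mg <= 0) {
    stop("effective flour mass per injection is zero or undefined; ",
         "check the extraction metadata", call. = FALSE)
  }
  mg
}

#' Internal-standard normalisation of peak areas
#'
#' The internal standard is spiked at a fixed level after sample cleanup, so
#' its measured area tracks ionization-stage signal drift only. Every analyte
#' area of a sample x replicate is multiplied by `is_reference_area / IS
#' area` of that cell (the IS response in water over the IS response in the
#' sample), cancelling multiplicative ionization effects shared by IS and
#' analytes. IS rows are set to the reference area. Digestion-stage losses,
#' which the IS does not experience, are deliberately not corrected.
#'
#' @param table A `measurement_table`.
#' @param is_reference_area IS peak area in water (positive number).
#' @param is_id Analyte id of the internal standard (default `"IS"`).
#' @return The normalised `measurement_table`.
#' @export
is_normalize <- function(table, is_reference_area, is_id = "IS") {
  stopifnot(inherits(table, "measurement_table"))
  if (!is.numeric(is_reference_area) || is_reference_area <= 0) {
    stop("is_reference_area must be a positive number", call. = FALSE)
  }
  key <- interaction(table$sample_id, table$replicate, drop = TRUE)
  for (cell in levels(key)) {
    rows <- which(key == cell)
    is_row <- rows[table$analyte_id[rows] == is_id]
    cell_name <- paste0("sample ", sQuote(unique(table$sample_id[rows])),
                        ", replicate ", unique(table$replicate[rows]))
    if (length(is_row) == 0L) {
      stop("no internal-standard row for ", cell_name, call. = FALSE)
    }
    if (length(is_row) > 1L) {
      stop("multiple internal-standard rows for ", cell_name, call. = FALSE)
    }
    is_pa <- table$peak_area[is_row]
    if (is_pa <= 0) {
      stop("internal-standard peak area is zero for ", cell_name,
           call. = FALSE)
    }
    table$peak_area[rows] <- table$peak_area[rows] * (is_reference_area / is_pa)
    table$peak_area[is_row] <- is_reference_area
  }
  table
}

#' Matrix-effect recovery and loss
#'
#' Recovery of an analyte relative to a matrix-free control:
#' `100 * observed / control` percent; loss is `100 - recovery`. Used to
#' express digestion-stage matrix suppression of the beta-lactoglobulin
#' monitor peptide and ionization-stage effects on the internal standard.
#'
#' @param observed Peak area(s) in the sample matrix.
#' @param control Peak area(s) in the matrix-free control (positive).
#' @return A `data.frame` with columns `recovery_pct` and `loss_pct`.
#' @examples
#' matrix_recovery(90, 1000)   # 9% recovery, 91% loss
#' @export
matrix_recovery <- function(observed, control) {
  if (any(control <= 0)) {
    stop("control peak area must be positive", call. = FALSE)
  }
  rec <- 100 * observed / control
  data.frame(recovery_pct = rec, loss_pct = 100 - rec)
}

#' Relative ATI content per mg flour
#'
#' Computes, per replicate, each protein's peak area (taken from its
#' quantifier peptide only; qualifier peptides serve identification, not
#' quantification), their sum divided by the effective flour mass of one
#' injection ([effective_flour_mg()]), and the percentage composition. Per
#' sample, replicate-level results are aggregated as mean and sample SD
#' (aggregation of per-replicate results, not of pooled areas). When every
#' protein is zero in a replicate the composition is undefined and reported
#' as `NA`.
#'
#' @param table A `measurement_table`, typically already IS-normalised with
#'   [is_normalize()].
#' @param quantifier_map Named character vector mapping protein accession to
#'   its quantifier peptide's `analyte_id`.
#' @return An object of class `quant_result`: a list with `per_replicate`
#'   (one row per sample x replicate), `summary` (one row per sample:
#'   `total_pa_per_mg_mean`, `total_pa_per_mg_sd`, and per-protein
#'   composition mean/SD) and `effective_mg`.
#' @export
relative_ati_content <- function(table, quantifier_map) {
  stopifnot(inherits(table, "measurement_table"))
  proteins <- names(quantifier_map)
  if (is.null(proteins) || any(!nzchar(proteins))) {
    stop("quantifier_map must be a named character vector ",
         "(protein -> analyte_id)", call. = FALSE)
  }
  eff_mg <- effective_flour_mg(table)
  cells <- unique(table[, c("sample_id", "replicate")])
  per_rep <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- table$sample_id == cells$sample_id[i] &
      table$replicate == cells$replicate[i]
    pa <- numeric(length(proteins))
    for (j in seq_along(proteins)) {
      rows <- sel & table$analyte_id == quantifier_map[[j]]
      if (!any(rows)) {
        stop("quantifier peptide ", sQuote(quantifier_map[[j]]),
             " for protein ", sQuote(proteins[j]), " is absent in sample ",
             sQuote(cells$sample_id[i]), ", replicate ",
             cells$replicate[i], call. = FALSE)
      }
      pa[j] <- sum(table$peak_area[rows])
    }
    total <- sum(pa)
    comp <- if (total > 0) 100 * pa / total else rep(NA_real_, length(pa))
    row <- data.frame(sample_id = cells$sample_id[i],
                      replicate = cells$replicate[i],
                      total_pa_per_mg = total / eff_mg,
                      stringsAsFactors = FALSE)
    for (j in seq_along(proteins)) {
      row[[paste0("pa_", proteins[j])]] <- pa[j]
      row[[paste0("pct_", proteins[j])]] <- comp[j]
    }
    per_rep[[i]] <- row
  }
  per_rep <- do.call(rbind, per_rep)
  samples <- unique(per_rep$sample_id)
  summ <- list()
  agg <- function(v) {
    c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }
  for (s in samples) {
    sub <- per_rep[per_rep$sample_id == s, , drop = FALSE]
    tot <- agg(sub$total_pa_per_mg)
    row <- data.frame(sample_id = s, n_replicates = nrow(sub),
                      total_pa_per_mg_mean = tot[["mean"]],
                      total_pa_per_mg_sd = tot[["sd"]],
                      stringsAsFactors = FALSE)
    for (p in proteins) {
      comp <- sub[[paste0("pct_", p)]]
      comp_ok <- comp[!is.na(comp)]
      a <- if (length(comp_ok) > 0L) agg(comp_ok) else c(mean = NA_real_, sd = NA_real_)
      row[[paste0("pct_", p, "_mean")]] <- a[["mean"]]
      row[[paste0("pct_", p, "_sd")]] <- a[["sd"]]
    }
    summ[[length(summ) + 1L]] <- row
  }
  structure(list(per_replicate = per_rep, summary = do.call(rbind, summ),
                 proteins = proteins, effective_mg = eff_mg),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<relative quantification> %d sample(s), proteins: %s\n",
              nrow(x$summary), paste(x$proteins, collapse = ", ")))
  cat(sprintf("effective flour mass per injection: %.4g mg\n", x$effective_mg))
  print.data.frame(x$summary, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Write a quantification result
#'
#' `write_quant_result()` writes the per-sample summary as CSV and, with a
#' `.json` path, the full result (per-replicate and summary) as JSON.
#'
#' @param x A `quant_result`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_quant_result <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(effective_mg = x$effective_mg, proteins = x$proteins,
           per_replicate = x$per_replicate, summary = x$summary),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(x$summary, path, row.names = FALSE)
  }
  invisible(path)
}

#' Per-condition mean and SD of peak areas
#'
#' Aggregates one or more measurement tables labelled by condition into a
#' long-format table of mean and sample SD per condition x analyte (the
#' numeric substrate of a grouped bar chart; inference is out of scope).
#' Conditions with a single observation report `NA` SD.
#'
#' @param tables Named list of `measurement_table`s (names are condition
#'   labels), or a single table carrying a `condition` column.
#' @return A `data.frame` with columns `condition`, `analyte_id`, `n`,
#'   `mean_pa`, `sd_pa`.
#' @export
group_summary <- function(tables) {
  if (is.data.frame(tables)) {
    if (!"condition" %in% names(tables)) {
      stop("a single table must carry a 'condition' column", call. = FALSE)
    }
    df <- as.data.frame(tables)
  } else {
    if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
      stop("tables must be a named list (names = condition labels)",
           call. = FALSE)
    }
    df <- do.call(rbind, lapply(names(tables), function(cond) {
      cbind(condition = cond, as.data.frame(tables[[cond]]))
    }))
  }
  groups <- split(df$peak_area,
                  interaction(df$condition, df$analyte_id, drop = TRUE,
                              sep = "\001"))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    parts <- strsplit(g, "\001", fixed = TRUE)[[1L]]
    data.frame(condition = parts[1L],
               analyte_id = parts[2L],
               n = length(v), mean_pa = mean(v),
               sd_pa = if (length(v) > 1L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out[order(out$condition, out$analyte_id), , drop = FALSE]
}
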