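# Required monitoring columns of a record table (Table-2-style schema plus
# the meteorological fields used by the thermal comfort index).
RECORD_VARIABLES <- c("pm25", "no2", "pm10", "o3",
                      "heavy_metal", "dissolved_oxygen", "ph",
                      "organic_matter", "n_p", "noise_level")
MET_VARIABLES <- c("temperature", "wind_speed", "relative_humidity")

#' Assess one environmental record
#'
#' Runs a single multi-media monitoring record through the hierarchical
#' fuzzy tree: the four per-medium leaf systems produce sub-scores on
#' `[0, 1]`, the root system combines them into the comprehensive health
#' risk index, and the formula indices (overall air-quality sub-index,
#' thermal comfort, noise pollution, composite air-quality index) are
#' attached alongside. Deterministic: identical records give identical
#' assessments.
#'
#' @param record Named list or one-row data frame with the ten monitoring
#'   variables (`pm25, no2, pm10, o3, heavy_metal, dissolved_oxygen, ph,
#'   organic_matter, n_p, noise_level`), the meteorological fields
#'   (`temperature, wind_speed, relative_humidity`) and optionally `site`
#'   and `timestamp`.
#' @param tree A `fis_tree` (see [default_fis_tree()]).
#' @param tables Breakpoint tables, as from [default_breakpoints()].
#' @param noise_sources Optional data frame of the record's noise-source
#'   decomposition with columns `p` (contribution rate) and `d` (decibels);
#'   when absent the noise pollution index falls back to the record's
#'   overall `noise_level`.
#' @param tci_form Passed to [compute_tci()].
#' @return List of class `risk_assessment_record`: `site`, `timestamp`,
#'   `risk`, `sub_scores`, `indices` (`iaqi`, `tci`, `npi`, `i_sum`) and
#'   `trace` (fired-rule strengths per tree node).
#' @export
assess_record <- function(record, tree = default_fis_tree(),
                          tables = default_breakpoints(),
                          noise_sources = NULL,
                          tci_form = c("ratio", "additive")) {
  tci_form <- match.arg(tci_form)
  stopifnot(inherits(tree, "fis_tree"))
  record <- as.list(record)
  missing <- setdiff(c(RECORD_VARIABLES, MET_VARIABLES), names(record))
  if (length(missing)) {
    uh_stop(sprintf("record missing variable(s): %s",
                    paste(missing, collapse = ", ")), "contract_error")
  }
  validate_record(record)
  trace <- list()
  subs <- vapply(names(tree$leaves), function(m) {
    r <- evaluate_fis(tree$leaves[[m]],
                      record[names(tree$leaves[[m]]$inputs)])
    trace[[m]] <<- r$trace
    r$output
  }, 0)
  root <- evaluate_fis(tree$root, as.list(subs))
  trace[["root"]] <- root$trace

  panel <- unlist(record[c("pm25", "no2", "pm10", "o3")])
  iaqi <- tryCatch(compute_overall_iaqi(panel, tables)$value,
                   above_scale = function(e) {
                     uh_warn("above-scale concentration capped at max index",
                             "above_scale_capped")
                     e$max_index
                   })
  npi <- if (!is.null(noise_sources) && nrow(noise_sources) > 0) {
    compute_npi(noise_sources$p, noise_sources$d)
  } else {
    record$noise_level
  }
  structure(list(
    site = if (is.null(record$site)) NA_character_ else record$site,
    timestamp = if (is.null(record$timestamp)) NA_character_
                else record$timestamp,
    risk = root$output,
    sub_scores = subs,
    indices = c(
      iaqi = iaqi,
      tci = compute_tci(record$temperature, record$wind_speed,
                        record$relative_humidity, form = tci_form),
      npi = npi,
      i_sum = compute_composite_index(panel, tables)
    ),
    trace = trace
  ), class = "risk_assessment_record")
}

validate_record <- function(record) {
  conc <- c("pm25", "no2", "pm10", "o3", "heavy_metal", "dissolved_oxygen",
            "organic_matter", "n_p", "noise_level")
  for (v in conc) {
    if (is.na(record[[v]]) || record[[v]] < 0) {
      uh_stop(sprintf("'%s' must be nonnegative", v), "domain_error")
    }
  }
  if (is.na(record$ph) || record$ph < 0 || record$ph > 14) {
    uh_stop("'ph' must lie in [0, 14]", "domain_error")
  }
  invisible(record)
}

#' Assess a batch of records
#'
#' Element-wise, order-preserving assessment of a record table; equivalent
#' to calling [assess_record()] per row but evaluated with the vectorised
#' fuzzy engine. Missing values are handled per the `missing` policy:
#' `"impute"` replaces them by the batch median of the column (with a
#' warning), `"error"` rejects the batch.
#'
#' @param records Data frame with one row per (site, timestamp) and the
#'   columns listed under [assess_record()].
#' @param noise Optional long-format noise decomposition with columns
#'   `site, timestamp, source_id, p, d`, matched to records by
#'   (site, timestamp).
#' @param missing Missing-value policy.
#' @inheritParams assess_record
#' @return Data frame of class `risk_assessment`: one row per record with
#'   `site`, `timestamp`, `risk`, the four sub-scores (`air, water, soil,
#'   noise`), and `iaqi, tci, npi, i_sum`. Per-site mean risk is attached
#'   as attribute `"site_summary"`.
#' @export
assess_batch <- function(records, tree = default_fis_tree(),
                         tables = default_breakpoints(), noise = NULL,
                         tci_form = c("ratio", "additive"),
                         missing = c("impute", "error")) {
  tci_form <- match.arg(tci_form)
  missing <- match.arg(missing)
  stopifnot(inherits(tree, "fis_tree"))
  records <- as.data.frame(records)
  if (nrow(records) == 0L) uh_stop("empty record batch", "domain_error")
  need <- c(RECORD_VARIABLES, MET_VARIABLES)
  miss_cols <- setdiff(need, names(records))
  if (length(miss_cols)) {
    uh_stop(sprintf("records missing column(s): %s",
                    paste(miss_cols, collapse = ", ")), "contract_error")
  }
  for (v in need) {
    if (anyNA(records[[v]])) {
      if (missing == "error") {
        uh_stop(sprintf("missing values in '%s'", v), "missing_value")
      }
      med <- stats::median(records[[v]], na.rm = TRUE)
      if (is.na(med)) {
        uh_stop(sprintf("column '%s' entirely missing", v), "missing_value")
      }
      uh_warn(sprintf("imputed %d missing value(s) in '%s' with the batch median",
                      sum(is.na(records[[v]])), v), "missing_imputed")
      records[[v]][is.na(records[[v]])] <- med
    }
  }
  for (i in seq_len(nrow(records))) {
    validate_record(as.list(records[i, need]))
  }

  subs <- vapply(names(tree$leaves), function(m) {
    evaluate_fis_batch(tree$leaves[[m]], records)
  }, numeric(nrow(records)))
  if (nrow(records) == 1L) subs <- matrix(subs, nrow = 1,
                                          dimnames = list(NULL, names(tree$leaves)))
  risk <- evaluate_fis_batch(tree$root, as.data.frame(subs))

  iaqi <- vapply(seq_len(nrow(records)), function(i) {
    panel <- unlist(records[i, c("pm25", "no2", "pm10", "o3")])
    tryCatch(compute_overall_iaqi(panel, tables)$value,
             above_scale = function(e) e$max_index)
  }, 0)
  i_sum <- vapply(seq_len(nrow(records)), function(i) {
    compute_composite_index(unlist(records[i, c("pm25", "no2", "pm10", "o3")]),
                            tables)
  }, 0)
  tci <- vapply(seq_len(nrow(records)), function(i) {
    compute_tci(records$temperature[i], records$wind_speed[i],
                records$relative_humidity[i], form = tci_form)
  }, 0)

  site <- if ("site" %in% names(records)) as.character(records$site)
          else rep(NA_character_, nrow(records))
  timestamp <- if ("timestamp" %in% names(records))
                 as.character(records$timestamp)
               else rep(NA_character_, nrow(records))
  npi <- records$noise_level
  if (!is.null(noise) && nrow(noise) > 0) {
    key <- paste(site, timestamp, sep = "\r")
    nkey <- paste(as.character(noise$site), as.character(noise$timestamp),
                  sep = "\r")
    agg <- tapply(seq_len(nrow(noise)), nkey, function(ix) {
      compute_npi(noise$p[ix], noise$d[ix])
    })
    hit <- match(key, names(agg))
    npi[!is.na(hit)] <- unlist(agg)[hit[!is.na(hit)]]
  }

  out <- data.frame(site = site, timestamp = timestamp, risk = risk,
                    as.data.frame(subs), iaqi = iaqi, tci = tci,
                    npi = npi, i_sum = i_sum)
  attr(out, "site_summary") <- stats::aggregate(
    out["risk"], by = list(site = out$site), FUN = mean)
  class(out) <- c("risk_assessment", "data.frame")
  out
}

#' @export
print.risk_assessment_record <- function(x, ...) {
  cat(sprintf("<risk_assessment site=%s time=%s>\n", x$site, x$timestamp))
  cat(sprintf("  risk: %.4f\n", x$risk))
  cat("  sub-scores:",
      paste(sprintf("%s=%.3f", names(x$sub_scores), x$sub_scores),
            collapse = ", "), "\n")
  cat("  indices:   ",
      paste(sprintf("%s=%.3f", names(x$indices), x$indices),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment: %d record(s), mean risk %.4f>\n",
              nrow(x), mean(x$risk)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.risk_assessment <- function(object, ...) {
  cat(sprintf("Risk assessment of %d record(s)\n", nrow(object)))
  print(summary(object$risk))
  cat("\nPer-site mean risk:\n")
  print(attr(object, "site_summary"), row.names = FALSE, digits = 4)
  invisible(attr(object, "site_summary"))
}

#' Predict method for the fuzzy risk tree
#'
#' Convenience wrapper so a `fis_tree` behaves like a fitted model:
#' `predict(tree, records)` is [assess_batch()].
#'
#' @param object A `fis_tree`.
#' @param newdata Record data frame.
#' @param ... Passed to [assess_batch()].
#' @export
predict.fis_tree <- function(object, newdata, ...) {
  assess_batch(newdata, tree = object, ...)
}
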