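#' Bootstrap credibility interval for the mean risk
#'
#' Percentile bootstrap confidence ("credibility") interval on the mean of
#' the model's risk outputs: the risks are resampled with replacement
#' `n_boot` times and the empirical `alpha/2` and `1 - alpha/2` quantiles
#' of the resampled means form the interval. A bias-corrected and
#' accelerated (BCa) variant is available via `method = "bca"`.
#'
#' @param risks Numeric vector of risk values (length >= 10).
#' @param level Confidence level in (0, 1), typically 0.90 or 0.95.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Optional integer seed; fixed seeds give bit-reproducible
#'   intervals, and intervals at nested levels computed from the same seed
#'   share resamples, so the 95% interval contains the 90% one.
#' @param method `"percentile"` (default) or `"bca"`.
#' @return List of class `credibility_result` with `level`, `lower`,
#'   `upper`, `point` (mean risk), `n_boot`, `method`, `seed`.
#' @export
credibility_interval <- function(risks, level = 0.95, n_boot = 2000,
                                 seed = NULL,
                                 method = c("percentile", "bca")) {
  method <- match.arg(method)
  stopifnot(is.numeric(risks))
  if (length(risks) < 10L) {
    uh_stop("need at least 10 risk values", "domain_error")
  }
  check_number(level, "level")
  if (level <= 0 || level >= 1) {
    uh_stop("`level` must lie strictly in (0, 1)", "domain_error")
  }
  if (n_boot < 200L) uh_stop("`n_boot` must be >= 200", "domain_error")
  n <- length(risks)
  means <- with_seed(seed, {
    colMeans(matrix(risks[sample.int(n, n * n_boot, replace = TRUE)],
                    nrow = n))
  })
  alpha <- 1 - level
  if (method == "percentile") {
    q <- stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else {
    # BCa: bias correction from the resample distribution, acceleration
    # from the jackknife skewness of the mean
    theta <- mean(risks)
    z0 <- stats::qnorm(clamp(mean(means < theta), 1 / n_boot,
                             1 - 1 / n_boot))
    jack <- (sum(risks) - risks) / (n - 1)
    d <- mean(jack) - jack
    denom <- 6 * sum(d^2)^1.5
    a <- if (denom == 0) 0 else sum(d^3) / denom
    zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    q <- stats::quantile(means, adj, names = FALSE)
  }
  structure(list(level = level, lower = q[1], upper = q[2],
                 point = mean(risks), n_boot = n_boot, method = method,
                 seed = seed),
            class = "credibility_result")
}

#' Applicability metrics: RMSE, R-squared, residual magnitude
#'
#' Model-fit metrics comparing predicted against observed risk:
#' root mean square error, coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, and the scalar residual magnitude
#' reported as the mean absolute residual (the mean signed residual is
#' also returned for transparency). By Jensen's inequality the RMSE always
#' dominates the mean absolute residual; this is asserted on every call.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2);
#'   `observed` must have nonzero variance for R-squared.
#' @return List of class `applicability_metrics` with `rmse`, `r_squared`,
#'   `mean_abs_residual`, `mean_residual`, `n`.
#' @export
applicability_metrics <- function(predicted, observed) {
  stopifnot(is.numeric(predicted), is.numeric(observed))
  if (length(predicted) != length(observed) || length(observed) < 2L) {
    uh_stop("predicted and observed must have equal length >= 2",
            "domain_error")
  }
  if (anyNA(predicted) || anyNA(observed)) {
    uh_stop("missing values in predicted/observed", "domain_error")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    uh_stop("observed values have zero variance; R-squared undefined",
            "degenerate_input")
  }
  res <- predicted - observed
  out <- list(
    rmse = sqrt(mean(res^2)),
    r_squared = 1 - sum(res^2) / ss_tot,
    mean_abs_residual = mean(abs(res)),
    mean_residual = mean(res),
    n = length(observed)
  )
  stopifnot(out$rmse >= out$mean_abs_residual - 1e-12)
  structure(out, class = "applicability_metrics")
}

#' Correlation screen of environmental factors against risk
#'
#' Pearson (or Spearman) correlation of each factor column against the
#' risk vector, with pairwise-complete handling of missing values.
#' Constant factors are reported as `NA` with a flag rather than dropped.
#'
#' @param factors Data frame of factor columns (environmental variables
#'   and/or indices).
#' @param risks Numeric risk vector, `nrow(factors)` long.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame of class `correlation_table` with `factor`, `r`,
#'   `n` (complete pairs) and `flag`.
#' @export
correlation_analysis <- function(factors, risks,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  factors <- as.data.frame(factors)
  stopifnot(is.numeric(risks), nrow(factors) == length(risks))
  rows <- lapply(names(factors), function(f) {
    x <- as.numeric(factors[[f]])
    ok <- stats::complete.cases(x, risks)
    n <- sum(ok)
    if (n < 3L) {
      return(data.frame(factor = f, r = NA_real_, n = n,
                        flag = "too_few_pairs"))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(risks[ok]) == 0) {
      return(data.frame(factor = f, r = NA_real_, n = n,
                        flag = "constant"))
    }
    data.frame(factor = f,
               r = stats::cor(x[ok], risks[ok], method = method),
               n = n, flag = "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Permutation significance test of an index against risk
#'
#' Tests whether a health indicator (e.g. the air-quality sub-index,
#' thermal comfort index or noise pollution index) is associated with the
#' model's risk output. The statistic is the absolute Pearson correlation;
#' its null distribution is obtained by randomly permuting the index
#' values, and the p-value uses add-one smoothing,
#' \deqn{p = \frac{1 + \#\{|r_{perm}| \ge |r_{obs}|\}}{n_{perm} + 1},}
#' so it is never exactly zero and has resolution `1/(n_permutations + 1)`.
#'
#' @param index_values Numeric indicator values (length >= 10, non-constant).
#' @param risks Numeric risk vector, equal length.
#' @param n_permutations Number of permutations (>= 999).
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `significance_result` with `statistic` (observed
#'   `|r|`), `p_value`, `n_permutations`, `n`, `seed`.
#' @export
significance_test <- function(index_values, risks, n_permutations = 999,
                              seed = NULL) {
  stopifnot(is.numeric(index_values), is.numeric(risks))
  n <- length(risks)
  if (length(index_values) != n || n < 10L) {
    uh_stop("index and risks must have equal length >= 10", "domain_error")
  }
  if (n_permutations < 999L) {
    uh_stop("`n_permutations` must be >= 999", "domain_error")
  }
  if (stats::sd(index_values) == 0 || stats::sd(risks) == 0) {
    uh_stop("constant input: correlation test degenerate",
            "degenerate_input")
  }
  xs <- (index_values - mean(index_values)) / stats::sd(index_values)
  ys <- (risks - mean(risks)) / stats::sd(risks)
  obs <- abs(sum(xs * ys) / (n - 1))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      abs(sum(xs[sample.int(n)] * ys) / (n - 1)) >= obs
    }, TRUE))
  })
  structure(list(statistic = obs,
                 p_value = (1 + exceed) / (n_permutations + 1),
                 n_permutations = n_permutations, n = n, seed = seed),
            class = "significance_result")
}

#' Full evaluation report for a city batch
#'
#' Bundles the three-part evaluation protocol applied to an assessed
#' batch: (1) credibility — bootstrap intervals on the mean risk at the
#' 90% and 95% levels; (2) correlation — each environmental factor and
#' each indicator (IAQI, TCI, NPI) against the risk output; significance —
#' permutation p-values for the three indicators (raw, plus Holm-adjusted
#' for transparency); (3) applicability — RMSE, R-squared and residual
#' magnitude of the risk output against an observed risk reference.
#'
#' @param assessments A `risk_assessment` data frame from [assess_batch()].
#' @param observed_risk Observed/reference risk values aligned with
#'   `assessments` (e.g. the planted latent risk of a synthetic batch), or
#'   `NULL` to skip the applicability section.
#' @param factors Optional data frame of environmental factor columns
#'   aligned with `assessments` (typically the record table); `NULL` gives
#'   an empty correlation section with a warning.
#' @param levels Credibility levels.
#' @param n_boot,n_permutations Resampling sizes.
#' @param seed Integer seed; component seeds are derived from it.
#' @param cor_method Correlation type for the correlation section.
#' @return List of class `evaluation_report` with sections `credibility`,
#'   `correlation`, `significance`, `applicability` and `config`.
#' @export
evaluate_city <- function(assessments, observed_risk = NULL, factors = NULL,
                          levels = c(0.90, 0.95), n_boot = 2000,
                          n_permutations = 999, seed = 1,
                          cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  stopifnot(is.data.frame(assessments),
            all(c("risk", "iaqi", "tci", "npi") %in% names(assessments)))
  risks <- assessments$risk

  credibility <- lapply(levels, function(lv) {
    credibility_interval(risks, level = lv, n_boot = n_boot, seed = seed)
  })
  names(credibility) <- sprintf("level_%g", levels)

  cor_factors <- NULL
  if (!is.null(factors)) {
    cor_factors <- as.data.frame(factors)
    cor_factors <- cor_factors[vapply(cor_factors, is.numeric, TRUE)]
  }
  idx_factors <- assessments[c("iaqi", "tci", "npi")]
  cor_factors <- if (is.null(cor_factors) || !ncol(cor_factors)) idx_factors
                 else cbind(cor_factors, idx_factors)
  if (is.null(factors)) {
    uh_warn("no factor table supplied; correlation section covers indices only",
            "empty_factors")
  }
  correlation <- correlation_analysis(cor_factors, risks,
                                      method = cor_method)

  significance <- lapply(c(iaqi = "iaqi", tci = "tci", npi = "npi"),
                         function(ix) {
    significance_test(assessments[[ix]], risks,
                      n_permutations = n_permutations,
                      seed = seed + match(ix, c("iaqi", "tci", "npi")))
  })
  praw <- vapply(significance, `[[`, 0, "p_value")
  holm <- stats::p.adjust(praw, method = "holm")
  for (ix in names(significance)) {
    significance[[ix]]$p_holm <- unname(holm[ix])
  }

  applicability <- NULL
  if (!is.null(observed_risk)) {
    if (length(observed_risk) != length(risks)) {
      uh_stop("observed_risk must align with assessments", "contract_error")
    }
    applicability <- applicability_metrics(risks, observed_risk)
  }

  structure(list(
    credibility = credibility,
    correlation = correlation,
    significance = significance,
    applicability = applicability,
    config = list(levels = levels, n_boot = n_boot,
                  n_permutations = n_permutations, seed = seed,
                  cor_method = cor_method, n = length(risks),
                  package_version = as.character(utils::packageVersion("urbanhealth")))
  ), class = "evaluation_report")
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path; the JSON embeds the report's configuration and
#'   the package version, and is byte-identical across reruns with the
#'   same inputs and seeds.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- list(
    credibility = lapply(report$credibility, unclass),
    correlation = as.data.frame(report$correlation),
    significance = lapply(report$significance, unclass),
    applicability = if (!is.null(report$applicability))
      unclass(report$applicability),
    config = report$config
  )
  out$config$config_hash <- config_hash(report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @export
print.credibility_result <- function(x, ...) {
  cat(sprintf(
    "%.0f%% credibility interval for mean risk: [%.4f, %.4f] (point %.4f, %s, B=%d)\n",
    100 * x$level, x$lower, x$upper, x$point, x$method, x$n_boot))
  invisible(x)
}

#' @export
print.applicability_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4f | R^2 %.4f | mean |resid| %.4f (n = %d)\n",
              x$rmse, x$r_squared, x$mean_abs_residual, x$n))
  invisible(x)
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("permutation test: |r| = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("== Evaluation report ==\n-- credibility --\n")
  for (ci in x$credibility) print(ci)
  cat("-- significance --\n")
  for (nm in names(x$significance)) {
    s <- x$significance[[nm]]
    cat(sprintf("  %-5s |r| = %.3f, p = %.4g (holm %.4g)\n",
                nm, s$statistic, s$p_value, s$p_holm))
  }
  cat("-- correlation (|r| top 5) --\n")
  tab <- x$correlation[order(-abs(x$correlation$r)), ]
  print(utils::head(as.data.frame(tab), 5), row.names = FALSE, digits = 3)
  if (!is.null(x$applicability)) {
    cat("-- applicability --\n  ")
    print(x$applicability)
  }
  invisible(x)
}
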