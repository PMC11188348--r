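# Internal helpers: structured conditions, seed scoping, small validators.

uh_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "urbanhealth_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

uh_warn <- function(message, class) {
  warning(structure(
    class = c(class, "urbanhealth_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @noRd
#' Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_number <- function(x, name, lo = -Inf, hi = Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    uh_stop(sprintf("`%s` must be a single number", name), "domain_error")
  }
  if (!is.na(x) && (x < lo || x > hi)) {
    uh_stop(sprintf("`%s` must lie in [%s, %s], got %s", name, lo, hi, x),
            "domain_error")
  }
  invisible(x)
}

# md5 of a canonical JSON rendering; used to stamp artifacts for reproducibility
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
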