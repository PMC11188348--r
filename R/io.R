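the_cache <- new.env(parent = emptyenv())

#' Default breakpoint tables
#'
#' Loads (and caches) the breakpoint/standard configuration shipped with
#' the package; see `inst/extdata/breakpoints.yaml`. Values follow the
#' Chinese ambient air-quality grading; all tables are user-overridable
#' via [read_breakpoints()].
#'
#' @return Named list of [breakpoint_table()]s.
#' @export
default_breakpoints <- function() {
  if (is.null(the_cache$breakpoints)) {
    the_cache$breakpoints <- read_breakpoints(
      system.file("extdata", "breakpoints.yaml", package = "urbanhealth"))
  }
  the_cache$breakpoints
}

#' Read and write breakpoint configurations
#'
#' YAML schema: a `pollutants` map of
#' `{units, s_p, rows: [[c_low, c_high, i_low, i_high], ...]}` entries.
#' Every table is validated on load (sorted contiguous rows, positive
#' standards).
#'
#' @param path YAML file path.
#' @return `read_breakpoints()` returns a named list of
#'   [breakpoint_table()]s; `write_breakpoints()` returns `path`
#'   invisibly.
#' @export
read_breakpoints <- function(path) {
  if (!file.exists(path)) {
    uh_stop(sprintf("breakpoints file not found: %s", path), "config_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pollutants)) {
    uh_stop("breakpoints YAML needs a 'pollutants' map", "config_error")
  }
  out <- lapply(names(cfg$pollutants), function(p) {
    entry <- cfg$pollutants[[p]]
    rows <- do.call(rbind, entry$rows)
    colnames(rows) <- c("c_low", "c_high", "i_low", "i_high")
    breakpoint_table(p, rows, s_p = entry$s_p,
                     units = if (is.null(entry$units)) "ug/m3"
                             else entry$units)
  })
  names(out) <- names(cfg$pollutants)
  out
}

#' @rdname read_breakpoints
#' @param tables Named list of [breakpoint_table()]s.
#' @export
write_breakpoints <- function(tables, path) {
  pollutants <- lapply(tables, function(t) {
    list(units = t$units, s_p = t$s_p,
         rows = lapply(seq_len(nrow(t$rows)),
                       function(i) as.numeric(t$rows[i, ])))
  })
  yaml::write_yaml(list(schema_version = 1, pollutants = pollutants), path)
  invisible(path)
}

#' Read a monitoring record table
#'
#' Reads a record CSV (one row per site and timestamp, columns for the ten
#' monitoring variables plus `temperature, wind_speed, relative_humidity`)
#' and optionally the companion long-format noise decomposition
#' (`site, timestamp, source_id, p, d`). Rows failing validation
#' (unparseable cells, negative concentrations, pH outside `[0, 14]`) are
#' collected in the `"validation"` attribute, not silently dropped.
#' Comment lines starting with `#` (artifact stamps) are skipped.
#'
#' @param path Records CSV path.
#' @param noise_path Optional noise CSV path.
#' @return Data frame of valid records; attributes `"validation"` (data
#'   frame of rejected rows with reasons) and, if requested, `"noise"`
#'   (the noise table).
#' @export
read_records <- function(path, noise_path = NULL) {
  if (!file.exists(path)) {
    uh_stop(sprintf("records file not found: %s", path), "io_error")
  }
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  need <- c(RECORD_VARIABLES, MET_VARIABLES)
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    uh_stop(sprintf("records file missing required column(s): %s",
                    paste(missing, collapse = ", ")), "schema_error")
  }
  problems <- list()
  for (v in need) {
    orig <- raw[[v]]
    num <- suppressWarnings(as.numeric(orig))
    bad <- which(is.na(num) & !is.na(orig) & nzchar(trimws(orig)))
    for (i in bad) {
      problems[[length(problems) + 1L]] <-
        data.frame(row = i, column = v,
                   reason = sprintf("unparseable value '%s'", orig[i]))
    }
    raw[[v]] <- num
  }
  nonneg <- setdiff(need, c("ph", "temperature"))
  for (v in nonneg) {
    bad <- which(raw[[v]] < 0)
    for (i in bad) {
      problems[[length(problems) + 1L]] <-
        data.frame(row = i, column = v, reason = "negative value")
    }
  }
  bad_ph <- which(raw$ph < 0 | raw$ph > 14)
  for (i in bad_ph) {
    problems[[length(problems) + 1L]] <-
      data.frame(row = i, column = "ph", reason = "pH outside [0, 14]")
  }
  validation <- if (length(problems)) do.call(rbind, problems)
                else data.frame(row = integer(), column = character(),
                                reason = character())
  keep <- setdiff(seq_len(nrow(raw)), unique(validation$row))
  records <- raw[keep, , drop = FALSE]
  rownames(records) <- NULL
  if (nrow(validation)) {
    uh_warn(sprintf("%d row(s) failed validation; see attr(x, 'validation')",
                    length(unique(validation$row))), "rows_rejected")
  }
  attr(records, "validation") <- validation
  if (!is.null(noise_path)) {
    noise <- utils::read.csv(noise_path, comment.char = "#",
                             stringsAsFactors = FALSE)
    nneed <- c("site", "timestamp", "source_id", "p", "d")
    if (!all(nneed %in% names(noise))) {
      uh_stop(sprintf("noise file missing column(s): %s",
                      paste(setdiff(nneed, names(noise)), collapse = ", ")),
              "schema_error")
    }
    attr(records, "noise") <- noise
  }
  records
}

#' Write a table as a stamped CSV artifact
#'
#' Writes `x` as CSV preceded by a `#` comment line embedding the package
#' version and a configuration hash, so every emitted artifact records its
#' provenance; [read_records()] skips such lines.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config Configuration object hashed into the stamp (may be NULL).
#' @return `path`, invisibly.
#' @export
write_stamped_csv <- function(x, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# urbanhealth %s config=%s",
                     as.character(utils::packageVersion("urbanhealth")),
                     config_hash(config)), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Serialize a fuzzy system or tree to YAML
#'
#' Round-trippable YAML representation: each variable carries its universe
#' and term membership parameters, each rule its antecedent map,
#' consequent (label or crisp level) and weight.
#'
#' @param tree A `fis_tree`.
#' @param path YAML path.
#' @return `write_fis_tree()` returns `path` invisibly; `read_fis_tree()`
#'   the reconstructed `fis_tree`.
#' @export
write_fis_tree <- function(tree, path) {
  stopifnot(inherits(tree, "fis_tree"))
  yaml::write_yaml(list(
    schema_version = 1,
    leaves = lapply(tree$leaves, system_to_list),
    root = system_to_list(tree$root)
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_fis_tree
#' @export
read_fis_tree <- function(path) {
  if (!file.exists(path)) {
    uh_stop(sprintf("tree file not found: %s", path), "config_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$leaves) || is.null(cfg$root)) {
    uh_stop("tree YAML needs 'leaves' and 'root'", "config_error")
  }
  leaves <- lapply(cfg$leaves, system_from_list)
  new_fis_tree(leaves, system_from_list(cfg$root))
}

mf_to_list <- function(mf) unclass(mf)

mf_from_list <- function(x) {
  switch(x$type,
    sigmoid = mf_sigmoid(x$center, x$steepness, x$base),
    gaussian = mf_gaussian(x$center, x$sigma),
    triangular = mf_triangular(x$left, x$peak, x$right),
    uh_stop(sprintf("unknown membership type '%s'", x$type), "config_error")
  )
}

variable_to_list <- function(v) {
  list(name = v$name, universe = as.numeric(v$universe),
       terms = lapply(v$terms, mf_to_list))
}

variable_from_list <- function(x) {
  fuzzy_variable(x$name, unlist(x$universe), lapply(x$terms, mf_from_list))
}

system_to_list <- function(s) {
  list(
    inputs = lapply(unname(s$inputs), variable_to_list),
    output = variable_to_list(s$output),
    rules = lapply(s$rules, function(r) {
      list(`if` = as.list(r$antecedent), then = r$consequent,
           weight = r$weight)
    }),
    and = s$and_op
  )
}

system_from_list <- function(x) {
  fuzzy_system(
    lapply(x$inputs, variable_from_list),
    variable_from_list(x$output),
    lapply(x$rules, function(r) {
      ante <- unlist(r$`if`)
      fuzzy_rule(ante, if (is.numeric(r$then)) r$then
                       else as.character(r$then),
                 weight = if (is.null(r$weight)) 1 else r$weight)
    }),
    and_op = if (is.null(x$and)) "product" else x$and
  )
}

#' Run the full assessment pipeline
#'
#' synth (optional) -> assess -> evaluate, with every artifact written to
#' disk: the record/noise/latent CSVs (when synthesised), the per-record
#' assessment CSV and the JSON evaluation report. Each stage is logged to
#' stderr with the seeds in effect, and every artifact embeds the package
#' version and the hash of the effective configuration, so a rerun with an
#' identical configuration reproduces the artifacts byte for byte.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   `out_dir` (required); either `profile` (shipped archetype name or
#'   profile YAML) with `n` to synthesise records, or `records` (CSV path,
#'   optionally `noise`, `observed`) to assess existing data; optional
#'   `tree` (tree YAML; default [default_fis_tree()]), `breakpoints`
#'   (YAML; default shipped), `seed` (default 1), `n_boot`, `n_permutations`,
#'   `levels`, `tci_form`, `cor_method`, `missing`, `quiet`.
#' @return Invisibly, a list with the `report`, the `assessments` and the
#'   paths of all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      uh_stop(sprintf("config file not found: %s", config), "config_error")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(n = 500, seed = 1, n_boot = 2000, n_permutations = 999,
                   levels = c(0.90, 0.95), tci_form = "ratio",
                   cor_method = "pearson", missing = "impute",
                   quiet = FALSE)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$out_dir)) {
    uh_stop("config needs 'out_dir'", "config_error")
  }
  log_stage <- function(fmt, ...) {
    if (!isTRUE(config$quiet)) {
      message(sprintf(paste0("[urbanhealth] ", fmt), ...))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- if (is.null(config$breakpoints)) default_breakpoints()
            else read_breakpoints(config$breakpoints)
  tree <- if (is.null(config$tree)) default_fis_tree()
          else read_fis_tree(config$tree)
  paths <- list()
  # hash the analysis configuration only, not the artifact location
  cfg_hashable <- config[setdiff(names(config), c("quiet", "out_dir"))]

  observed <- NULL
  noise <- NULL
  if (!is.null(config$records)) {
    log_stage("stage=read records=%s", config$records)
    records <- read_records(config$records, noise_path = config$noise)
    noise <- attr(records, "noise")
    if (!is.null(config$observed)) {
      obs_df <- utils::read.csv(config$observed, comment.char = "#")
      col <- intersect(c("observed_risk", "latent_risk", "risk"),
                       names(obs_df))
      if (!length(col)) {
        uh_stop("observed CSV needs an observed_risk/latent_risk column",
                "schema_error")
      }
      observed <- obs_df[[col[1]]]
    }
  } else {
    if (is.null(config$profile)) {
      uh_stop("config needs either 'records' or 'profile'", "config_error")
    }
    log_stage("stage=synth profile=%s n=%d seed=%d", config$profile,
              config$n, config$seed)
    batch <- generate_city(city_profile(config$profile), n = config$n,
                           seed = config$seed, tables = tables)
    records <- batch$records
    noise <- batch$noise
    observed <- batch$latent_risk
    paths$records <- write_stamped_csv(records,
                                       file.path(config$out_dir,
                                                 "records.csv"),
                                       cfg_hashable)
    paths$noise <- write_stamped_csv(noise,
                                     file.path(config$out_dir, "noise.csv"),
                                     cfg_hashable)
    paths$latent <- write_stamped_csv(
      data.frame(site = records$site, timestamp = records$timestamp,
                 latent_risk = observed),
      file.path(config$out_dir, "latent.csv"), cfg_hashable)
  }

  log_stage("stage=assess n=%d", nrow(records))
  assessments <- assess_batch(records, tree = tree, tables = tables,
                              noise = noise, tci_form = config$tci_form,
                              missing = config$missing)
  paths$assessments <- write_stamped_csv(
    assessments, file.path(config$out_dir, "assessments.csv"), cfg_hashable)

  log_stage("stage=evaluate boot=%d perms=%d seed=%d", config$n_boot,
            config$n_permutations, config$seed)
  report <- evaluate_city(assessments, observed_risk = observed,
                          factors = records[intersect(RECORD_VARIABLES,
                                                      names(records))],
                          levels = config$levels, n_boot = config$n_boot,
                          n_permutations = config$n_permutations,
                          seed = config$seed,
                          cor_method = config$cor_method)
  report$config$pipeline <- cfg_hashable
  paths$report <- file.path(config$out_dir, "report.json")
  write_report(report, paths$report)
  log_stage("stage=done artifacts=%d", length(paths))
  invisible(list(report = report, assessments = assessments, paths = paths))
}
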