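#' Default configuration of the hierarchical risk tree
#'
#' Returns the configuration list from which [default_fis_tree()] builds
#' the shipped assessment tree: per-variable universes and risk directions,
#' term-placement parameters, per-medium groupings and root media weights.
#' Universes cover plausible urban monitoring ranges; directions encode
#' whether larger values are more harmful (`increasing`), protective
#' (`decreasing`, dissolved oxygen) or harmful away from a neutral band
#' (`vshape`, pH). Media weights reflect the consensus ranking of urban
#' environmental health burdens (air pollution first, noise second, water
#' and soil smaller within-city contributions).
#'
#' @return A nested configuration list; edit and pass to
#'   [default_fis_tree()] to customise the tree.
#' @export
default_tree_config <- function() {
  list(
    variables = list(
      pm25             = list(medium = "air",   universe = c(0, 100),
                              direction = "increasing"),
      no2              = list(medium = "air",   universe = c(0, 80),
                              direction = "increasing"),
      pm10             = list(medium = "air",   universe = c(0, 160),
                              direction = "increasing"),
      o3               = list(medium = "air",   universe = c(0, 200),
                              direction = "increasing"),
      heavy_metal      = list(medium = "water", universe = c(0, 0.1),
                              direction = "increasing"),
      dissolved_oxygen = list(medium = "water", universe = c(0, 14),
                              direction = "decreasing"),
      ph               = list(medium = "water", universe = c(0, 14),
                              direction = "vshape"),
      organic_matter   = list(medium = "soil",  universe = c(0, 8),
                              direction = "increasing"),
      n_p              = list(medium = "soil",  universe = c(0, 1500),
                              direction = "increasing"),
      noise_level      = list(medium = "noise", universe = c(40, 90),
                              direction = "increasing")
    ),
    # sigmoid centers at 30%/70% of the universe, slope parameter on the
    # normalised axis; Gaussian 'medium' at midspan
    term_centers = c(low = 0.3, high = 0.7),
    steepness = 8,
    medium_sigma = 0.12,
    # pH neutral band parameters (universe units)
    ph = list(acid_center = 6.0, alk_center = 9.0, steepness = 4,
              neutral_center = 7.5, neutral_sigma = 1.0),
    # output/sub-score linguistic levels on [0, 1]
    levels = c(low = 0.1, medium = 0.5, high = 0.9),
    level_sigma = 0.15,
    media_weights = c(air = 0.35, water = 0.17, soil = 0.13, noise = 0.35),
    and_op = "product"
  )
}

# severity of each term (0 = benign, 1 = harmful) given the risk direction
term_severities <- function(direction) {
  switch(direction,
    increasing = c(low = 0, medium = 0.5, high = 1),
    decreasing = c(low = 1, medium = 0.5, high = 0),
    vshape     = c(acidic = 1, neutral = 0, alkaline = 1),
    uh_stop(sprintf("unknown direction '%s'", direction), "config_error")
  )
}

# input variable with low/medium/high terms (or acidic/neutral/alkaline
# for the V-shaped pH response)
build_input_variable <- function(name, cfg, config) {
  uni <- cfg$universe
  span <- uni[2] - uni[1]
  if (identical(cfg$direction, "vshape")) {
    p <- config$ph
    terms <- list(
      acidic   = mf_sigmoid(p$acid_center, -p$steepness, 1),
      neutral  = mf_gaussian(p$neutral_center, p$neutral_sigma),
      alkaline = mf_sigmoid(p$alk_center, p$steepness, 1)
    )
  } else {
    terms <- list(
      low    = mf_sigmoid(uni[1] + config$term_centers[["low"]] * span,
                          -config$steepness, span),
      medium = mf_gaussian(uni[1] + 0.5 * span, config$medium_sigma * span),
      high   = mf_sigmoid(uni[1] + config$term_centers[["high"]] * span,
                          config$steepness, span)
    )
  }
  fuzzy_variable(name, uni, terms)
}

# sub-score / risk variable on [0, 1]
build_score_variable <- function(name, config) {
  fuzzy_variable(name, c(0, 1), list(
    low    = mf_sigmoid(config$term_centers[["low"]], -config$steepness, 1),
    medium = mf_gaussian(0.5, config$medium_sigma),
    high   = mf_sigmoid(config$term_centers[["high"]], config$steepness, 1)
  ))
}

# output variable with Gaussian terms centred on the linguistic levels
build_output_variable <- function(name, config) {
  fuzzy_variable(name, c(0, 1), list(
    low    = mf_gaussian(config$levels[["low"]], config$level_sigma),
    medium = mf_gaussian(config$levels[["medium"]], config$level_sigma),
    high   = mf_gaussian(config$levels[["high"]], config$level_sigma)
  ))
}

# full monotone rule grid: one rule per combination of terms, crisp
# consequent level affine in the (weighted) mean term severity so that
# worse conditions always raise the consequent
build_rule_grid <- function(directions, config, var_weights = NULL) {
  lo <- config$levels[["low"]]; hi <- config$levels[["high"]]
  labels <- lapply(directions, function(d) names(term_severities(d)))
  names(labels) <- names(directions)
  grid <- expand.grid(labels, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (is.null(var_weights)) {
    var_weights <- rep(1, length(directions))
    names(var_weights) <- names(directions)
  }
  var_weights <- var_weights / sum(var_weights)
  lapply(seq_len(nrow(grid)), function(i) {
    ante <- unlist(grid[i, , drop = FALSE])
    sev <- sum(vapply(names(ante), function(v) {
      var_weights[[v]] * term_severities(directions[[v]])[[ante[[v]]]]
    }, 0))
    fuzzy_rule(ante, lo + (hi - lo) * sev, weight = 1)
  })
}

#' Build the default hierarchical assessment tree
#'
#' Constructs the shipped FIS tree: one fuzzy system per environmental
#' medium (air, water, soil, noise) mapping that medium's monitoring
#' variables to a sub-score on `[0, 1]`, and a root system combining the
#' four sub-scores into the comprehensive health risk index on `[0, 1]`.
#' Every rule base is a full monotone grid (worse environment implies a
#' higher crisp consequent), so the tree's risk output is non-decreasing in
#' every harmful-direction variable, non-increasing in dissolved oxygen,
#' and V-shaped in pH around the neutral band.
#'
#' The tree is this package's documented default — expert rule bases and
#' membership parameters for a given city should replace it via the same
#' constructors or a serialized tree file; all assessment and evaluation
#' functions take the tree as a parameter.
#'
#' @param config Configuration list as produced by [default_tree_config()];
#'   missing entries are filled with the defaults.
#' @return An object of class `fis_tree` with elements `leaves` (named list
#'   of per-medium `fuzzy_system`s), `root` (`fuzzy_system`) and
#'   `variables` (variable -> medium map used when assessing records).
#' @examples
#' tree <- default_fis_tree()
#' print(tree)
#' @export
default_fis_tree <- function(config = NULL) {
  base <- default_tree_config()
  if (!is.null(config)) {
    base[names(config)] <- config
  }
  config <- base
  media <- names(config$media_weights)
  vars_by_medium <- split(names(config$variables),
                          vapply(config$variables, `[[`, "", "medium"))
  missing <- setdiff(media, names(vars_by_medium))
  if (length(missing)) {
    uh_stop(sprintf("no variables configured for medium: %s",
                    paste(missing, collapse = ", ")), "config_error")
  }
  leaves <- lapply(media, function(m) {
    vars <- vars_by_medium[[m]]
    inputs <- lapply(vars, function(v) {
      build_input_variable(v, config$variables[[v]], config)
    })
    directions <- vapply(config$variables[vars], `[[`, "", "direction")
    names(directions) <- vars
    fuzzy_system(inputs, build_output_variable(m, config),
                 build_rule_grid(directions, config),
                 and_op = config$and_op)
  })
  names(leaves) <- media
  root_inputs <- lapply(media, build_score_variable, config = config)
  root_directions <- rep("increasing", length(media))
  names(root_directions) <- media
  root <- fuzzy_system(root_inputs, build_output_variable("risk", config),
                       build_rule_grid(root_directions, config,
                                       var_weights = config$media_weights),
                       and_op = config$and_op)
  new_fis_tree(leaves, root, config)
}

#' @rdname default_fis_tree
#' @param leaves Named list of per-medium `fuzzy_system`s.
#' @param root `fuzzy_system` over the leaf output names.
#' @export
new_fis_tree <- function(leaves, root, config = NULL) {
  stopifnot(is.list(leaves), length(leaves) >= 1L, !is.null(names(leaves)))
  for (s in leaves) stopifnot(inherits(s, "fuzzy_system"))
  stopifnot(inherits(root, "fuzzy_system"))
  leaf_out <- vapply(leaves, function(s) s$output$name, "")
  if (!setequal(names(root$inputs), unname(leaf_out))) {
    uh_stop("root input variables must match leaf output names",
            "config_error")
  }
  for (s in c(leaves, list(root))) {
    if (!isTRUE(all.equal(s$output$universe, c(0, 1)))) {
      uh_stop("all sub-scores and the risk output live on [0, 1]",
              "config_error")
    }
  }
  variables <- unlist(lapply(names(leaves), function(m) {
    v <- names(leaves[[m]]$inputs)
    stats::setNames(rep(m, length(v)), v)
  }))
  structure(list(leaves = leaves, root = root, variables = variables,
                 config = config),
            class = "fis_tree")
}

#' @export
print.fis_tree <- function(x, ...) {
  cat("<fis_tree>\n")
  for (m in names(x$leaves)) {
    s <- x$leaves[[m]]
    cat(sprintf("  leaf %-6s: %s -> %s (%d rules)\n", m,
                paste(names(s$inputs), collapse = ", "),
                s$output$name, length(s$rules)))
  }
  cat(sprintf("  root       : %s -> %s (%d rules)\n",
              paste(names(x$root$inputs), collapse = ", "),
              x$root$output$name, length(x$root$rules)))
  invisible(x)
}

#' @export
summary.fis_tree <- function(object, ...) {
  cat("Hierarchical fuzzy risk tree\n")
  print(object)
  cat("\nVariable universes:\n")
  for (m in names(object$leaves)) {
    for (v in object$leaves[[m]]$inputs) {
      cat(sprintf("  %-17s [%g, %g] (%s)\n", v$name,
                  v$universe[1], v$universe[2],
                  paste(names(v$terms), collapse = "/")))
    }
  }
  invisible(object)
}

#' Plot membership functions of a tree's variables
#'
#' @param x A `fis_tree`.
#' @param variables Which input variables to draw (default: all).
#' @param n Curve resolution.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fis_tree <- function(x, variables = names(x$variables), n = 200, ...) {
  vars <- lapply(names(x$leaves), function(m) x$leaves[[m]]$inputs)
  vars <- do.call(c, vars)
  vars <- vars[intersect(variables, names(vars))]
  if (!length(vars)) uh_stop("no matching variables to plot", "domain_error")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (v in vars) {
    xs <- seq(v$universe[1], v$universe[2], length.out = n)
    m <- vapply(v$terms, membership, numeric(n), x = xs)
    graphics::matplot(xs, m, type = "l", lty = 1, lwd = 2,
                      xlab = v$name, ylab = "membership",
                      main = v$name, ylim = c(0, 1), ...)
    graphics::legend("right", legend = names(v$terms), lty = 1,
                     col = seq_along(v$terms), cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Grid scan of tree monotonicity
#'
#' Scans each input variable on an equally spaced grid across its universe,
#' holding every other variable at its universe midpoint, and reports
#' whether the risk output respects the variable's configured direction
#' (non-decreasing, non-increasing, or V-shaped around the pH neutral
#' center).
#'
#' @param tree A `fis_tree` built by [default_fis_tree()] (the directions
#'   are read from its config).
#' @param n_grid Grid points per variable.
#' @return Data frame with `variable`, `direction` and logical `monotone`.
#' @export
tree_monotonicity <- function(tree, n_grid = 5) {
  stopifnot(inherits(tree, "fis_tree"))
  cfg <- tree$config
  if (is.null(cfg)) cfg <- default_tree_config()
  all_inputs <- do.call(c, lapply(tree$leaves, function(s) s$inputs))
  names(all_inputs) <- vapply(all_inputs, `[[`, "", "name")
  mid <- vapply(all_inputs, function(v) mean(v$universe), 0)
  res <- lapply(names(all_inputs), function(vn) {
    v <- all_inputs[[vn]]
    dir <- cfg$variables[[vn]]$direction
    grid <- seq(v$universe[1], v$universe[2], length.out = n_grid)
    risks <- vapply(grid, function(g) {
      rec <- as.list(mid)
      rec[[vn]] <- g
      assess_risk_values(tree, rec)
    }, 0)
    ok <- switch(dir,
      increasing = all(diff(risks) >= -1e-9),
      decreasing = all(diff(risks) <= 1e-9),
      vshape = {
        center <- cfg$ph$neutral_center
        all(diff(risks[grid <= center]) <= 1e-9) &&
          all(diff(risks[grid >= center]) >= -1e-9)
      },
      NA)
    data.frame(variable = vn, direction = dir, monotone = ok)
  })
  do.call(rbind, res)
}

# risk output of the tree for one named list of variable values
assess_risk_values <- function(tree, values) {
  subs <- vapply(names(tree$leaves), function(m) {
    evaluate_fis(tree$leaves[[m]], values[names(tree$leaves[[m]]$inputs)])$output
  }, 0)
  evaluate_fis(tree$root, as.list(subs))$output
}
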