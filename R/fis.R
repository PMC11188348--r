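#' Fuzzy variables, rules and systems
#'
#' A `fuzzy_variable` couples a named universe of discourse with a set of
#' linguistic terms (label -> membership function). A `fuzzy_rule` is a
#' conjunction of (variable, label) antecedents with either a linguistic
#' consequent label or a crisp consequent level, and a nonnegative weight.
#' A `fuzzy_system` bundles input variables, one output variable, a rule
#' base and the AND operator (`"product"` default, `"min"` available).
#'
#' Inference is zero-order Sugeno style: inputs are fuzzified term by term,
#' each rule fires with the AND-combination of its antecedent degrees times
#' its weight, and the crisp output is the firing-strength-weighted average
#' of the rules' crisp consequent levels,
#' \deqn{\mathrm{Output} = \sum_i w_i\,\mathrm{Output}_i \Big/ \sum_i w_i.}
#' A linguistic consequent's crisp level is the center of the output term's
#' membership function.
#'
#' @param name Variable name.
#' @param universe Length-2 numeric, the closed interval of admissible values.
#' @param terms Named list of `fuzzy_mf` objects, one per linguistic label.
#' @return `fuzzy_variable()` returns a `fuzzy_variable`;
#'   `fuzzy_rule()` a `fuzzy_rule`; `fuzzy_system()` a `fuzzy_system`.
#' @examples
#' v <- fuzzy_variable("x", c(0, 1), list(
#'   low  = mf_sigmoid(0.3, -12),
#'   high = mf_sigmoid(0.7, 12)))
#' out <- fuzzy_variable("y", c(0, 1), list(
#'   low = mf_gaussian(0.1, 0.15), high = mf_gaussian(0.9, 0.15)))
#' sys <- fuzzy_system(list(v), out, list(
#'   fuzzy_rule(c(x = "low"), "low"),
#'   fuzzy_rule(c(x = "high"), "high")))
#' evaluate_fis(sys, c(x = 0.9))$output
#' @export
fuzzy_variable <- function(name, universe, terms) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(universe) || length(universe) != 2L ||
      universe[1] >= universe[2]) {
    uh_stop("`universe` must be c(lo, hi) with lo < hi", "domain_error")
  }
  if (!is.list(terms) || length(terms) == 0L || is.null(names(terms)) ||
      anyDuplicated(names(terms)) || !all(nzchar(names(terms)))) {
    uh_stop("`terms` must be a non-empty uniquely named list", "domain_error")
  }
  for (tm in terms) stopifnot(inherits(tm, "fuzzy_mf"))
  structure(list(name = name, universe = as.numeric(universe), terms = terms),
            class = "fuzzy_variable")
}

#' @rdname fuzzy_variable
#' @param antecedent Named character vector, `c(variable = label, ...)`.
#' @param consequent A linguistic label of the output variable, or a single
#'   crisp numeric level.
#' @param weight Nonnegative rule weight.
#' @export
fuzzy_rule <- function(antecedent, consequent, weight = 1) {
  if (!is.character(antecedent) || is.null(names(antecedent)) ||
      length(antecedent) == 0L || anyDuplicated(names(antecedent))) {
    uh_stop("`antecedent` must be a named character vector c(var = label)",
            "domain_error")
  }
  if (!(is.character(consequent) || is.numeric(consequent)) ||
      length(consequent) != 1L) {
    uh_stop("`consequent` must be one label or one crisp level", "domain_error")
  }
  check_number(weight, "weight", lo = 0)
  structure(list(antecedent = antecedent, consequent = consequent,
                 weight = weight),
            class = "fuzzy_rule")
}

#' @rdname fuzzy_variable
#' @param inputs List of input `fuzzy_variable`s.
#' @param output Output `fuzzy_variable`.
#' @param rules List of `fuzzy_rule`s (at least one).
#' @param and_op AND operator for antecedent conjunction.
#' @export
fuzzy_system <- function(inputs, output, rules,
                         and_op = c("product", "min")) {
  and_op <- match.arg(and_op)
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  for (v in inputs) stopifnot(inherits(v, "fuzzy_variable"))
  stopifnot(inherits(output, "fuzzy_variable"))
  if (!is.list(rules) || length(rules) == 0L) {
    uh_stop("a fuzzy system needs at least one rule", "domain_error")
  }
  in_names <- vapply(inputs, `[[`, "", "name")
  if (anyDuplicated(in_names)) {
    uh_stop("duplicated input variable names", "domain_error")
  }
  names(inputs) <- in_names
  used <- character(0)
  for (r in rules) {
    stopifnot(inherits(r, "fuzzy_rule"))
    for (v in names(r$antecedent)) {
      if (!v %in% in_names) {
        uh_stop(sprintf("rule references unknown variable '%s'", v),
                "domain_error")
      }
      if (!r$antecedent[[v]] %in% names(inputs[[v]]$terms)) {
        uh_stop(sprintf("rule references unknown label '%s' of '%s'",
                        r$antecedent[[v]], v), "domain_error")
      }
    }
    if (is.character(r$consequent) &&
        !r$consequent %in% names(output$terms)) {
      uh_stop(sprintf("rule consequent label '%s' not in output terms",
                      r$consequent), "domain_error")
    }
    used <- union(used, names(r$antecedent))
  }
  if (!all(in_names %in% used)) {
    uh_stop(sprintf("input variable(s) %s referenced by no rule",
                    paste(setdiff(in_names, used), collapse = ", ")),
            "domain_error")
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 and_op = and_op),
            class = "fuzzy_system")
}

#' Fuzzify a value against a variable's terms
#'
#' @param value Numeric vector of crisp values.
#' @param variable A `fuzzy_variable`.
#' @param clamp If `TRUE` (default) values outside the universe are clamped
#'   to it with a warning; if `FALSE` they raise an error. Monitoring data
#'   contain excursions, hence the lenient default.
#' @return For scalar `value`, a named vector of degrees (one per term); for
#'   vector input, a matrix with one row per value and one column per term.
#' @export
fuzzify <- function(value, variable, clamp = TRUE) {
  stopifnot(inherits(variable, "fuzzy_variable"), is.numeric(value))
  lo <- variable$universe[1]; hi <- variable$universe[2]
  out_of <- value < lo | value > hi
  if (any(out_of, na.rm = TRUE)) {
    if (!clamp) {
      uh_stop(sprintf("value outside universe of '%s'", variable$name),
              "universe_error")
    }
    uh_warn(sprintf("%d value(s) outside universe of '%s' clamped",
                    sum(out_of, na.rm = TRUE), variable$name),
            "universe_clamp")
    value <- clamp(value, lo, hi)
  }
  deg <- vapply(variable$terms, membership, numeric(length(value)), x = value)
  if (length(value) == 1L) {
    deg <- stats::setNames(as.numeric(deg), names(variable$terms))
  }
  deg
}

# crisp level of a rule consequent
consequent_level <- function(rule, output) {
  if (is.numeric(rule$consequent)) as.numeric(rule$consequent)
  else mf_center(output$terms[[rule$consequent]])
}

#' Fire the rules of a system against fuzzified degrees
#'
#' @param system A `fuzzy_system`.
#' @param degrees Named list, one element per input variable, each a named
#'   vector of per-term degrees (as returned by [fuzzify()]).
#' @return Data frame with one row per rule: `rule` (index), `consequent`
#'   (crisp level) and `strength` (AND-combined degrees times the weight).
#' @export
fire_rules <- function(system, degrees) {
  stopifnot(inherits(system, "fuzzy_system"))
  need <- unique(unlist(lapply(system$rules,
                               function(r) names(r$antecedent))))
  missing <- setdiff(need, names(degrees))
  if (length(missing)) {
    uh_stop(sprintf("degrees missing for variable(s): %s",
                    paste(missing, collapse = ", ")),
            "contract_error")
  }
  strength <- vapply(system$rules, function(r) {
    d <- vapply(names(r$antecedent),
                function(v) degrees[[v]][[r$antecedent[[v]]]], 0)
    s <- if (system$and_op == "product") prod(d) else min(d)
    s * r$weight
  }, 0)
  data.frame(
    rule = seq_along(system$rules),
    consequent = vapply(system$rules, consequent_level, 0,
                        output = system$output),
    strength = strength
  )
}

#' Weighted-average defuzzification
#'
#' Collapses fired rules to a crisp value
#' \eqn{\sum_i w_i\,\mathrm{Output}_i / \sum_i w_i}; the result always lies
#' in the convex hull of the consequent levels with positive strength.
#'
#' @param strengths Nonnegative firing strengths.
#' @param levels Crisp consequent levels, same length.
#' @return Crisp output value.
#' @export
defuzzify <- function(strengths, levels) {
  stopifnot(is.numeric(strengths), is.numeric(levels),
            length(strengths) == length(levels))
  if (any(strengths < 0)) uh_stop("negative firing strength", "domain_error")
  total <- sum(strengths)
  if (total <= 0) {
    uh_stop("no rule fired (all strengths zero)", "no_rule_fired")
  }
  sum(strengths * levels) / total
}

#' Evaluate a fuzzy system on a crisp record
#'
#' Composition fuzzify -> fire rules -> defuzzify, returning the crisp
#' output together with the per-rule firing trace for explainability.
#'
#' @inheritParams fire_rules
#' @param values Named numeric vector or list covering every input variable.
#' @param clamp Passed to [fuzzify()].
#' @return List with `output` (crisp value) and `trace` (the [fire_rules()]
#'   data frame).
#' @export
evaluate_fis <- function(system, values, clamp = TRUE) {
  stopifnot(inherits(system, "fuzzy_system"))
  values <- unlist(values)
  missing <- setdiff(names(system$inputs), names(values))
  if (length(missing)) {
    uh_stop(sprintf("record missing input(s): %s",
                    paste(missing, collapse = ", ")), "contract_error")
  }
  degrees <- lapply(system$inputs, function(v) {
    fuzzify(values[[v$name]], v, clamp = clamp)
  })
  fired <- fire_rules(system, degrees)
  list(output = defuzzify(fired$strength, fired$consequent), trace = fired)
}

#' Evaluate a fuzzy system on many records at once
#'
#' Vectorised equivalent of [evaluate_fis()]: memberships are computed as
#' matrices and rule strengths combined column-wise, which matters for
#' batches of hundreds of records against rule bases of a few hundred rules.
#'
#' @inheritParams evaluate_fis
#' @param data Data frame (or named list of equal-length vectors) with one
#'   column per input variable.
#' @return Numeric vector of crisp outputs, one per row.
#' @export
evaluate_fis_batch <- function(system, data, clamp = TRUE) {
  stopifnot(inherits(system, "fuzzy_system"))
  missing <- setdiff(names(system$inputs), names(data))
  if (length(missing)) {
    uh_stop(sprintf("data missing input column(s): %s",
                    paste(missing, collapse = ", ")), "contract_error")
  }
  n <- length(data[[names(system$inputs)[1]]])
  # per-variable membership matrices: n x n_terms
  mem <- lapply(system$inputs, function(v) {
    x <- as.numeric(data[[v$name]])
    lo <- v$universe[1]; hi <- v$universe[2]
    out_of <- x < lo | x > hi
    if (any(out_of, na.rm = TRUE)) {
      if (!clamp) {
        uh_stop(sprintf("value outside universe of '%s'", v$name),
                "universe_error")
      }
      x <- clamp(x, lo, hi)
    }
    m <- vapply(v$terms, membership, numeric(length(x)), x = x)
    if (length(x) == 1L) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, names(v$terms)))
    m
  })
  strengths <- matrix(0, nrow = n, ncol = length(system$rules))
  levels <- vapply(system$rules, consequent_level, 0, output = system$output)
  for (j in seq_along(system$rules)) {
    r <- system$rules[[j]]
    s <- NULL
    for (v in names(r$antecedent)) {
      d <- mem[[v]][, r$antecedent[[v]]]
      s <- if (is.null(s)) d
           else if (system$and_op == "product") s * d
           else pmin(s, d)
    }
    strengths[, j] <- s * r$weight
  }
  total <- rowSums(strengths)
  if (any(total <= 0)) {
    uh_stop(sprintf("no rule fired for %d record(s)", sum(total <= 0)),
            "no_rule_fired")
  }
  as.numeric(strengths %*% levels) / total
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  cat(sprintf("<fuzzy_variable '%s' on [%g, %g], terms: %s>\n",
              x$name, x$universe[1], x$universe[2],
              paste(names(x$terms), collapse = ", ")))
  invisible(x)
}

#' @export
print.fuzzy_system <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_system: %d input(s) [%s] -> '%s', %d rules, %s-AND>\n",
    length(x$inputs), paste(names(x$inputs), collapse = ", "),
    x$output$name, length(x$rules), x$and_op))
  invisible(x)
}
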