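# Independent oracles: deliberately naive, single-expression / straight-line
# re-implementations used to cross-check the package's vectorised code.
# They share no helpers with the package internals.

oracle_iaqi <- function(C, rows) {
  for (k in seq_len(nrow(rows))) {
    if (C >= rows$c_low[k] && C <= rows$c_high[k]) {
      return(rows$i_low[k] + (rows$i_high[k] - rows$i_low[k]) *
               (C - rows$c_low[k]) / (rows$c_high[k] - rows$c_low[k]))
    }
  }
  stop("no bracketing row")
}

oracle_tci <- function(T, V, RH, form = "ratio") {
  if (form == "additive") {
    (T - 14.3) + 0.0216 * V * (T - 14.3) + (1 - 0.01 * abs(70.5 - RH))
  } else {
    (T - 14.3) / (1 + 0.0216 * V * (T - 14.3)) +
      (1 - 0.01 * abs(70.5 - RH))
  }
}

oracle_npi <- function(p, d) sum(p * d) / sum(p)

oracle_composite <- function(conc, sp) sum(conc / sp[names(conc)])

# straight-line membership evaluation by type, formulas written out
oracle_membership <- function(mf, x) {
  if (mf$type == "sigmoid") {
    v <- 1 / (1 + exp(-mf$steepness * (x - mf$center) / mf$base))
    min(max(v, 1e-300), 1 - 1e-15)
  } else if (mf$type == "gaussian") {
    exp(-(x - mf$center)^2 / (2 * mf$sigma^2))
  } else {
    if (x < mf$left || x > mf$right) 0
    else if (x == mf$peak) 1
    else if (x < mf$peak) (x - mf$left) / (mf$peak - mf$left)
    else (mf$right - x) / (mf$right - mf$peak)
  }
}

# independent straight-line FIS evaluation: loops, no matrices
oracle_evaluate_fis <- function(system, values) {
  num <- 0; den <- 0
  for (r in system$rules) {
    s <- NA_real_
    for (v in names(r$antecedent)) {
      var <- system$inputs[[v]]
      mu <- oracle_membership(var$terms[[r$antecedent[[v]]]],
                              values[[v]])
      s <- if (is.na(s)) mu
           else if (system$and_op == "product") s * mu
           else min(s, mu)
    }
    s <- s * r$weight
    lev <- if (is.numeric(r$consequent)) r$consequent
           else {
             mfo <- system$output$terms[[r$consequent]]
             if (mfo$type == "triangular") mfo$peak else mfo$center
           }
    num <- num + s * lev
    den <- den + s
  }
  num / den
}

# random contiguous breakpoint table with 2-5 rows
random_breakpoint_rows <- function() {
  k <- sample(2:5, 1)
  cb <- sort(runif(k + 1, 0, 500))
  ib <- sort(runif(k + 1, 0, 500))
  cb <- cb + seq_along(cb) * 1e-3  # guard against ties
  ib <- ib + seq_along(ib) * 1e-3
  data.frame(c_low = cb[-(k + 1)], c_high = cb[-1],
             i_low = ib[-(k + 1)], i_high = ib[-1])
}

random_table <- function() {
  breakpoint_table("x", random_breakpoint_rows(), s_p = runif(1, 1, 100))
}

# random fuzzy system with <= 3 inputs and <= 12 rules; sigmoid/gaussian
# input terms keep all memberships positive so some rule always fires
random_fuzzy_system <- function(max_inputs = 3, max_rules = 12) {
  n_in <- sample.int(max_inputs, 1)
  inputs <- lapply(seq_len(n_in), function(i) {
    lo <- runif(1, -10, 0); hi <- lo + runif(1, 1, 20)
    n_terms <- sample(2:3, 1)
    terms <- lapply(seq_len(n_terms), function(j) {
      if (runif(1) < 0.5) {
        mf_sigmoid(runif(1, lo, hi), runif(1, -6, 6), runif(1, 0.5, 2))
      } else {
        mf_gaussian(runif(1, lo, hi), runif(1, 0.2, 3))
      }
    })
    names(terms) <- paste0("t", seq_len(n_terms))
    fuzzy_variable(paste0("x", i), c(lo, hi), terms)
  })
  out_terms <- list(low = mf_gaussian(0.1, 0.2),
                    mid = mf_triangular(0.2, 0.5, 0.8),
                    high = mf_gaussian(0.9, 0.2))
  output <- fuzzy_variable("y", c(0, 1), out_terms)
  n_rules <- sample(n_in:max_rules, 1)
  rules <- lapply(seq_len(n_rules), function(j) {
    # first n_in rules each pin one variable so all inputs are referenced
    vars <- if (j <= n_in) unique(c(j, sample.int(n_in, sample.int(n_in, 1))))
            else sample.int(n_in, sample.int(n_in, 1))
    ante <- vapply(vars, function(v) {
      sample(names(inputs[[v]]$terms), 1)
    }, "")
    names(ante) <- paste0("x", vars)
    cons <- if (runif(1) < 0.5) sample(names(out_terms), 1)
            else runif(1, 0, 1)
    fuzzy_rule(ante, cons, weight = runif(1, 0.2, 1))
  })
  fuzzy_system(inputs, output, rules,
               and_op = sample(c("product", "min"), 1))
}

random_system_values <- function(system) {
  vals <- lapply(system$inputs, function(v) runif(1, v$universe[1],
                                                  v$universe[2]))
  names(vals) <- names(system$inputs)
  vals
}

# small record in the default tree's universes
make_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    site = rep("S1", n),
    timestamp = as.character(seq_len(n)),
    pm25 = runif(n, 5, 95), no2 = runif(n, 2, 75),
    pm10 = runif(n, 10, 150), o3 = runif(n, 5, 190),
    heavy_metal = runif(n, 0.001, 0.09),
    dissolved_oxygen = runif(n, 1, 13), ph = runif(n, 5, 10),
    organic_matter = runif(n, 0.2, 7.5), n_p = runif(n, 50, 1400),
    noise_level = runif(n, 42, 88),
    temperature = runif(n, 5, 35), wind_speed = runif(n, 0, 6),
    relative_humidity = runif(n, 20, 95)
  )
}
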