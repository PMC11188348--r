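#' Membership functions
#'
#' Constructors for the membership-function shapes used by the fuzzy
#' inference engine. Input variables conventionally use sigmoid terms,
#'
#' \deqn{\mu(x) = \frac{1}{1 + \exp(-c\,(x - a)/b)}}
#'
#' where `a` (`center`) locates the 0.5-membership point, `c` (`steepness`)
#' controls the slope and its sign the direction, and `b` (`base`) rescales
#' the input axis (default 1 so that `c` alone sets the steepness). Output
#' (and some input) terms use the Gaussian form
#' \eqn{\mu(y) = \exp(-(y - b)^2 / (2\sigma^2))}, peaking at 1 exactly at its
#' center, or the triangular form, 1 at `peak` and 0 outside `[left, right]`.
#'
#' @param center Location parameter: the 0.5 crossing for a sigmoid, the peak
#'   for a Gaussian.
#' @param steepness Sigmoid slope parameter `c`; negative values give a
#'   decreasing ("low") term.
#' @param base Sigmoid scale parameter `b`; must be nonzero.
#' @param sigma Gaussian spread; must be positive.
#' @param left,peak,right Triangular vertices, `left <= peak <= right`.
#' @return An object of class `fuzzy_mf`.
#' @examples
#' membership(mf_sigmoid(0, 1), log(3))  # 0.75
#' membership(mf_gaussian(5, 2), 7)      # exp(-0.5)
#' @name membership-functions
NULL

#' @rdname membership-functions
#' @export
mf_sigmoid <- function(center, steepness = 1, base = 1) {
  check_number(center, "center")
  check_number(steepness, "steepness")
  check_number(base, "base")
  if (base == 0) uh_stop("sigmoid `base` must be nonzero", "domain_error")
  structure(list(type = "sigmoid", center = center, steepness = steepness,
                 base = base),
            class = "fuzzy_mf")
}

#' @rdname membership-functions
#' @export
mf_gaussian <- function(center, sigma) {
  check_number(center, "center")
  check_number(sigma, "sigma", lo = .Machine$double.xmin)
  structure(list(type = "gaussian", center = center, sigma = sigma),
            class = "fuzzy_mf")
}

#' @rdname membership-functions
#' @export
mf_triangular <- function(left, peak, right) {
  check_number(left, "left"); check_number(peak, "peak"); check_number(right, "right")
  if (!(left <= peak && peak <= right)) {
    uh_stop("triangular MF requires left <= peak <= right", "domain_error")
  }
  structure(list(type = "triangular", left = left, peak = peak, right = right),
            class = "fuzzy_mf")
}

#' Evaluate a membership function
#'
#' @param mf A `fuzzy_mf` object.
#' @param x Numeric vector of variable values.
#' @return Membership degrees in `[0, 1]` (sigmoid degrees are clamped to the
#'   open interval so saturation never returns exactly 0 or 1).
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "fuzzy_mf"))
  switch(mf$type,
    sigmoid = {
      v <- stats::plogis(mf$steepness * (x - mf$center) / mf$base)
      clamp(v, 1e-300, 1 - 1e-15)
    },
    gaussian = exp(-(x - mf$center)^2 / (2 * mf$sigma^2)),
    triangular = {
      v <- pmin((x - mf$left) / max(mf$peak - mf$left, .Machine$double.xmin),
                (mf$right - x) / max(mf$right - mf$peak, .Machine$double.xmin))
      # degenerate sides collapse to an indicator at the peak
      v[x == mf$peak] <- 1
      clamp(v, 0, 1)
    },
    uh_stop(sprintf("unknown membership type '%s'", mf$type), "domain_error")
  )
}

# representative crisp value of a term, used as its consequent level
mf_center <- function(mf) {
  switch(mf$type,
    sigmoid = mf$center,
    gaussian = mf$center,
    triangular = mf$peak
  )
}

#' @export
print.fuzzy_mf <- function(x, ...) {
  params <- x[setdiff(names(x), "type")]
  cat(sprintf("<fuzzy_mf %s: %s>\n", x$type,
              paste(sprintf("%s=%g", names(params), unlist(params)),
                    collapse = ", ")))
  invisible(x)
}
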