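#' Distribution specifications for model parameters
#'
#' Parameters are either fixed (`dist_point`) or uncertain with a PERT
#' (min, mode, max) specification (`dist_pert`) used in probabilistic
#' sensitivity analysis. The PERT distribution is the classic
#' lambda = 4 re-parameterization of the beta distribution.
#'
#' @param value Finite numeric value (point distribution).
#' @param min,mode,max PERT support minimum, mode and maximum; requires
#'   `min <= mode <= max` and `min < max`.
#' @return An object of class `perspecta_dist`.
#' @examples
#' dist_pert(0.12, 0.20, 0.32)
#' dist_point(0.05)
#' @export
dist_pert <- function(min, mode, max) {
  if (!all(is.finite(c(min, mode, max))))
    stop("PERT parameters must be finite")
  if (!(min <= mode && mode <= max))
    stop("PERT requires min <= mode <= max, got (", min, ", ", mode, ", ",
         max, ")")
  if (!(min < max))
    stop("PERT support is degenerate: min must be < max")
  structure(list(kind = "pert", min = min, mode = mode, max = max),
            class = "perspecta_dist")
}

#' @rdname dist_pert
#' @export
dist_point <- function(value) {
  if (!is.finite(value)) stop("point distribution requires a finite value")
  structure(list(kind = "point", value = value), class = "perspecta_dist")
}

#' Convert a PERT specification to beta shape parameters
#'
#' Uses the standard lambda = 4 PERT parameterization:
#' `alpha = 1 + 4 (mode - min) / (max - min)`,
#' `beta  = 1 + 4 (max - mode) / (max - min)`.
#' Sampling rescales the unit beta onto `[min, max]`, so the mean equals
#' `(min + 4 mode + max) / 6`.
#'
#' @param spec A `perspecta_dist` of kind `"pert"`.
#' @return List with `alpha`, `beta`, `min`, `max`.
#' @examples
#' pert_to_beta(dist_pert(0, 0.5, 1))  # alpha = beta = 3
#' @export
pert_to_beta <- function(spec) {
  stopifnot(inherits(spec, "perspecta_dist"))
  if (spec$kind != "pert") stop("pert_to_beta requires a pert specification")
  rng <- spec$max - spec$min
  list(alpha = 1 + 4 * (spec$mode - spec$min) / rng,
       beta  = 1 + 4 * (spec$max - spec$mode) / rng,
       min = spec$min, max = spec$max)
}

#' Mean of a distribution specification
#'
#' For PERT this is the closed form `(min + 4 mode + max) / 6`.
#'
#' @param spec A `perspecta_dist`.
#' @return Numeric mean.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "perspecta_dist"))
  if (spec$kind == "point") spec$value
  else (spec$min + 4 * spec$mode + spec$max) / 6
}

#' Draw from a distribution specification
#'
#' Uses the current R random number stream (seed it with [set.seed()]).
#'
#' @param spec A `perspecta_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "perspecta_dist"))
  if (spec$kind == "point") return(rep(spec$value, n))
  ab <- pert_to_beta(spec)
  ab$min + rbeta(n, ab$alpha, ab$beta) * (ab$max - ab$min)
}

#' @export
print.perspecta_dist <- function(x, ...) {
  if (x$kind == "point") {
    cat("<point:", x$value, ">\n")
  } else {
    cat(sprintf("<pert: min %g, mode %g, max %g>\n", x$min, x$mode, x$max))
  }
  invisible(x)
}
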