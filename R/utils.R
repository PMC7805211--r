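# internal helpers shared across modules

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_param <- function(...) stop(..., call. = FALSE)

#' Squeeze beta values off the boundary
#'
#' Applies the standard `(beta * (n - 1) + 0.5) / n` shrinkage so that 0
#' and 1 become representable on the logit scale before model fitting.
#'
#' @param beta numeric vector or matrix of methylation fractions in
#'   `[0, 1]`.
#' @param n sample count used for the shrinkage; defaults to
#'   `length(beta)`.
#' @return object of the same shape with all values in the open interval
#'   `(0, 1)`.
#' @export
squeeze_beta <- function(beta, n = length(beta)) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_param("beta values must lie in [0, 1]")
  (beta * (n - 1) + 0.5) / n
}

# numeric formatting that round-trips doubles exactly through text
fmt_full <- function(x) sprintf("%.17g", x)
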