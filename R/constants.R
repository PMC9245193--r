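# Physical constants (CODATA 2018, exact where defined by the SI)
.R_GAS <- 8.31446261815324   # molar gas constant, J K^-1 mol^-1
.KB <- 1.380649e-23          # Boltzmann constant, J K^-1
.HBAR <- 1.054571817e-34     # reduced Planck constant, J s
.N_AVOGADRO <- 6.02214076e23 # mol^-1

#' Gas constant used throughout the package
#'
#' Entropies are reported in J K^-1 mol^-1; the molar gas constant converts
#' dimensionless (nats) information quantities to that scale.
#'
#' @return The molar gas constant in J K^-1 mol^-1.
#' @export
gas_constant <- function() .R_GAS

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards.  All stochastic package functions route their seeding
#' through this helper, so nothing leaves a footprint on the global stream;
#' a `NULL` seed evaluates the expression with the current stream.
#'
#' @param seed integer seed, or `NULL` for no seeding.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
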