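# Internal helpers shared across modules.

#' Gas constant in kcal mol^-1 K^-1
#'
#' Value used throughout for interconverting dissociation constants and free
#' energies (\eqn{\Delta G = RT \ln K_d} with a 1 M standard state).
#' @export
R_KCAL <- 1.9872e-3

#' Default temperature (K)
#'
#' 25 degrees Celsius, the temperature at which the titrations are run.
#' @export
T_STANDARD <- 298.15

# Round half away from zero. base::round() rounds half to even, which is the
# wrong convention for reproducing reported per-assay solubilities
# (e.g. 0.0445 must print as 0.045, not 0.044).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  invisible(x)
}
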