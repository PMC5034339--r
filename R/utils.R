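# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (`0.5 -> 1`),
#' the convention used when comparing against printed percentages;
#' base R's [round()] rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)   # 3, where round(2.5) gives 2
#' round_half_up(6.994) # 7
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a substream seed from a master seed, staying inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 100003 + as.numeric(index)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Wavenumber from an illumination wavelength
#'
#' @param wavelength_nm Center wavelength in nanometres.
#' @return k0 = 2 * pi / lambda0 in rad/um.
#' @keywords internal
wavenumber_um <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0) {
    stopf("`wavelength_nm` must be positive, got %s", format(wavelength_nm))
  }
  2 * pi / (wavelength_nm / 1000)
}
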