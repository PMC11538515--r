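#' @importFrom rlang .data
#' @importFrom generics tidy glance augment
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Run code under a temporary RNG state so package internals never disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Half-up rounding (0.5 always rounds away from zero), used when comparing
# against published tables rounded that way.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

condition_key <- function(meta) {
  paste(meta$compound, meta$organ, meta$dose, meta$time_days, sep = "|")
}

treatment_key <- function(meta) {
  paste(meta$compound, meta$dose, meta$time_days, sep = "|")
}
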