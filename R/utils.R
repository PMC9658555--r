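#' @keywords internal
"_PACKAGE"

# Deterministic substream seed for a simulation component.
#
# Episodes, meals, drift and the noise channels each draw from their own
# seeded stream so that changing, say, the CGM noise level leaves episode
# times untouched (ceteris-paribus comparisons in tests).
#
# The mixing constants are arbitrary large primes; the result is kept below
# 2^31 - 1 so it is a valid `set.seed()` argument.
substream_seed <- function(seed, subject_index, component) {
  offsets <- c(
    subject = 1L, episodes = 2L, meals = 3L, drift = 4L,
    cgm_noise = 5L, hr_grid_noise = 6L, highrate_noise = 7L, gaps = 8L
  )
  off <- offsets[[component]]
  s <- (as.double(seed) * 2654435761 + as.double(subject_index) * 40503 +
    as.double(off) * 97) %% (2^31 - 1)
  as.integer(s)
}

# Evaluate a function under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_substream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
    call. = FALSE
  )
}

#' Convert glucose concentrations from mmol/L to mg/dL
#'
#' Applies the molar-mass factor for glucose (18.0182 g/mol scaled to dL).
#' All downstream feature arithmetic in this package is in mg/dL; D1namo-style
#' registrations arrive in mmol/L and are converted at ingest.
#'
#' @param x numeric vector of concentrations in mmol/L.
#' @return numeric vector in mg/dL.
#' @export
#' @examples
#' mmol_to_mgdl(5.5) # approximately 99.1
mmol_to_mgdl <- function(x) {
  x * 18.0182
}
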