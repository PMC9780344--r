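# Internal helpers shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, 4, -4, pi, -pi))
#' @export
wrap_angle <- function(x) {
  # map to [-pi, pi) then move the -pi boundary to +pi so the interval is (-pi, pi]
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w == -pi] <- pi
  w
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Deterministic per-stage seed derivation from one master seed.
# Keeps results reproducible without sharing one RNG stream across stages.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(index))
  as.integer(((abs(as.numeric(master)) %% 65521) * 31741 + index * 7919 + 1) %%
               2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ag <- function(msg, class = "alphagate_error") {
  rlang::abort(msg, class = class)
}
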