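# shared helpers: seed derivation, rotations, small numerics

#' Derive a child seed from a master seed and a counter
#'
#' Deterministic counter-based scheme used everywhere the pipeline needs an
#' independent random stream (per-nucleus draws, per-iteration null
#' replicates). Stays within the 32-bit signed-integer range R requires.
#'
#' @param master integer master seed.
#' @param counter non-negative integer counter.
#' @return An integer seed.
#' @export
child_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + as.numeric(counter) * 16807 + 1) %%
               2147483647)
}

# rotation matrix about the z axis (active, counter-clockwise looking down +z)
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# rows of `x` as (x, y, z) point matrix
as_points <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("expected an n x 3 point matrix")
  storage.mode(x) <- "double"
  unname(x)
}

vnorm <- function(v) sqrt(sum(v^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
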