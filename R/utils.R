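## Internal helpers shared across modules.

## Classed error so callers can branch on failure kind without parsing text.
pvStop <- function(code, msg, ...) {
  stop(structure(
    class = c(paste0("pluckvision_", code), "pluckvision_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Run `expr` with the RNG seeded, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
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

vnorm <- function(v) sqrt(sum(v^2))

unitVector <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) pvStop("contract", "%s has zero length", what)
  v / n
}

## Two unit vectors orthogonal to `u` (completes a right-handed-ish basis).
orthobasis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitVector(a - sum(a * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2)
}
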