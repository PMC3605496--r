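# Internal helpers: seeding, grid rounding, bisection.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed from a master seed and integer tags, staying < 2^31.
# Polynomial hash in double arithmetic (exact below 2^53).
derive_seed <- function(master, ...) {
  m <- 2147483629
  h <- as.numeric(master) %% m
  for (tag in c(...)) h <- (h * 69069 + as.numeric(tag) + 1) %% m
  as.integer(h) + 1L
}

# Round a delay (ms) to the dt grid, half-up, minimum one step.
delay_to_steps <- function(delay_ms, dt) {
  pmax(1L, as.integer(floor(delay_ms / dt + 0.5)))
}

# Map an arrival time (ms) to the 0-based step in which it participates:
# the step whose end is the first grid point >= time.
time_to_step <- function(time_ms, dt) {
  pmax(0L, as.integer(ceiling(time_ms / dt - 1e-9)) - 1L)
}

# Bisection for a continuous f with f(lo), f(hi) of opposite sign.
bisect <- function(f, lo, hi, tol = 1e-10, max_iter = 200L) {
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi))
    stop("bisect: non-finite function value at bracket endpoint")
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop(sprintf("bisect: no sign change on [%g, %g] (f = %g, %g)",
                 lo, hi, flo, fhi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) < tol * max(1, abs(mid))) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
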