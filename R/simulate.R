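# Simulators used as fixtures and experiment drivers: the logistic map,
# the Lorenz system, and planted nested-periodic texts with ground truth.

#' Iterate the logistic map
#'
#' The population recursion `x[n+1] = rho * x[n] * (1 - x[n])`, the classic
#' route from stable fixed points through period doubling into chaos as the
#' growth parameter increases.
#'
#' @param rho Growth parameter, `0 < rho <= 4`.
#' @param n Number of values returned (including `x0`), `n >= 1`.
#' @param x0 Initial value in `(0, 1)`.
#' @return Numeric vector of length `n`.
#' @examples
#' tail(may_map(2.5, 200), 1)  # fixed point 1 - 1/rho = 0.6
#' @export
may_map <- function(rho, n, x0 = 0.5) {
  if (!is.finite(rho) || rho <= 0 || rho > 4) stop("`rho` must be in (0, 4]")
  if (!is.finite(x0) || x0 <= 0 || x0 >= 1) stop("`x0` must be in (0, 1)")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  x <- numeric(n)
  x[1] <- x0
  for (i in seq_len(n - 1L)) x[i + 1] <- rho * x[i] * (1 - x[i])
  x
}

#' Integrate the Lorenz system
#'
#' Fixed-step fourth-order Runge-Kutta integration of
#' `dx/dt = sigma (y - x)`, `dy/dt = x (rho - z) - y`, `dz/dt = x y - beta z`,
#' via `deSolve` (method `"rk4"`). Deterministic for a fixed configuration.
#' Defaults are the canonical chaotic parameters (`sigma = 10`, `rho = 28`,
#' `beta = 8/3`) with the two-lobe attractor.
#'
#' @param n Number of steps (the output has `n` rows, the state after steps
#'   `1..n`; the initial state is not included).
#' @param dt Time step, `> 0`.
#' @param sigma,rho,beta Lorenz parameters.
#' @param init Numeric length-3 initial state `(x0, y0, z0)`.
#' @return data.frame with columns `time`, `x`, `y`, `z` and `n` rows.
#' @export
lorenz_system <- function(n, dt = 0.005, sigma = 10, rho = 28, beta = 8 / 3,
                          init = c(1, 1, 1)) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  if (length(init) != 3L || any(!is.finite(init))) stop("`init` must be 3 finite values")
  deriv <- function(t, state, parms) {
    x <- state[1]; y <- state[2]; z <- state[3]
    list(c(sigma * (y - x), x * (rho - z) - y, x * y - beta * z))
  }
  times <- seq(0, n * dt, by = dt)
  sol <- deSolve::rk4(c(x = init[1], y = init[2], z = init[3]), times, deriv, NULL)
  sol <- as.data.frame(sol)[-1, , drop = FALSE]  # drop the initial state row
  bad <- which(!stats::complete.cases(sol) | !apply(is.finite(as.matrix(sol)), 1, all))
  if (length(bad)) stop("non-finite Lorenz state at step ", bad[1])
  names(sol)[1] <- "time"
  rownames(sol) <- NULL
  sol
}

#' Generate a planted nested-periodic text
#'
#' Builds `block = strrep(motif, inner_reps) + spacer`, repeats it
#' `outer_reps` times, and corrupts a `noise_rate` fraction of positions with
#' digits (characters outside the planted alphabet). The planted hierarchy is
#' returned alongside the text so decomposition tests can check recovery.
#'
#' @param motif Inner motif string (length >= 1).
#' @param inner_reps Motif repetitions per block, `>= 2`.
#' @param outer_reps Block repetitions, `>= 2`.
#' @param spacer Spacer string appended to each block (may be `""`).
#' @param noise_rate Fraction of positions corrupted, in `[0, 1)`.
#' @param seed Optional integer; fixes the corrupted positions exactly.
#' @return List with `text`, and `truth` (list: `motif`, `block`,
#'   `block_len`, `inner_reps`, `outer_reps`, `noise_positions` 0-based).
#' @examples
#' nested_periodic_text("at", 3, 4, "q")$text  # "atatatq" repeated 4 times
#' @export
nested_periodic_text <- function(motif, inner_reps, outer_reps, spacer = "",
                                 noise_rate = 0, seed = NULL) {
  if (nchar(motif) < 1L) stop("`motif` must be non-empty")
  if (inner_reps < 2L || outer_reps < 2L) stop("repetition counts must be >= 2")
  if (noise_rate < 0 || noise_rate >= 1) stop("`noise_rate` must be in [0, 1)")
  block <- paste0(strrep(motif, inner_reps), spacer)
  text <- strrep(block, outer_reps)
  L <- nchar(text)
  noise_pos <- integer(0)
  if (noise_rate > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    k <- max(1L, round(noise_rate * L))
    noise_pos <- sort(sample.int(L, k))
    ch <- chars_of(text)
    ch[noise_pos] <- sample(as.character(0:9), k, replace = TRUE)
    text <- paste(ch, collapse = "")
  }
  list(text = text,
       truth = list(motif = motif, block = block, block_len = nchar(block),
                    inner_reps = inner_reps, outer_reps = outer_reps,
                    noise_positions = as.integer(noise_pos - 1L)))
}

#' Detect the fundamental period of a symbolic text
#'
#' On the post-burn-in suffix, returns the smallest `p >= 1` such that
#' `suffix[i] == suffix[i + p]` for every valid `i`, or `NA` if no
#' `p <= length(suffix)/2` qualifies. The default burn-in discards the first
#' half of the text, where transients live.
#'
#' @param text Character string (a symbolic text).
#' @param burn_in Number of leading characters discarded (default `L %/% 2`).
#' @return Integer period, or `NA_integer_`.
#' @examples
#' detect_period("abababab", burn_in = 0)  # 2
#' @export
detect_period <- function(text, burn_in = NULL) {
  ch <- chars_of(text)
  L <- length(ch)
  if (is.null(burn_in)) burn_in <- L %/% 2L
  if (burn_in < 0 || burn_in >= L) stop("`burn_in` must be in [0, length)")
  x <- ch[(burn_in + 1L):L]
  n <- length(x)
  for (p in seq_len(n %/% 2L)) {
    if (all(x[seq_len(n - p)] == x[(p + 1L):n])) return(as.integer(p))
  }
  NA_integer_
}
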