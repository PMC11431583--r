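#' Discretization scale alphabet
#'
#' Ordered single-character alphabet used by discretization scales: lowercase
#' letters for ranks 1..26, uppercase for 27..52, and Unicode letters from
#' U+00C0 onward for larger resolutions, so every symbol stays one character.
#'
#' @param s Integer resolution (alphabet size), `s >= 2`.
#' @return Character vector of `s` distinct single characters, in rank order.
#' @examples
#' scale_alphabet(20)  # "a" .. "t"
#' @export
scale_alphabet <- function(s) {
  s <- as.integer(s)
  if (is.na(s) || s < 2) stop("resolution `s` must be an integer >= 2")
  base <- c(letters, LETTERS)
  if (s <= length(base)) return(base[seq_len(s)])
  extra <- vapply(seq_len(s - length(base)), function(i) intToUtf8(0xBF + i), "")
  c(base, extra)
}

parse_scale_spec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec))
    stop("scale spec must be a single string like \"T: 20/10/0.01\"")
  m <- regmatches(spec, regexec(
    "^\\s*([TtHhLl])\\s*:\\s*([0-9]+)\\s*/\\s*([0-9]+)\\s*/\\s*([0-9.eE+-]+)\\s*$",
    spec))[[1]]
  if (length(m) != 5L)
    stop("malformed scale spec '", spec, "'; expected \"<T|H|L>: <res>/<inflect>/<param>\"")
  type <- c(T = "tangential", H = "hyperbolic", L = "linear")[[toupper(m[2])]]
  s <- as.integer(m[3]); inflect <- as.integer(m[4]); param <- as.numeric(m[5])
  if (is.na(s) || s < 2) stop("scale resolution must be >= 2")
  if (is.na(inflect) || inflect < 0 || inflect >= s)
    stop("inflection index must be in [0, resolution)")
  if (!is.finite(param) || param <= 0) stop("scale param must be a positive number")
  list(type = type, resolution = s, inflection = inflect, param = param)
}

#' Build a discretization scale
#'
#' Parses the scale notation `"<T|H|L>: <res>/<inflect>/<param>"` (tangential,
#' hyperbolic or linear; resolution = alphabet size; 0-based inflection
#' character index; positive nonlinearity parameter) and fits bin boundaries
#' to a numeric series. Linear scales cut the observed range into equal-width
#' bins. Tangential and hyperbolic scales concentrate resolution around the
#' inflection character: with `v_c` the series value at the quantile
#' `(inflect + 0.5)/s` and `W` the series range, interior boundaries are
#' `v_c + param * W * tan(pi * (k/s - (inflect + 0.5)/s))` (tangential) or
#' `v_c + param * W * sinh(g * (k/s - (inflect + 0.5)/s)) / sinh(g/2)` with
#' `g = 1/param` (hyperbolic), for `k = 1, ..., s - 1`. The first and last
#' boundaries are `-Inf` and `+Inf`, so every finite value maps to a symbol.
#'
#' @param spec Scale notation string, e.g. `"T: 20/10/0.01"`.
#' @param series Numeric series the scale is fitted to. May be omitted for a
#'   linear scale with explicit `limits`.
#' @param limits Optional length-2 numeric vector overriding the series
#'   min/max used to anchor the scale.
#' @return An object of class `nrsdm_scale`: a list with `type`, `resolution`,
#'   `inflection`, `param`, `bounds` (length `s + 1`, strictly increasing,
#'   infinite at both ends) and `alphabet`.
#' @examples
#' sc <- build_scale("L: 4/2/0.01", seq(0, 4 - 1e-9, length.out = 100))
#' sc$bounds  # interior boundaries at 1, 2, 3
#' @seealso [discretize()], [optimize_scale()]
#' @export
build_scale <- function(spec, series = NULL, limits = NULL) {
  p <- parse_scale_spec(spec)
  if (is.null(limits)) {
    if (is.null(series)) stop("either `series` or `limits` is required")
    if (!is.numeric(series) || length(series) < 1L)
      stop("`series` must be a non-empty numeric vector")
    if (any(!is.finite(series))) stop("series contains non-finite values")
    limits <- range(series)
  }
  lo <- limits[1]; hi <- limits[2]
  W <- hi - lo
  s <- p$resolution
  qc <- (p$inflection + 0.5) / s
  if (W <= 0) {
    # constant series: unit-width bins centred so the value lands on the
    # inflection character
    vc <- lo
    interior <- vc + (seq_len(s - 1) - p$inflection - 0.5)
  } else if (p$type == "linear") {
    interior <- lo + seq_len(s - 1) * W / s
  } else {
    vc <- if (!is.null(series)) {
      stats::quantile(series, qc, names = FALSE, type = 7)
    } else lo + qc * W
    k <- seq_len(s - 1) / s
    interior <- if (p$type == "tangential") {
      vc + p$param * W * tan(pi * (k - qc))
    } else {
      g <- 1 / p$param
      vc + p$param * W * sinh(g * (k - qc)) / sinh(g / 2)
    }
  }
  if (any(diff(interior) <= 0)) stop("degenerate scale: boundaries not strictly increasing")
  structure(list(
    type = p$type, resolution = s, inflection = p$inflection, param = p$param,
    bounds = c(-Inf, interior, Inf), alphabet = scale_alphabet(s), spec = spec
  ), class = "nrsdm_scale")
}

#' @export
print.nrsdm_scale <- function(x, ...) {
  cat(sprintf("<nrsdm_scale> %s, resolution %d, inflection %d, param %g\n",
              x$type, x$resolution, x$inflection, x$param))
  interior <- x$bounds[is.finite(x$bounds)]
  cat("  interior boundaries: ",
      paste(signif(utils::head(interior, 6), 4), collapse = ", "),
      if (length(interior) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Discretize a numeric series into a symbolic text
#'
#' Maps each value to the alphabet character of its bin: position `p` gets
#' `alphabet[k]` where `bounds[k] <= value < bounds[k + 1]` (half-open bins,
#' lower boundary inclusive). The mapping is monotone non-decreasing in the
#' value and the output text has exactly one character per input value.
#'
#' @param series Numeric vector of finite values.
#' @param scale A scale from [build_scale()] or [optimize_scale()].
#' @return Single character string of `length(series)` symbols.
#' @examples
#' sc <- build_scale("L: 4/2/0.01", c(0, 4))
#' discretize(c(0.5, 1.5, 2.5, 3.5), sc)  # "abcd"
#' @export
discretize <- function(series, scale) {
  if (!inherits(scale, "nrsdm_scale")) stop("`scale` must be an nrsdm_scale")
  if (!is.numeric(series) || length(series) < 1L)
    stop("`series` must be a non-empty numeric vector")
  if (any(!is.finite(series))) {
    bad <- which(!is.finite(series))[1]
    stop("non-finite series value at position ", bad)
  }
  idx <- findInterval(series, scale$bounds[is.finite(scale$bounds)]) + 1L
  paste(scale$alphabet[idx], collapse = "")
}

#' Negentropy of a symbolic text
#'
#' The extractable information of a discretized text: one minus its base-`s`
#' Shannon character entropy, `h = 1 - sum_i p_i log_s(1/p_i)` with `p_i` the
#' character frequencies over the `s` scale characters (zero-frequency terms
#' contribute nothing). `h` is 1 for a single repeated character and 0 when
#' all `s` characters are equally frequent.
#'
#' @param text Non-empty character string (a symbolic text).
#' @param resolution Scale resolution `s >= 2` (the entropy's log base).
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' negentropy("abab", 2)  # 0
#' negentropy("aaaa", 2)  # 1
#' @export
negentropy <- function(text, resolution) {
  s <- as.integer(resolution)
  if (is.na(s) || s < 2) stop("`resolution` must be an integer >= 2")
  if (!is.character(text) || length(text) != 1L || nchar(text) < 1L)
    stop("`text` must be a non-empty string")
  cnt <- table(strsplit(text, "", fixed = TRUE)[[1]])
  p <- as.numeric(cnt) / sum(cnt)
  1 - sum(p * log(1 / p, base = s))
}

#' Enumerate candidate scale specs
#'
#' Convenience grid builder for [optimize_scale()]: the Cartesian product of
#' scale types, resolutions, inflection indices and nonlinearity parameters,
#' rendered in scale notation.
#'
#' @param types Character vector over `c("L", "T", "H")`.
#' @param resolution Integer vector of alphabet sizes.
#' @param inflection Integer vector of 0-based inflection indices, or `NULL`
#'   for the middle character `floor(s/2)`.
#' @param params Numeric vector of positive nonlinearity parameters.
#' @return Character vector of scale spec strings.
#' @examples
#' scale_candidates(c("L", "T"), 20, params = c(0.01, 0.05))
#' @export
scale_candidates <- function(types = c("L", "T", "H"), resolution = 20,
                             inflection = NULL, params = 0.01) {
  out <- character(0)
  for (ty in types) for (s in resolution) {
    infl <- if (is.null(inflection)) s %/% 2L else inflection
    for (i in infl) for (pa in params)
      out <- c(out, sprintf("%s: %d/%d/%g", ty, s, i, pa))
  }
  unique(out)
}

#' Select the scale maximizing extractable information
#'
#' Discretizes the series under every candidate scale and returns the one
#' whose text has the highest negentropy [negentropy()]. Ties are broken by
#' scale type (linear before tangential before hyperbolic), then by smaller
#' nonlinearity parameter. The full audit grid of `(spec, h)` is attached as
#' attribute `"grid"`. If every candidate collapses the series onto a single
#' character the best-effort winner is still returned with a warning.
#'
#' @param series Numeric series to discretize.
#' @param candidates Character vector of scale specs (see [scale_candidates()]).
#' @return The winning `nrsdm_scale`, with attribute `grid` (data.frame of
#'   `spec`, `type`, `param`, `h`).
#' @export
optimize_scale <- function(series, candidates = scale_candidates()) {
  if (length(candidates) < 1L) stop("empty candidate set")
  rows <- lapply(candidates, function(sp) {
    sc <- build_scale(sp, series)
    txt <- discretize(series, sc)
    data.frame(spec = sp, type = sc$type, param = sc$param,
               h = negentropy(txt, sc$resolution),
               degenerate = length(unique(strsplit(txt, "")[[1]])) == 1L,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  type_rank <- c(linear = 1L, tangential = 2L, hyperbolic = 3L)
  ord <- order(-grid$h, type_rank[grid$type], grid$param)
  if (all(grid$degenerate))
    warning("all candidate scales produce a single-character text; returning best effort")
  best <- build_scale(grid$spec[ord[1]], series)
  attr(best, "grid") <- grid[c("spec", "type", "param", "h")]
  best
}
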