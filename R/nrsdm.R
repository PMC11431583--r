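#' Fit a nested repeated sequence decomposition
#'
#' The main entry point. A numeric series is first discretized into a symbolic
#' text (with the given scale, or the negentropy-maximizing scale from
#' [optimize_scale()] when `scale` is `NULL`); a character string is taken as
#' an already-symbolic text. The text is then decomposed by recursive greedy
#' longest-first repeat extraction ([decompose_nested()]), effective counts
#' and coverage probabilities are annotated, and the entropy complexity
#' measures (per-node NPC, tree MSIC) are computed.
#'
#' @param x Numeric series, or a single character string (symbolic text).
#' @param scale Scale notation string (e.g. `"T: 20/10/0.01"`), an
#'   `nrsdm_scale`, or `NULL` to select a scale by negentropy maximization.
#'   Ignored when `x` is already a text.
#' @param rq Minimum occurrence count for a repeated sequence (`>= 2`).
#' @param min_len Minimum symbol length (`>= 2`).
#' @return Object of class `nrsdm`: list with `text`, `L`, `scale` (or
#'   `NULL`), `config`, `asrsm` (the depth-0 [find_repeats()] result), `tree`
#'   (NPC-annotated `nrsdm_tree`), `complexity` ([msic()] report) and `call`.
#' @examples
#' fit <- nrsdm("CADCADCCACAECCACACEDDCADCABCCACAECCACACEDD", rq = 2)
#' fit
#' coef(fit)
#' @export
nrsdm <- function(x, scale = NULL, rq = 2L, min_len = 2L) {
  cl <- match.call()
  used_scale <- NULL
  if (is.numeric(x)) {
    used_scale <- if (is.null(scale)) {
      optimize_scale(x)
    } else if (inherits(scale, "nrsdm_scale")) {
      scale
    } else {
      build_scale(scale, x)
    }
    text <- discretize(x, used_scale)
  } else if (is.character(x) && length(x) == 1L) {
    text <- x
  } else {
    stop("`x` must be a numeric series or a single character string")
  }
  depth0 <- find_repeats(text, rq = rq, min_len = min_len)
  tree <- decompose_nested(text, rq = rq, min_len = min_len, depth0 = depth0)
  cx <- msic(tree)
  structure(list(text = text, L = nchar(text), scale = used_scale,
                 config = list(rq = as.integer(rq), min_len = as.integer(min_len)),
                 asrsm = depth0, tree = cx$tree, complexity = cx, call = cl),
            class = "nrsdm")
}

#' @export
print.nrsdm <- function(x, ...) {
  cat(sprintf("Nested repeated sequence decomposition (rq = %d)\n", x$config$rq))
  cat(sprintf("  text length %d, %d depth-0 symbol(s), noise fraction %.4f\n",
              x$L, nrow(x$asrsm$symbols), x$asrsm$noise_fraction))
  st <- x$tree$stats
  cat(sprintf("  tree: %d node(s), max depth %d, %d leaf/leaves\n",
              st$n_nodes, st$max_depth, st$n_leaves))
  cat(sprintf("  Complexity: MSIC/NPC = %.4g/%.4g\n",
              x$complexity$msic, x$complexity$npc_root))
  invisible(x)
}

#' @export
summary.nrsdm <- function(object, ...) {
  out <- list(config = object$config,
              L = object$L,
              scale = object$scale,
              spectrogram = spectrogram(object$asrsm),
              stats = object$tree$stats,
              msic = object$complexity$msic,
              npc_root = object$complexity$npc_root,
              nodes = tree_nodes(object))
  class(out) <- "summary.nrsdm"
  out
}

#' @export
print.summary.nrsdm <- function(x, ...) {
  cat(sprintf("NRSDM fit: L = %d, rq = %d, min_len = %d\n",
              x$L, x$config$rq, x$config$min_len))
  if (!is.null(x$scale))
    cat(sprintf("  scale: %s (%s, s = %d)\n", x$scale$spec, x$scale$type,
                x$scale$resolution))
  cat(sprintf("  tree: %d nodes, max depth %d, mean branching %.2f\n",
              x$stats$n_nodes, x$stats$max_depth, x$stats$mean_branching))
  cat(sprintf("  Complexity: MSIC/NPC = %.4g/%.4g\n\n", x$msic, x$npc_root))
  cat("Depth-0 spectrogram (length : frequency : probability):\n")
  if (nrow(x$spectrogram)) print(x$spectrogram, row.names = FALSE)
  else cat("  (no repeated sequences)\n")
  invisible(x)
}

#' Per-node coverage probabilities of a fit
#'
#' The decomposition's "coefficients": for every non-root node, the fraction
#' of the original text its effective occurrences cover, named by sequence.
#'
#' @param object An `nrsdm` fit.
#' @param ... Unused.
#' @return Named numeric vector of coverage probabilities `Q`.
#' @export
coef.nrsdm <- function(object, ...) {
  nodes <- tree_nodes(object)
  nodes <- nodes[!is.na(nodes$parent), , drop = FALSE]
  stats::setNames(nodes$q, nodes$sequence)
}

#' Noise characters of a fit
#'
#' The depth-0 residual: characters of the text never covered by any repeated
#' sequence, named by their 0-based positions.
#'
#' @param object An `nrsdm` fit.
#' @param ... Unused.
#' @return Named character vector.
#' @export
residuals.nrsdm <- function(object, ...) {
  stats::setNames(object$asrsm$noise_chars,
                  as.character(object$asrsm$noise_positions))
}

#' Plot an NRSDM fit
#'
#' Log-log probability-versus-length view of the decomposition: MSIR dots
#' (aggregated over depth) or NPR bubbles (per node, bubble size decreasing
#' with nesting depth), over faint equal-repetition bands.
#'
#' @param x An `nrsdm` fit.
#' @param type `"msir"` or `"npr"`.
#' @param bands Draw equal-repetition band lines.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nrsdm <- function(x, type = c("msir", "npr"), bands = TRUE, ...) {
  type <- match.arg(type)
  if (type == "msir") plot_msir(x, bands = bands, ...)
  else plot_npr(x, bands = bands, ...)
}
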