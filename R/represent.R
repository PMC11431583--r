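# Probability-versus-length representations of a decomposition tree:
# the multiscale integral representation (MSIR, aggregated over depth) and
# the nested pattern representation (NPR, one point per node with its depth),
# plus the equal-repetition band lines they align on.

#' Multiscale integral representation table
#'
#' Aggregates all non-root nodes of the tree by sequence length, disregarding
#' nesting depth: for each length, the summed original-text coverage
#' probability and the summed effective count. Each row satisfies
#' `prob = count * length / L0` exactly.
#'
#' @param tree An `nrsdm_tree` or `nrsdm` fit with effective counts annotated.
#' @return data.frame with `length`, `prob`, `count`, sorted by length.
#' @export
msir_table <- function(tree) {
  nodes <- tree_nodes(tree)
  nodes <- nodes[!is.na(nodes$parent), , drop = FALSE]
  if (!nrow(nodes))
    return(data.frame(length = integer(0), prob = numeric(0), count = numeric(0)))
  prob <- stats::aggregate(q ~ length, data = nodes, FUN = sum)
  cnt <- stats::aggregate(effective_count ~ length, data = nodes, FUN = sum)
  out <- merge(prob, cnt, by = "length")
  names(out) <- c("length", "prob", "count")
  out[order(out$length), , drop = FALSE]
}

#' Nested pattern representation table
#'
#' One row per non-root node, keeping its nesting depth: length, coverage
#' probability `Q = effective_count * length / L0`, depth and effective count.
#' No aggregation is performed, so identical sequences under different parents
#' appear as separate rows.
#'
#' @param tree An `nrsdm_tree` or `nrsdm` fit with effective counts annotated.
#' @return data.frame with `length`, `prob`, `depth`, `count`, ordered by
#'   depth then decreasing length.
#' @export
npr_table <- function(tree) {
  nodes <- tree_nodes(tree)
  nodes <- nodes[!is.na(nodes$parent), , drop = FALSE]
  if (!nrow(nodes))
    return(data.frame(length = integer(0), prob = numeric(0),
                      depth = integer(0), count = numeric(0)))
  out <- data.frame(length = nodes$length, prob = nodes$q,
                    depth = nodes$depth, count = nodes$effective_count)
  out[order(out$depth, -out$length), , drop = FALSE]
}

#' Equal-repetition band lines
#'
#' For each repetition count `r` in `[r_min, r_max]`, the band
#' `prob(l) = r * l / L` on which all symbols with effective count `r` lie.
#' On log-log axes these are parallel unit-slope lines.
#'
#' @param L Original text length.
#' @param r_min,r_max Integer repetition-count range (`r_min >= 2`).
#' @param lengths Lengths at which to evaluate each band (default `1..L/r`).
#' @return data.frame with `r`, `length`, `prob`.
#' @export
repetition_bands <- function(L, r_min = 2L, r_max = 8L, lengths = NULL) {
  if (r_min < 2L) stop("`r_min` must be >= 2")
  if (r_max < r_min) stop("`r_max` must be >= `r_min`")
  rows <- lapply(seq.int(r_min, r_max), function(r) {
    l <- if (is.null(lengths)) seq_len(max(L %/% r, 1L)) else lengths
    data.frame(r = r, length = l, prob = pmin(r * l / L, 1))
  })
  do.call(rbind, rows)
}

plot_prob_length <- function(tab, L, style = c("msir", "npr"), bands = TRUE,
                             band_r = NULL, main = NULL, ...) {
  style <- match.arg(style)
  if (is.null(main)) main <- toupper(style)
  if (!nrow(tab)) {
    graphics::plot(1, 1, type = "n", log = "xy", xlim = c(1, max(L, 2)),
                   ylim = c(1 / max(L, 2), 1), xlab = "sequence length l",
                   ylab = "probability", main = main, ...)
    return(invisible(NULL))
  }
  xlim <- range(tab$length) * c(0.8, 1.25)
  ylim <- range(tab$prob) * c(0.5, 2)
  graphics::plot(NA, NA, log = "xy", xlim = xlim, ylim = pmin(ylim, 1.5),
                 xlab = "sequence length l", ylab = "probability",
                 main = main, ...)
  if (bands) {
    rr <- if (is.null(band_r)) sort(unique(round(tab$count))) else band_r
    rr <- rr[rr >= 2]
    for (r in utils::head(rr, 12)) {
      ll <- exp(seq(log(xlim[1]), log(xlim[2]), length.out = 50))
      graphics::lines(ll, r * ll / L, col = "grey80", lty = 3)
    }
  }
  if (style == "msir") {
    graphics::points(tab$length, tab$prob, pch = 16, col = "steelblue")
  } else {
    # bubble size decreases with nesting depth (largest = depth 1)
    dmax <- max(tab$depth)
    cex <- 0.6 + 2.2 * (dmax - tab$depth + 1) / dmax
    graphics::points(tab$length, tab$prob, pch = 21, cex = cex,
                     bg = grDevices::adjustcolor("tomato", 0.5), col = "tomato4")
  }
  invisible(NULL)
}

#' Plot the MSIR of a decomposition
#'
#' Log-log scatter of coverage probability against sequence length, aggregated
#' over depth, with faint equal-repetition guide bands.
#'
#' @param tree An `nrsdm_tree` or `nrsdm` fit.
#' @param bands Draw equal-repetition band lines.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_msir <- function(tree, bands = TRUE, ...) {
  L <- if (inherits(tree, "nrsdm")) tree$tree$L0 else tree$L0
  plot_prob_length(msir_table(tree), L, "msir", bands = bands, ...)
}

#' Plot the NPR of a decomposition
#'
#' Log-log bubble plot of coverage probability against sequence length, one
#' bubble per node; smaller bubbles are more deeply nested sequences.
#'
#' @inheritParams plot_msir
#' @export
plot_npr <- function(tree, bands = TRUE, ...) {
  L <- if (inherits(tree, "nrsdm")) tree$tree$L0 else tree$L0
  plot_prob_length(npr_table(tree), L, "npr", bands = bands, ...)
}
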