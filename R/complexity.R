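# Entropy-based complexity of a decomposition: nested pattern complexity
# (NPC) per node and multiscale integral complexity (MSIC) over the tree.

#' Symbol census of a decomposition node
#'
#' The node's description as a multiset of symbol types: each child symbol is
#' one type with its in-parent count, and each distinct noise character is one
#' type with its occurrence count among the node's noise positions. For a leaf
#' the census is simply its raw characters grouped by identity. `d` is the
#' symbolic diversity (number of types) and `N` the total instance count.
#'
#' @param node A node list from an `nrsdm_tree` (e.g. `tree$root`).
#' @return List with `types` (character), `counts` (integer), `d`, `N`.
#' @export
node_census <- function(node) {
  if (is.null(node$sequence)) stop("`node` must be a decomposition node")
  if (length(node$children)) {
    types <- vapply(node$children, `[[`, "", "sequence")
    counts <- vapply(node$children, `[[`, 0L, "count_in_parent")
    if (length(node$noise$char)) {
      nt <- table(node$noise$char)
      types <- c(types, names(nt))
      counts <- c(counts, as.integer(nt))
    }
  } else {
    nt <- table(chars_of(node$sequence))
    types <- names(nt)
    counts <- as.integer(nt)
  }
  list(types = types, counts = as.integer(counts),
       d = length(types), N = sum(counts))
}

#' Nested pattern complexity of a census
#'
#' Entropy of one node's description: with `d` symbol types of counts `n_i`
#' and `N = sum(n_i)` instances, `NPC = sum_i (n_i/N) * log_d(N/n_i)`. By
#' convention NPC is 0 when `d <= 1` (a description with a single type carries
#' no pattern diversity). NPC lies in `[0, 1]` and equals 1 exactly when all
#' counts are equal and `d >= 2`.
#'
#' @param census A census from [node_census()], or a bare vector of positive
#'   counts.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' npc(c(2, 2))        # 1
#' npc(c(4))           # 0
#' @export
npc <- function(census) {
  counts <- if (is.list(census)) census$counts else census
  counts <- counts[counts > 0]
  d <- length(counts)
  if (d <= 1L) return(0)
  N <- sum(counts)
  p <- counts / N
  sum(p * log(1 / p, base = d))
}

annotate_npc <- function(node) {
  node$npc <- npc(node_census(node))
  node$children <- lapply(node$children, annotate_npc)
  node
}

#' Multiscale integral complexity of a decomposition tree
#'
#' Computes the NPC of every node and sums it over all non-leaf (branch)
#' nodes: `MSIC = sum of NPC over nodes with at least one child`. Trees with
#' more than one nesting level and non-degenerate branch censuses have
#' `1 < MSIC <` (number of branch nodes). A tree with no repeats at all has
#' `MSIC = NPC(root)` computed on the raw characters.
#'
#' @param tree An `nrsdm_tree` (or `nrsdm` fit).
#' @return List of class `nrsdm_complexity`: `msic`, `npc_root`,
#'   `n_branch_nodes`, `n_leaves`, `tree` (the NPC-annotated tree) and
#'   `table` (per-node data.frame with `depth`, `d`, `N`, `npc`, `is_leaf`).
#' @export
msic <- function(tree) {
  if (inherits(tree, "nrsdm")) tree <- tree$tree
  stopifnot(inherits(tree, "nrsdm_tree"))
  tree$root <- annotate_npc(tree$root)
  rows <- walk_nodes(tree$root, function(n) {
    cen <- node_census(n)
    data.frame(depth = n$depth, sequence = n$sequence, d = cen$d, N = cen$N,
               npc = n$npc, is_leaf = length(n$children) == 0L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  branch <- tab[!tab$is_leaf, , drop = FALSE]
  msic_val <- if (nrow(branch)) sum(branch$npc) else tab$npc[1]
  structure(list(msic = msic_val,
                 npc_root = tab$npc[1],
                 n_branch_nodes = max(nrow(branch), 1L),
                 n_leaves = sum(tab$is_leaf),
                 tree = tree,
                 table = tab),
            class = "nrsdm_complexity")
}

#' @export
print.nrsdm_complexity <- function(x, ...) {
  cat(sprintf("Complexity: MSIC/NPC = %.4g/%.4g (%d branch node(s), %d leaf(s))\n",
              x$msic, x$npc_root, x$n_branch_nodes, x$n_leaves))
  invisible(x)
}
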