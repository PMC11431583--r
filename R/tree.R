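# Nested repeated sequence decomposition: recursive application of the
# greedy repeat search inside every symbol found, yielding a tree whose
# non-leaf nodes are symbols that still contain internal repeats.

node_from_asrsm <- function(sequence, count_in_parent, asrsm) {
  list(sequence = sequence,
       depth = NA_integer_,
       count_in_parent = count_in_parent,
       effective_count = NA_real_,
       q = NA_real_,
       npc = NA_real_,
       noise = list(pos = asrsm$noise_positions, char = asrsm$noise_chars),
       children = list())
}

# Identical sequences are decomposed identically (rq and min_len are constant
# across depths), so subtrees are memoized by sequence; the logical model
# still keeps one node per parent-child relation (depths and counts are
# annotated per instance afterwards).
build_node <- function(sequence, count_in_parent, rq, min_len, memo,
                       asrsm = NULL) {
  cached <- memo[[sequence]]
  if (!is.null(cached)) {
    cached$count_in_parent <- count_in_parent
    return(cached)
  }
  res <- if (is.null(asrsm)) find_repeats(sequence, rq = rq, min_len = min_len)
         else asrsm
  node <- node_from_asrsm(sequence, count_in_parent, res)
  if (nrow(res$symbols)) {
    node$children <- lapply(seq_len(nrow(res$symbols)), function(i) {
      build_node(res$symbols$sequence[i], res$symbols$count[i],
                 rq, min_len, memo)
    })
  }
  memo[[sequence]] <- node
  node
}

#' Nested repeated sequence decomposition of a text
#'
#' Applies the greedy longest-first repeat search ([find_repeats()]) to the
#' whole text and then, recursively with the same `rq`, to every symbol found,
#' until symbols contain no internal repeat of `min_len` or more characters
#' appearing at least `rq` times. Identical sequences found under different
#' parents are decomposed independently (one node per parent-child relation).
#' Effective counts (in-parent count multiplied along the ancestor chain) and
#' original-text coverage `Q = effective_count * length / L0` are annotated on
#' every node.
#'
#' @param text Non-empty character string.
#' @param rq Minimum occurrence count (`>= 2`), constant across depths.
#' @param min_len Minimum symbol length (`>= 2`).
#' @param depth0 Optional precomputed [find_repeats()] result for `text`
#'   (avoids repeating the depth-0 search when the caller already has it).
#' @return Object of class `nrsdm_tree`: list with `root` (nested node list),
#'   `L0`, `config`, and `stats` (`n_nodes`, `max_depth`, `n_leaves`,
#'   `mean_branching`, `max_branching`).
#' @seealso [nrsdm()] for the full fit including complexity measures.
#' @export
decompose_nested <- function(text, rq = 2L, min_len = 2L, depth0 = NULL) {
  memo <- new.env(parent = emptyenv())
  root <- build_node(text, 1L, as.integer(rq), as.integer(min_len), memo,
                     asrsm = depth0)
  tree <- structure(list(root = root, L0 = nchar(text),
                         config = list(rq = as.integer(rq),
                                       min_len = as.integer(min_len))),
                    class = "nrsdm_tree")
  tree <- effective_counts(tree)
  tree$stats <- tree_stats(tree)
  tree
}

annotate_counts <- function(node, parent_eff, depth, L0) {
  node$depth <- depth
  node$effective_count <- node$count_in_parent * parent_eff
  node$q <- node$effective_count * nchar(node$sequence) / L0
  node$children <- lapply(node$children, annotate_counts,
                          parent_eff = node$effective_count,
                          depth = depth + 1L, L0 = L0)
  node
}

#' Annotate effective counts and coverage on a decomposition tree
#'
#' Every node gets `effective_count = count_in_parent * parent effective
#' count` (1 at the root) and coverage `Q = effective_count * length / L0`,
#' which for depth-1 symbols reduces to the plain coverage probability.
#' Called by [decompose_nested()]; exposed for re-annotation after manual
#' edits or deserialization.
#'
#' @param tree An `nrsdm_tree`.
#' @return The tree with annotations filled in.
#' @export
effective_counts <- function(tree) {
  stopifnot(inherits(tree, "nrsdm_tree"))
  tree$root <- annotate_counts(tree$root, parent_eff = 1, depth = 0L,
                               L0 = tree$L0)
  tree$root$effective_count <- 1
  tree$root$q <- 1
  tree
}

walk_nodes <- function(node, f, acc = list()) {
  acc[[length(acc) + 1L]] <- f(node)
  for (ch in node$children) acc <- walk_nodes(ch, f, acc)
  acc
}

tree_stats <- function(tree) {
  depths <- unlist(walk_nodes(tree$root, function(n) n$depth))
  branching <- unlist(walk_nodes(tree$root, function(n) length(n$children)))
  nonleaf <- branching[branching > 0]
  list(n_nodes = length(depths),
       max_depth = max(depths),
       n_leaves = sum(branching == 0L),
       mean_branching = if (length(nonleaf)) mean(nonleaf) else 0,
       max_branching = if (length(nonleaf)) max(nonleaf) else 0L)
}

#' Flat node table of a decomposition tree
#'
#' One row per node, in depth-first pre-order: node id, parent id, depth,
#' sequence, length, in-parent count, effective count, coverage `Q`, noise
#' character count and leaf flag. `npc` is filled when the tree comes from
#' [nrsdm()] or [msic()].
#'
#' @param tree An `nrsdm_tree` or `nrsdm` fit.
#' @return data.frame, one row per node.
#' @export
tree_nodes <- function(tree) {
  if (inherits(tree, "nrsdm")) tree <- tree$tree
  stopifnot(inherits(tree, "nrsdm_tree"))
  rows <- list()
  rec <- function(node, parent_id) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(
      id = id, parent = parent_id, depth = node$depth,
      sequence = node$sequence, length = nchar(node$sequence),
      count_in_parent = node$count_in_parent,
      effective_count = node$effective_count, q = node$q,
      n_noise = length(node$noise$pos),
      npc = node$npc,
      is_leaf = length(node$children) == 0L,
      stringsAsFactors = FALSE)
    for (ch in node$children) rec(ch, id)
  }
  rec(tree$root, NA_integer_)
  do.call(rbind, rows)
}

canonical_serialization <- function(node) {
  child_digests <- vapply(node$children, function(ch) {
    paste0(canonical_digest(ch), ":", ch$count_in_parent)
  }, "")
  noise <- paste(paste0(node$noise$pos, "=", node$noise$char), collapse = ",")
  paste0("seq{", node$sequence, "}noise{", noise, "}children{",
         paste(sort(child_digests), collapse = ";"), "}")
}

canonical_digest <- function(node) sha256_hex(canonical_serialization(node))

#' Structural digest of a decomposition (sub)tree
#'
#' SHA-256 of a canonical serialization of the node: its sequence, its noise
#' characters with positions, and the sorted digests of its children with
#' their in-parent counts. Equal decompositions give equal digests; any change
#' in structure, counts or noise changes the digest with overwhelming
#' probability. The digest is platform-independent.
#'
#' @param x An `nrsdm` fit, an `nrsdm_tree`, or a single node list.
#' @return Lowercase hex string (64 characters).
#' @export
tree_hash <- function(x) {
  if (inherits(x, "nrsdm")) x <- x$tree
  node <- if (inherits(x, "nrsdm_tree")) x$root else x
  if (is.null(node$sequence)) stop("`x` must be a decomposition tree or node")
  canonical_digest(node)
}
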