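# Independent brute-force reference for the greedy longest-first repeat
# extraction: plain descending length scan, explicit pattern enumeration,
# greedy left-to-right occurrence counting. Deliberately simple; used only
# on short texts.

oracle_greedy_positions <- function(chs, pattern_chs, locked) {
  L <- length(chs); l <- length(pattern_chs)
  sel <- integer(0)
  p <- 1L
  while (p <= L - l + 1L) {
    win <- p:(p + l - 1L)
    if (!any(locked[win]) && all(chs[win] == pattern_chs)) {
      sel <- c(sel, p)
      p <- p + l
    } else {
      p <- p + 1L
    }
  }
  sel
}

# best qualifying candidate at one length, or NULL: leftmost first counted
# occurrence wins, ties broken by lexicographically smallest pattern
oracle_best_at_length <- function(chs, l, locked, rq) {
  L <- length(chs)
  best <- NULL
  seen <- character(0)
  for (p in seq_len(L - l + 1L)) {
    win <- p:(p + l - 1L)
    if (any(locked[win])) next
    pat <- paste(chs[win], collapse = "")
    if (pat %in% seen) next
    seen <- c(seen, pat)
    sel <- oracle_greedy_positions(chs, chs[win], locked)
    if (length(sel) >= rq) {
      if (is.null(best) || sel[1] < best$first ||
          (sel[1] == best$first && pat < best$sequence)) {
        best <- list(sequence = pat, first = sel[1], positions = sel,
                     count = length(sel))
      }
    }
  }
  best
}

oracle_asrsm <- function(text, rq = 2L, min_len = 2L) {
  chs <- strsplit(text, "", fixed = TRUE)[[1]]
  L <- length(chs)
  locked <- logical(L)
  syms <- list()
  l <- L %/% rq
  while (l >= min_len) {
    best <- oracle_best_at_length(chs, l, locked, rq)
    if (is.null(best)) {
      l <- l - 1L
    } else {
      syms[[length(syms) + 1L]] <- list(sequence = best$sequence, length = l,
                                        count = best$count,
                                        positions = best$positions - 1L)
      for (p in best$positions) locked[p:(p + l - 1L)] <- TRUE
      # re-scan the same length before descending
    }
  }
  list(symbols = syms, noise_positions = which(!locked) - 1L,
       noise_chars = chs[!locked])
}

oracle_tree <- function(text, rq = 2L, min_len = 2L) {
  res <- oracle_asrsm(text, rq, min_len)
  children <- lapply(res$symbols, function(s) {
    sub <- oracle_tree(s$sequence, rq, min_len)
    sub$count_in_parent <- s$count
    sub
  })
  list(sequence = text, count_in_parent = 1L,
       noise = list(pos = res$noise_positions, char = res$noise_chars),
       children = children)
}

# compare implementation node against oracle node (structure, counts, noise)
expect_tree_matches_oracle <- function(node, oracle) {
  expect_identical(node$sequence, oracle$sequence)
  expect_identical(as.integer(node$count_in_parent),
                   as.integer(oracle$count_in_parent))
  expect_identical(as.integer(node$noise$pos), as.integer(oracle$noise$pos))
  expect_identical(as.character(node$noise$char), as.character(oracle$noise$char))
  expect_identical(length(node$children), length(oracle$children))
  for (i in seq_along(node$children)) {
    expect_tree_matches_oracle(node$children[[i]], oracle$children[[i]])
  }
}

random_text <- function(len, alphabet_size) {
  paste(sample(letters[seq_len(alphabet_size)], len, replace = TRUE),
        collapse = "")
}

# the tangential May pipeline used across tests
may_text <- function(rho, n, x0 = 0.5, spec = "T: 20/10/0.01") {
  x <- may_map(rho, n, x0)
  discretize(x, build_scale(spec, x))
}
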