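# Greedy longest-first extraction of non-overlapping repeated sequences.
#
# All exported position outputs are 0-based with half-open occurrence
# intervals [start, start + length); internal computation is 1-based.

chars_of <- function(text) strsplit(text, "", fixed = TRUE)[[1]]

greedy_pick <- function(pos, len) {
  # maximal left-to-right set of pairwise non-overlapping starts (1-based)
  sel <- integer(0); nxt <- -Inf
  for (p in pos) {
    if (p >= nxt) { sel <- c(sel, p); nxt <- p + len }
  }
  sel
}

#' Count non-overlapping occurrences of a pattern
#'
#' Greedy left-to-right maximal set of exact, non-overlapping occurrences of
#' `pattern` in `text` that contain no masked position. Greedy left-to-right
#' selection is optimal in count for a fixed pattern.
#'
#' @param text Character string to scan.
#' @param pattern Non-empty character string.
#' @param mask Optional logical vector, one flag per text position; `TRUE`
#'   positions are locked and occurrences may not touch them.
#' @return List with `count` and `positions` (0-based start offsets of the
#'   counted occurrences).
#' @examples
#' count_nonoverlapping("aaaa", "aa")  # count 2, positions 0 and 2
#' @export
count_nonoverlapping <- function(text, pattern, mask = NULL) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L)
    stop("`pattern` must be a non-empty string")
  L <- nchar(text); l <- nchar(pattern)
  if (is.null(mask)) mask <- logical(L)
  if (length(mask) != L) stop("`mask` must have one flag per text position")
  if (l > L) return(list(count = 0L, positions = integer(0)))
  starts <- seq_len(L - l + 1L)
  hits <- starts[substring(text, starts, starts + l - 1L) == pattern]
  if (any(mask)) {
    cm <- c(0L, cumsum(mask))
    hits <- hits[cm[hits + l] - cm[hits] == 0L]
  }
  sel <- greedy_pick(hits, l)
  list(count = length(sel), positions = as.integer(sel - 1L))
}

# Scan one candidate length: among all length-l sequences with >= rq greedy
# non-overlapping occurrences in fully unlocked windows, return the one whose
# first occurrence starts leftmost (ties: lexicographically smallest pattern),
# or NULL. `cumlock` = c(0, cumsum(locked)).
scan_length <- function(text, L, l, cumlock, rq) {
  if (l > L) return(NULL)
  p <- seq_len(L - l + 1L)
  p <- p[cumlock[p + l] - cumlock[p] == 0L]
  if (length(p) < rq) return(NULL)
  groups <- split(p, substring(text, p, p + l - 1L))
  best <- NULL
  for (w in names(groups)) {
    pos <- groups[[w]]
    if (length(pos) < rq) next
    sel <- greedy_pick(pos, l)
    if (length(sel) >= rq &&
        (is.null(best) || sel[1] < best$positions[1] ||
         (sel[1] == best$positions[1] && w < best$sequence))) {
      best <- list(sequence = w, positions = sel, count = length(sel))
    }
  }
  best
}

# Largest l in [min_len, cap] with a qualifying candidate. The predicate is
# monotone (the prefix of a qualifying length-l sequence qualifies at l - 1),
# so binary search finds the same length a descending scan would reach first.
next_extraction <- function(text, L, cap, cumlock, rq, min_len) {
  hit <- scan_length(text, L, cap, cumlock, rq)
  if (!is.null(hit)) return(list(len = cap, cand = hit))
  lo <- min_len; hi <- cap - 1L; found <- NULL
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    hit <- scan_length(text, L, mid, cumlock, rq)
    if (!is.null(hit)) { found <- list(len = mid, cand = hit); lo <- mid + 1L }
    else hi <- mid - 1L
  }
  found
}

#' Extract the at-scale repeated sequence decomposition of a text
#'
#' Greedy longest-first search for exact repeated sequences: candidate lengths
#' run from `floor(L/rq)` down to `min_len`; at each length the text is
#' scanned for a sequence with at least `rq` non-overlapping occurrences in
#' unlocked positions (ties among equal-length candidates go to the leftmost
#' first occurrence, then the lexicographically smallest sequence). Each found
#' symbol's occurrences are locked and the same length is re-scanned before
#' descending. Characters never covered by a symbol are noise.
#'
#' @param text Non-empty character string.
#' @param rq Minimum occurrence count for a sequence to become a symbol
#'   (`rq >= 2`).
#' @param min_len Minimum symbol length (`>= 2`; single characters are noise).
#' @return Object of class `asrsm`: list with `symbols` (data.frame of
#'   `sequence`, `length`, `count`, `extraction_rank`, plus a list column
#'   `positions` of 0-based starts), `noise_positions` (0-based),
#'   `noise_chars`, `L`, `coverage_fraction` and `noise_fraction`.
#' @examples
#' r <- find_repeats("xyxyxyxy", rq = 2)
#' r$symbols$sequence  # "xyxy" (length floor(8/2) = 4 found first)
#' @seealso [nrsdm()] for the nested (recursive) decomposition.
#' @export
find_repeats <- function(text, rq = 2L, min_len = 2L) {
  if (!is.character(text) || length(text) != 1L || nchar(text) < 1L)
    stop("`text` must be a non-empty string")
  rq <- as.integer(rq); min_len <- as.integer(min_len)
  if (is.na(rq) || rq < 2L) stop("`rq` must be an integer >= 2")
  if (is.na(min_len) || min_len < 2L) stop("`min_len` must be an integer >= 2")
  L <- nchar(text)
  locked <- logical(L)
  cap <- L %/% rq
  seqs <- character(0); lens <- integer(0); counts <- integer(0)
  poss <- list()
  while (cap >= min_len) {
    cumlock <- c(0L, cumsum(locked))
    nxt <- next_extraction(text, L, cap, cumlock, rq, min_len)
    if (is.null(nxt)) break
    cand <- nxt$cand
    seqs <- c(seqs, cand$sequence)
    lens <- c(lens, nxt$len)
    counts <- c(counts, cand$count)
    poss[[length(poss) + 1L]] <- as.integer(cand$positions - 1L)
    for (p in cand$positions) locked[p:(p + nxt$len - 1L)] <- TRUE
    cap <- nxt$len  # re-scan the same length before descending
  }
  symbols <- data.frame(sequence = seqs,
                        length = lens,
                        count = counts,
                        extraction_rank = seq_along(seqs),
                        stringsAsFactors = FALSE)
  symbols$positions <- poss
  noise <- which(!locked)
  covered <- if (length(lens)) sum(as.numeric(lens) * counts) else 0
  structure(list(symbols = symbols,
                 noise_positions = as.integer(noise - 1L),
                 noise_chars = if (length(noise)) chars_of(text)[noise] else character(0),
                 L = L,
                 coverage_fraction = covered / L,
                 noise_fraction = length(noise) / L,
                 rq = rq, min_len = min_len,
                 text = text),
            class = "asrsm")
}

#' @export
print.asrsm <- function(x, ...) {
  cat(sprintf("<asrsm> text length %d, %d symbol(s), coverage %.3f, noise %.3f (rq = %d)\n",
              x$L, nrow(x$symbols), x$coverage_fraction, x$noise_fraction, x$rq))
  if (nrow(x$symbols)) {
    show <- utils::head(x$symbols[c("sequence", "length", "count")], 10)
    show$sequence <- ifelse(nchar(show$sequence) > 40,
                            paste0(substr(show$sequence, 1, 37), "..."),
                            show$sequence)
    print(show, row.names = FALSE)
    if (nrow(x$symbols) > 10) cat("  ...", nrow(x$symbols) - 10, "more\n")
  }
  invisible(x)
}

#' Coverage probability of a repeated sequence
#'
#' Fraction of the original text occupied by the counted occurrences of a
#' sequence: `Q = count * length / L0`. For nested symbols the effective count
#' (in-parent count multiplied along the ancestor chain) plays the role of
#' `count`.
#'
#' @param count Occurrence count (or effective count for nested symbols).
#' @param length Sequence length in characters.
#' @param L0 Original text length, `> 0`.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' coverage_probability(2, 15, 42)  # 30/42
#' @export
coverage_probability <- function(count, length, L0) {
  if (any(L0 <= 0)) stop("`L0` must be positive")
  count * length / L0
}

#' Length spectrogram of a repeat decomposition
#'
#' Groups the symbols of an [find_repeats()] result by length: one row per
#' distinct length with the summed occurrence count (`frequency`) and summed
#' coverage of the original text (`prob = frequency * length / L`).
#'
#' @param x An `asrsm` object.
#' @return data.frame with columns `length`, `frequency`, `prob`, sorted by
#'   ascending length.
#' @export
spectrogram <- function(x) {
  if (!inherits(x, "asrsm")) stop("`x` must be an asrsm object")
  if (!nrow(x$symbols))
    return(data.frame(length = integer(0), frequency = integer(0), prob = numeric(0)))
  agg <- stats::aggregate(count ~ length, data = x$symbols, FUN = sum)
  out <- data.frame(length = agg$length,
                    frequency = agg$count,
                    prob = coverage_probability(agg$count, agg$length, x$L))
  out[order(out$length), , drop = FALSE]
}
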