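# Readers and writers: numeric series (CSV/TSV), symbolic texts (plain/FASTA),
# decomposition trees (JSON, TSV), config sidecars (YAML).

#' Read a numeric series from CSV or TSV
#'
#' Separator is inferred from the extension (`.csv` comma, otherwise tab /
#' whitespace) unless given. A header line is auto-detected (first line not
#' parseable as numbers). With `column`, that named column is used; otherwise
#' the file must have a single column.
#'
#' @param path File path.
#' @param column Optional column name.
#' @param sep Optional field separator.
#' @return Numeric vector, with attributes `n` and `range`.
#' @export
read_series <- function(path, column = NULL, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  first <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1,
                             colClasses = "character", stringsAsFactors = FALSE)
  header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(column)) {
    if (!column %in% names(df)) {
      stop("column '", column, "' not found; available: ",
           paste(names(df), collapse = ", "))
    }
    raw <- df[[column]]
  } else {
    if (ncol(df) != 1L)
      stop("file has ", ncol(df), " columns; select one with `column`")
    raw <- df[[1]]
  }
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric value '", raw[bad], "' at data row ", bad)
  }
  structure(vals, n = length(vals), range = range(vals))
}

#' Read a symbolic text from a plain or FASTA file
#'
#' Plain files are concatenated with all whitespace stripped; FASTA files
#' yield the single record, or the record named by `record` when there are
#' several. Character case is preserved.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"plain"`, or `"fasta"`.
#' @param record FASTA record id, required for multi-record files.
#' @return Character string.
#' @export
read_text <- function(path, format = c("auto", "plain", "fasta"), record = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna|faa)$", path, ignore.case = TRUE))
      "fasta" else "plain"
  }
  if (format == "plain") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    txt <- gsub("\\s+", "", txt)
    if (nchar(txt) == 0L) stop("empty text file: ", path)
    return(txt)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  ids <- names(recs)
  if (is.null(record)) {
    if (length(recs) > 1L)
      stop("multiple FASTA records; pick one with `record`: ",
           paste(ids, collapse = ", "))
    record <- ids[1]
  }
  if (!record %in% ids) stop("no FASTA record '", record, "'")
  as.character(recs[[record]])
}

#' Write a symbolic text
#'
#' @param text Character string.
#' @param path Output path.
#' @param format `"plain"` (one line) or `"fasta"` (single record, 80-char
#'   wrapped).
#' @param name FASTA record name.
#' @return `path`, invisibly.
#' @export
write_text <- function(text, path, format = c("plain", "fasta"), name = "text") {
  format <- match.arg(format)
  if (format == "plain") {
    writeLines(text, path)
  } else {
    seqinr::write.fasta(text, names = name, file.out = path, nbchar = 80,
                        as.string = TRUE)
  }
  invisible(path)
}

node_to_list <- function(node) {
  list(sequence = node$sequence,
       depth = node$depth,
       count_in_parent = node$count_in_parent,
       effective_count = node$effective_count,
       q = node$q,
       npc = node$npc,
       noise = list(pos = as.integer(node$noise$pos),
                    char = as.character(node$noise$char)),
       children = lapply(node$children, node_to_list))
}

list_to_node <- function(x) {
  list(sequence = x$sequence,
       depth = as.integer(x$depth),
       count_in_parent = as.integer(x$count_in_parent),
       effective_count = as.numeric(x$effective_count),
       q = as.numeric(x$q),
       npc = if (is.null(x$npc)) NA_real_ else as.numeric(x$npc),
       noise = list(pos = as.integer(unlist(x$noise$pos)),
                    char = as.character(unlist(x$noise$char))),
       children = lapply(x$children, list_to_node))
}

#' Write a decomposition tree to JSON
#'
#' Nested objects `{sequence, depth, count_in_parent, effective_count, q, npc,
#' noise{pos, char}, children[]}` with 0-based noise positions, plus top-level
#' `L0` and `config`. Round-trips losslessly: reading the file back gives a
#' tree with an identical [tree_hash()].
#'
#' @param tree An `nrsdm_tree` or `nrsdm` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  if (inherits(tree, "nrsdm")) tree <- tree$tree
  stopifnot(inherits(tree, "nrsdm_tree"))
  obj <- list(L0 = tree$L0, config = tree$config, root = node_to_list(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a decomposition tree from JSON
#'
#' @param path Path written by [write_tree_json()].
#' @return An `nrsdm_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  tree <- structure(list(root = list_to_node(obj$root),
                         L0 = as.integer(obj$L0),
                         config = list(rq = as.integer(obj$config$rq),
                                       min_len = as.integer(obj$config$min_len))),
                    class = "nrsdm_tree")
  tree$stats <- tree_stats(tree)
  tree
}

#' Write a YAML sidecar describing a run configuration
#'
#' @param config Named list of run parameters.
#' @param path Output path (conventionally `<output>.yaml`).
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
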