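#' Read a hyperedge list
#'
#' Parses a plain-text hyperedge list: one hyperedge per line, node tokens
#' separated by whitespace or commas, optionally followed by an integer
#' weight column. Lines starting with \code{#} are comments. Node tokens may
#' be arbitrary strings; they are mapped to a stable 1-based integer index
#' (order of first appearance) retained in \code{node_names}. Duplicate
#' hyperedges accumulate weight.
#'
#' @param con a file path, connection, or (with \code{text =} semantics) a
#'   character vector of lines via \code{text}.
#' @param text character scalar holding the whole input, as an alternative
#'   to \code{con}.
#' @param sep token separator: \code{"whitespace"} or \code{","}.
#' @param weighted if \code{TRUE}, the last token of each line is the edge
#'   weight.
#' @return a \code{hypergraph}.
#' @examples
#' H <- read_hyperedge_list(text = "1 2\n1 2 3\n2 3 4")
#' @export
read_hyperedge_list <- function(con = NULL, text = NULL,
                                sep = c("whitespace", ","),
                                weighted = FALSE) {
  sep <- match.arg(sep)
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(con)
  raw <- lines
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty hyperedge list")
  toks <- if (sep == "whitespace") strsplit(trimws(lines), "\\s+")
          else lapply(strsplit(lines, ",", fixed = TRUE), trimws)
  weights <- rep(1, length(toks))
  if (weighted) {
    for (i in seq_along(toks)) {
      tk <- toks[[i]]
      if (length(tk) < 2L)
        stop(sprintf("line %d: weighted edge needs >= 1 node + weight", lineno[i]))
      w <- suppressWarnings(as.numeric(tk[length(tk)]))
      if (is.na(w) || w <= 0 || w != round(w))
        stop(sprintf("line %d: weight must be a positive integer", lineno[i]))
      weights[i] <- w
      toks[[i]] <- tk[-length(tk)]
    }
  }
  bad <- which(vapply(toks, function(t) length(t) < 1L || any(t == ""), TRUE))
  if (length(bad))
    stop(sprintf("line %d: malformed hyperedge", lineno[bad[1]]))
  names_seen <- unique(unlist(toks, use.names = FALSE))
  edges <- lapply(toks, function(t) match(t, names_seen))
  dup <- which(vapply(edges, anyDuplicated, 1L) > 0L)
  if (length(dup))
    stop(sprintf("line %d: repeated node within a hyperedge", lineno[dup[1]]))
  hypergraph(edges, weights, n = length(names_seen), node_names = names_seen)
}

#' Write a hyperedge list
#'
#' Emits the format read by \code{\link{read_hyperedge_list}}: one hyperedge
#' per line (external node names, whitespace separated) with a trailing
#' weight column, preceded by a comment header recording the node index
#' mapping. Reading the output back yields a hypergraph with identical
#' \code{n}, per-size edge counts and degrees.
#'
#' @param H a \code{hypergraph}.
#' @param con file path or connection; if \code{NULL} the text is returned
#'   invisibly as a character scalar.
#' @export
write_hyperedge_list <- function(H, con = NULL) {
  stopifnot(inherits(H, "hypergraph"))
  header <- c("# hyperedge list: nodes... weight",
              paste0("# node ", seq_len(H$n), " = ", H$node_names))
  body <- vapply(seq_along(H$edges), function(i)
    paste(c(H$node_names[H$edges[[i]]], format(H$weights[i])), collapse = " "),
    "")
  out <- paste(c(header, body), collapse = "\n")
  if (is.null(con)) return(invisible(out))
  writeLines(out, con)
  invisible(out)
}

#' Read a bipartite (node, edge) incidence list
#'
#' Each line holds a node identifier and a hyperedge identifier; all rows
#' sharing an edge identifier form one hyperedge.
#'
#' @inheritParams read_hyperedge_list
#' @return a \code{hypergraph}.
#' @export
read_bipartite_edge_list <- function(con = NULL, text = NULL,
                                     sep = c("whitespace", ",")) {
  sep <- match.arg(sep)
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty bipartite edge list")
  toks <- if (sep == "whitespace") strsplit(trimws(lines), "\\s+")
          else lapply(strsplit(lines, ",", fixed = TRUE), trimws)
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad))
    stop(sprintf("line %d: expected 'node edge' pair", lineno[bad[1]]))
  node <- vapply(toks, `[`, "", 1L)
  eid <- vapply(toks, `[`, "", 2L)
  names_seen <- unique(node)
  groups <- split(match(node, names_seen), factor(eid, levels = unique(eid)))
  if (any(vapply(groups, anyDuplicated, 1L) > 0L))
    stop("repeated node within a hyperedge")
  hypergraph(unname(groups), 1, n = length(names_seen),
             node_names = names_seen)
}

#' Read node labels from a two-column TSV
#'
#' @param con file path or connection.
#' @param text character scalar alternative to \code{con}.
#' @param H optional \code{hypergraph}; if given, labels are returned in the
#'   order of \code{H$node_names} and every node must be labelled.
#' @return if \code{H} is given, an integer label vector (1-based, contiguous)
#'   with attribute \code{"levels"}; otherwise a named character vector.
#' @export
read_node_labels <- function(con = NULL, text = NULL, H = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(con)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(toks, length, 1L) != 2L))
    stop("label file must have exactly two tab-separated columns")
  lab <- stats::setNames(vapply(toks, `[`, "", 2L), vapply(toks, `[`, "", 1L))
  if (is.null(H)) return(lab)
  got <- lab[H$node_names]
  if (anyNA(got)) stop("missing label for some nodes")
  lev <- sort(unique(unname(got)))
  structure(match(got, lev), levels = lev)
}

#' Write node labels as a two-column TSV
#'
#' @param H a \code{hypergraph} supplying external node names.
#' @param z integer label vector.
#' @param con file path or connection; \code{NULL} returns the text.
#' @export
write_node_labels <- function(H, z, con = NULL) {
  z <- check_labels(z, H$n)
  out <- paste(paste0(H$node_names, "\t", z), collapse = "\n")
  if (is.null(con)) return(invisible(out))
  writeLines(out, con)
  invisible(out)
}
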