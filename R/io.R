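#' @importFrom stats phyper setNames
#' @importFrom utils write.table
NULL

ppx_message <- function(..., verbose = getOption("ppicomplex.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}

read_lines_any <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      (file.exists(x) || grepl("^(http|ftp)", x))) {
    return(readLines(x, warn = FALSE))
  }
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  as.character(x)
}

#' Read a protein-protein interaction edge list
#'
#' Parses a two-or-more-column whitespace/tab separated edge list of protein
#' identifiers into an undirected simple graph. Following the standard
#' preprocessing for interaction data, self-interactions are dropped and
#' repeated interactions (in either orientation) are collapsed to a single
#' undirected edge. Lines starting with `#` and blank lines are ignored;
#' columns beyond the first two are ignored. Proteins that occur only in
#' self-interactions are not added to the network: an isolated node can never
#' belong to a complex of size three or more.
#'
#' Identifier comparison is case-sensitive exact string match; no identifier
#' mapping is performed.
#'
#' @param x a file path, a connection, or a character vector of lines.
#' @param verbose emit a summary of dropped records (default
#'   `getOption("ppicomplex.verbose", TRUE)`).
#' @return an undirected simple [igraph::graph] whose vertices are protein
#'   ids sorted lexicographically, with attributes `n_self_loops` and
#'   `n_duplicates` recording the number of dropped records.
#' @export
#' @examples
#' g <- read_edge_list(c("A\tB", "B\tA", "C\tC", "A\tB"))
#' igraph::vcount(g) # 2
read_edge_list <- function(x, verbose = getOption("ppicomplex.verbose", TRUE)) {
  lines <- read_lines_any(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed edge-list line ", idx[which(nf < 2L)[1L]],
         ": fewer than 2 fields", call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  self <- a == b
  lo <- pmin(a[!self], b[!self])
  hi <- pmax(a[!self], b[!self])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_self <- sum(self)
  n_dup <- sum(dup)
  lo <- lo[!dup]
  hi <- hi[!dup]
  nodes <- sort(unique(c(lo, hi)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE)[order(lo, hi), ,
                                                             drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "n_self_loops", n_self)
  g <- igraph::set_graph_attr(g, "n_duplicates", n_dup)
  ppx_message("read_edge_list: ", igraph::vcount(g), " proteins, ",
              igraph::ecount(g), " interactions (dropped ", n_self,
              " self-interactions, ", n_dup, " duplicates)",
              verbose = verbose)
  g
}

#' Read a protein-to-GO-term annotation table
#'
#' Parses a 2-3 column whitespace/tab separated table: protein id, GO term
#' id, optional namespace (`BP`, `MF` or `CC`). Term ids are treated as
#' opaque strings; no ontology traversal is performed. Duplicate
#' (protein, term) pairs are collapsed. When `namespaces` is given and a
#' namespace column exists, only rows in the requested namespaces are kept
#' (for edge weighting the usual choice is `c("BP", "MF")`, since the CC
#' namespace itself encodes complex membership).
#'
#' @param x a file path, a connection, or a character vector of lines.
#' @param namespaces optional character vector of namespaces to keep.
#' @param verbose emit a load summary.
#' @return a named list of class `go_annotations`: protein id -> character
#'   vector of term ids (every stored protein has a non-empty term set).
#' @export
read_annotations <- function(x, namespaces = NULL,
                             verbose = getOption("ppicomplex.verbose", TRUE)) {
  lines <- read_lines_any(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed annotation line ", idx[which(nf < 2L)[1L]],
         ": fewer than 2 fields", call. = FALSE)
  }
  prot <- vapply(fields, `[[`, "", 1L)
  term <- vapply(fields, `[[`, "", 2L)
  ns <- ifelse(nf >= 3L, vapply(fields, function(f)
    if (length(f) >= 3L) f[[3L]] else NA_character_, ""), NA_character_)
  if (!is.null(namespaces)) {
    sel <- is.na(ns) | ns %in% namespaces
    prot <- prot[sel]; term <- term[sel]
  }
  key <- paste(prot, term, sep = "\r")
  d <- !duplicated(key)
  prot <- prot[d]; term <- term[d]
  out <- lapply(split(term, prot), function(t) sort(unique(t)))
  out <- out[order(names(out))]
  ppx_message("read_annotations: ", length(out), " annotated proteins, ",
              length(unique(term)), " distinct terms", verbose = verbose)
  structure(out, class = "go_annotations")
}

#' Construct a complex set
#'
#' A `complex_set` is an ordered list of protein-id sets, optionally carrying
#' a per-complex score (for detected complexes, the fitness at which growth
#' stopped). Member ids inside each complex are deduplicated and sorted;
#' the order of complexes is preserved as given (detection order for
#' detected complexes).
#'
#' @param complexes a list of character vectors (each non-empty).
#' @param scores optional numeric vector of per-complex scores.
#' @return an object of class `complex_set`.
#' @export
complex_set <- function(complexes, scores = NULL) {
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  if (any(lengths(complexes) == 0L)) {
    stop("each complex must be a non-empty set", call. = FALSE)
  }
  if (!is.null(scores) && length(scores) != length(complexes)) {
    stop("scores must match the number of complexes", call. = FALSE)
  }
  structure(list(complexes = complexes, scores = scores),
            class = "complex_set")
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' @export
print.complex_set <- function(x, ...) {
  cat("<complex_set> ", length(x$complexes), " complexes, sizes ",
      if (length(x$complexes)) paste(range(lengths(x$complexes)),
                                     collapse = "-") else "-",
      "\n", sep = "")
  invisible(x)
}

#' Read a complex file (one complex per line)
#'
#' Each non-blank line lists the members of one complex, separated by spaces
#' or tabs (the flat format used by common gold-standard catalogues such as
#' CYC2008 exports). Duplicate ids within a line are collapsed.
#'
#' @param x a file path, a connection, or a character vector of lines.
#' @param min_size drop complexes with fewer members (default 1 keeps all;
#'   gold standards are conventionally filtered at 3).
#' @return a [complex_set].
#' @export
read_complexes <- function(x, min_size = 1L) {
  lines <- read_lines_any(x)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cx <- lapply(strsplit(trimws(lines), "\\s+"), function(m) sort(unique(m)))
  cx <- cx[lengths(cx) >= min_size]
  # exact duplicates dropped (reference de-duplication)
  key <- vapply(cx, paste, "", collapse = "\r")
  complex_set(cx[!duplicated(key)])
}

#' Write a complex set
#'
#' One complex per line, members sorted lexicographically and separated by
#' tabs, in the stored (detection) order, so output is deterministic.
#'
#' @param cs a [complex_set].
#' @param path output file path or connection.
#' @export
write_complexes <- function(cs, path) {
  stopifnot(inherits(cs, "complex_set"))
  writeLines(vapply(cs$complexes, paste, "", collapse = "\t"), path)
  invisible(cs)
}

# canonical edge data frame of a raw or weighted network (sorted endpoints,
# then sorted rows) -- used for determinism checks and exports
edge_table <- function(g) {
  df <- igraph::as_data_frame(g, what = "edges")
  lo <- pmin(df$from, df$to)
  hi <- pmax(df$from, df$to)
  df$from <- lo
  df$to <- hi
  df[order(df$from, df$to), , drop = FALSE]
}
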