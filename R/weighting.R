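#' Common-neighbour reliability score of an edge
#'
#' Topological reliability of an interaction (v, u):
#' \deqn{CN(v,u) = \sqrt{|N(v) \cap N(u)|^2 / (|N(v)| \cdot |N(u)|)}}
#' where N(.) is the full adjacency set (so |N(v)| is the degree of v, and
#' includes u itself when (v,u) is an edge); common neighbours never include
#' the endpoints. The score is 0 when either endpoint has no neighbours or
#' the endpoints share none, and lies in [0, 1].
#'
#' @param net an undirected igraph (a raw network from [read_edge_list]).
#' @param v,u protein ids (must be distinct vertices of `net`).
#' @return numeric score in [0, 1].
#' @export
common_neighbor_weight <- function(net, v, u) {
  if (identical(v, u)) stop("v and u must be distinct", call. = FALSE)
  nv <- igraph::neighbors(net, v)$name
  nu <- igraph::neighbors(net, u)$name
  if (length(nv) == 0L || length(nu) == 0L) return(0)
  cn <- length(intersect(nv, nu))
  sqrt(cn^2 / (length(nv) * length(nu)))
}

#' Average annotation count over a network
#'
#' The mean number of GO terms per protein, taken over the network proteins
#' that carry at least one annotation. Proteins present in the annotation
#' table but absent from the network do not contribute; network proteins
#' without annotations are excluded from both numerator and denominator.
#' This average is the penalisation floor in [go_similarity].
#'
#' @param annot a `go_annotations` object from [read_annotations].
#' @param net the raw network (igraph).
#' @return positive numeric, or `NA_real_` when no network protein is
#'   annotated (the degenerate-annotation condition; [build_weighted_network]
#'   then falls back to common-neighbour-only weights).
#' @export
average_annotation_count <- function(annot, net) {
  counts <- lengths(annot[names(annot) %in% igraph::V(net)$name])
  counts <- counts[counts >= 1L]
  if (length(counts) == 0L) return(NA_real_)
  mean(counts)
}

#' GO-annotation similarity of two proteins
#'
#' Annotation-overlap similarity with a penalty for sparsely annotated
#' proteins:
#' \deqn{GO(v,u) = |GO(v) \cap GO(u)| / \max(\min(|GO(v)|, |GO(u)|), avg)}
#' when the intersection is non-empty, and 0 otherwise (including when
#' either protein is unannotated). `avg` is [average_annotation_count]:
#' proteins with fewer terms than the network average have their
#' denominator raised to the average, damping similarity scores that rest
#' on very few annotations.
#'
#' @param annot a `go_annotations` object.
#' @param avg the network-wide average annotation count (> 0).
#' @param v,u protein ids.
#' @return numeric score in [0, 1].
#' @export
go_similarity <- function(annot, avg, v, u) {
  stopifnot(is.numeric(avg), avg > 0)
  gv <- annot[[v]]
  gu <- annot[[u]]
  if (is.null(gv) || is.null(gu)) return(0)
  k <- length(intersect(gv, gu))
  if (k == 0L) return(0)
  k / max(min(length(gv), length(gu)), avg)
}

#' Build the weighted interaction network
#'
#' Assigns each interaction the arithmetic mean of its common-neighbour
#' score ([common_neighbor_weight]) and its annotation similarity
#' ([go_similarity]); edges whose combined weight is 0 are considered noise
#' and deleted, and proteins left without any edge are removed. The
#' average annotation count is computed once, on the full loaded network,
#' before any pruning. Network proteins absent from the annotation table
#' are treated as unannotated (empty term set) and counted in the log.
#'
#' @param net a raw network (igraph) from [read_edge_list].
#' @param annot a `go_annotations` object; may be `NULL` or empty, in which
#'   case weights reduce to the common-neighbour score alone.
#' @param verbose emit pruning counts.
#' @return an undirected igraph with an edge attribute `weight` in (0, 1],
#'   vertices sorted lexicographically; graph attribute `average_go` stores
#'   the annotation average used (NA when unannotated).
#' @export
build_weighted_network <- function(net, annot = NULL,
                                   verbose = getOption("ppicomplex.verbose",
                                                       TRUE)) {
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), function(vs) vs$name)
  names(adj) <- nodes
  avg <- if (is.null(annot) || length(annot) == 0L) NA_real_ else
    average_annotation_count(annot, net)
  if (is.na(avg)) {
    n_unannot <- length(nodes)
    terms <- NULL
  } else {
    terms <- annot[names(annot) %in% nodes]
    n_unannot <- sum(!(nodes %in% names(terms)))
  }
  et <- edge_table(net)
  n_e <- nrow(et)
  w <- numeric(n_e)
  deg <- lengths(adj)
  for (i in seq_len(n_e)) {
    a <- et$from[i]; b <- et$to[i]
    cnn <- length(intersect(adj[[a]], adj[[b]]))
    cn <- if (deg[[a]] >= 1L && deg[[b]] >= 1L && cnn > 0L)
      sqrt(cnn^2 / (deg[[a]] * deg[[b]])) else 0
    go <- 0
    if (!is.na(avg)) {
      ga <- terms[[a]]; gb <- terms[[b]]
      if (!is.null(ga) && !is.null(gb)) {
        k <- length(intersect(ga, gb))
        if (k > 0L) go <- k / max(min(length(ga), length(gb)), avg)
      }
    }
    w[i] <- (cn + go) / 2
  }
  keep <- w > 0
  et <- et[keep, , drop = FALSE]
  kept_nodes <- sort(unique(c(et$from, et$to)))
  g <- igraph::graph_from_data_frame(
    cbind(et, weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = kept_nodes, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "average_go", avg)
  ppx_message("build_weighted_network: kept ", igraph::ecount(g), "/", n_e,
              " edges, ", igraph::vcount(g), "/", length(nodes),
              " proteins (", n_unannot, " unannotated; Average(GO) = ",
              signif(avg, 4), ")", verbose = verbose)
  g
}

#' Export a weighted edge list
#'
#' Writes `idA<TAB>idB<TAB>weight` rows (weights with 6 decimals), endpoints
#' and rows sorted for reproducibility.
#'
#' @param wnet a weighted network from [build_weighted_network].
#' @param path output file path or connection.
#' @export
write_weighted_edges <- function(wnet, path) {
  et <- edge_table(wnet)
  writeLines(sprintf("%s\t%s\t%.6f", et$from, et$to, et$weight), path)
  invisible(wnet)
}
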