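# weighted adjacency list in canonical (lexicographic) order; the fixed
# iteration order makes every floating-point sum independent of input file
# line order, which the determinism guarantees rely on
wadj_list <- function(wnet) {
  nodes <- igraph::V(wnet)$name
  if (length(nodes) == 0L) return(stats::setNames(list(), character(0)))
  et <- edge_table(wnet)
  adj <- stats::setNames(
    rep(list(stats::setNames(numeric(0), character(0))), length(nodes)),
    nodes)
  nb <- split(c(stats::setNames(et$weight, et$to),
                stats::setNames(et$weight, et$from)),
              c(et$from, et$to))
  for (v in names(nb)) adj[[v]] <- nb[[v]][order(names(nb[[v]]))]
  adj
}

#' Weighted degree of a protein
#'
#' Sum of the weights of all edges incident to `v` in the weighted network.
#'
#' @param wnet a weighted network from [build_weighted_network].
#' @param v a protein id (vector allowed).
#' @return numeric vector of weighted degrees.
#' @export
weighted_degree <- function(wnet, v) {
  if (!all(v %in% igraph::V(wnet)$name)) {
    stop("unknown node: ", paste(setdiff(v, igraph::V(wnet)$name),
                                 collapse = ", "), call. = FALSE)
  }
  unname(igraph::strength(wnet, vids = v, weights = igraph::E(wnet)$weight))
}

#' Neighbourhood-graph clustering coefficient
#'
#' For node v let the neighbourhood graph G_v be induced by V_v = {v} union
#' its neighbours. The coefficient is the sum of the weights of all edges of
#' the network with both endpoints in V_v (each edge once), divided by the
#' number of possible pairs |V_v|(|V_v|-1)/2. Zero when |V_v| < 2. With
#' weights in (0, 1] the value lies in [0, 1]; it measures how densely and
#' reliably a node's neighbourhood is interconnected.
#'
#' @param wnet a weighted network.
#' @param v a protein id.
#' @return numeric in [0, 1].
#' @export
ngcc <- function(wnet, v) {
  if (!(v %in% igraph::V(wnet)$name)) {
    stop("unknown node: ", v, call. = FALSE)
  }
  vv <- c(v, igraph::neighbors(wnet, v)$name)
  k <- length(vv)
  if (k < 2L) return(0)
  sub <- igraph::induced_subgraph(wnet, vv)
  sum(igraph::E(sub)$weight) / (k * (k - 1) / 2)
}

#' Seed priority score of a protein
#'
#' The product of the weighted degree and the neighbourhood-graph clustering
#' coefficient. High-scoring nodes sit at the reliable, densely
#' interconnected centre of a putative complex and are grown first.
#'
#' @param wnet a weighted network.
#' @param v a protein id.
#' @return non-negative numeric.
#' @export
seed_score <- function(wnet, v) {
  weighted_degree(wnet, v) * ngcc(wnet, v)
}

#' Build the seed queue
#'
#' Scores every node of the weighted network once (scores are never updated
#' during detection) and orders the queue by non-increasing score, ties
#' broken lexicographically by protein id.
#'
#' @param wnet a weighted network.
#' @return a data.frame with columns `node` and `score`, one row per network
#'   node, in queue order.
#' @export
build_seed_queue <- function(wnet) {
  nodes <- igraph::V(wnet)$name
  if (length(nodes) == 0L) {
    return(data.frame(node = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  adj <- wadj_list(wnet)
  score <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    dw <- sum(nb)
    vv <- c(v, names(nb))
    k <- length(vv)
    if (k < 2L) return(0)
    # sum of weights among V_v: each member's weights restricted to V_v,
    # halved because each internal edge is seen from both endpoints
    s <- sum(vapply(vv, function(x) {
      ax <- adj[[x]]
      sum(ax[names(ax) %in% vv])
    }, 0)) / 2
    dw * (s / (k * (k - 1) / 2))
  }, 0)
  ord <- order(-score, nodes)
  data.frame(node = nodes[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Export seed scores
#'
#' Writes `node<TAB>score` in queue order.
#'
#' @param queue a seed queue from [build_seed_queue].
#' @param path output file path or connection.
#' @export
write_seed_queue <- function(queue, path) {
  writeLines(sprintf("%s\t%.10g", queue$node, queue$score), path)
  invisible(queue)
}
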