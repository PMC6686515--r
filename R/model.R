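#' Create a cluster over a weighted network
#'
#' A `ppi_cluster` is a candidate complex: a member set plus cached weighted
#' in-degree (sum of weights of edges with both endpoints inside) and
#' weighted out-degree (edges with exactly one endpoint inside). The caches
#' are maintained incrementally by [cluster_update] and always equal a full
#' recomputation from the network.
#'
#' @param wnet a weighted network (igraph) or a weighted adjacency list as
#'   produced internally; members must be nodes of it.
#' @param members character vector of member ids (may be empty).
#' @return an object of class `ppi_cluster` with fields `members`
#'   (sorted), `d_in`, `d_out`.
#' @export
new_cluster <- function(wnet, members = character(0)) {
  adj <- if (igraph::is_igraph(wnet)) wadj_list(wnet) else wnet
  members <- sort(unique(as.character(members)))
  if (!all(members %in% names(adj))) {
    stop("members must belong to the network", call. = FALSE)
  }
  d_in <- 0
  d_out <- 0
  for (v in members) {
    nb <- adj[[v]]
    inside <- names(nb) %in% members
    d_in <- d_in + sum(nb[inside])
    d_out <- d_out + sum(nb[!inside])
  }
  structure(list(members = members, d_in = d_in / 2, d_out = d_out),
            class = "ppi_cluster")
}

#' @export
print.ppi_cluster <- function(x, ...) {
  cat("<ppi_cluster> ", length(x$members), " members; d_in = ",
      signif(x$d_in, 6), ", d_out = ", signif(x$d_out, 6),
      ", fitness = ", signif(cluster_fitness(x), 6), "\n", sep = "")
  invisible(x)
}

#' Density of a cluster
#'
#' Summed internal edge weights divided by the number of possible internal
#' pairs |SG|(|SG|-1)/2; 0 for clusters of fewer than two members (the
#' ratio is 0/0 there, and 0 makes a seed's first accepted expansion
#' well defined).
#'
#' @param c a `ppi_cluster`.
#' @return numeric in [0, 1] for weights in (0, 1].
#' @export
cluster_density <- function(c) {
  n <- length(c$members)
  if (n < 2L) return(0)
  c$d_in / (n * (n - 1) / 2)
}

#' Modularity of a cluster
#'
#' Weighted in-degree over total incident weight, d_in / (d_in + d_out);
#' 0 when the cluster has no incident weight at all. A value of 1 means the
#' cluster has no connection to the rest of the network.
#'
#' @param c a `ppi_cluster`.
#' @return numeric in [0, 1].
#' @export
cluster_modularity <- function(c) {
  tot <- c$d_in + c$d_out
  if (tot == 0) return(0)
  c$d_in / tot
}

#' Composite fitness of a cluster
#'
#' \deqn{F = (D + M + \sqrt{D M}) / 3}
#' where D is [cluster_density] and M is [cluster_modularity]. The geometric
#' mean term rewards clusters that are simultaneously dense and modular
#' while keeping the range in [0, 1]; an isolated unit-weight clique scores
#' exactly 1. Growth accepts only moves that strictly increase F.
#'
#' @param c a `ppi_cluster`.
#' @return numeric in [0, 1].
#' @export
cluster_fitness <- function(c) {
  d <- cluster_density(c)
  m <- cluster_modularity(c)
  (d + m + sqrt(d * m)) / 3
}

#' Average internal interaction weight per member
#'
#' 2 * d_in / |SG|: every member's share of the cluster's internal weighted
#' interactions. This is the priority used to rank boundary nodes during
#' growth (evaluated on the cluster as it would be after the move).
#'
#' @param c a non-empty `ppi_cluster`.
#' @return non-negative numeric.
#' @export
cluster_weight_avg <- function(c) {
  n <- length(c$members)
  if (n == 0L) stop("empty cluster", call. = FALSE)
  2 * c$d_in / n
}

#' Incrementally add or remove a node
#'
#' Returns a new cluster whose cached in/out weights are updated from the
#' moved node's incident edges alone, avoiding a full recomputation. Adding
#' node x moves its cluster-touching weight from out to in and adds its
#' remaining incident weight to out; removal is the exact inverse.
#'
#' @param c a `ppi_cluster`.
#' @param node the node to move.
#' @param direction `"add"` (node must be outside) or `"remove"` (inside).
#' @param wnet the host weighted network (igraph) or its adjacency list.
#' @return the updated `ppi_cluster`.
#' @export
cluster_update <- function(c, node, direction = c("add", "remove"), wnet) {
  direction <- match.arg(direction)
  adj <- if (igraph::is_igraph(wnet)) wadj_list(wnet) else wnet
  if (!(node %in% names(adj))) stop("unknown node: ", node, call. = FALSE)
  nb <- adj[[node]]
  inside <- names(nb) %in% c$members
  w_to_cluster <- sum(nb[inside])
  w_elsewhere <- sum(nb[!inside])
  if (direction == "add") {
    if (node %in% c$members) stop("node already in cluster", call. = FALSE)
    members <- sort(c(c$members, node))
    d_in <- c$d_in + w_to_cluster
    d_out <- c$d_out - w_to_cluster + w_elsewhere
  } else {
    if (!(node %in% c$members)) stop("node not in cluster", call. = FALSE)
    # w_to_cluster here counts edges to the *other* members
    members <- setdiff(c$members, node)
    d_in <- c$d_in - w_to_cluster
    d_out <- c$d_out + w_to_cluster - w_elsewhere
  }
  structure(list(members = members, d_in = d_in, d_out = d_out),
            class = "ppi_cluster")
}
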