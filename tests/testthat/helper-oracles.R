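# Independent naive implementations used as oracles. They work on a plain
# edge data.frame (from, to, weight) plus a node vector and never touch the
# package's adjacency caching, so agreement is a genuine cross-check.

rand_raw_graph <- function(n, p = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n))
  pr <- t(combn(nodes, 2))
  keep <- runif(nrow(pr)) < p
  ed <- data.frame(from = pr[keep, 1], to = pr[keep, 2],
                   stringsAsFactors = FALSE)
  list(nodes = sort(unique(c(ed$from, ed$to))), edges = ed)
}

rand_annotations <- function(nodes, n_terms = 8, p_annot = 0.8,
                             max_terms = 5) {
  terms <- sprintf("T%02d", seq_len(n_terms))
  ann <- list()
  for (v in nodes) {
    if (runif(1) < p_annot) {
      k <- sample.int(max_terms, 1)
      ann[[v]] <- sort(unique(sample(terms, k, replace = TRUE)))
    }
  }
  structure(ann[order(names(ann))], class = "go_annotations")
}

rand_weights <- function(g) {
  g$edges$weight <- round(runif(nrow(g$edges), 0.05, 1), 3)
  g
}

as_raw_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges, directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
}

as_weighted_igraph <- as_raw_igraph

naive_neighbors <- function(g, v) {
  unique(c(g$edges$to[g$edges$from == v], g$edges$from[g$edges$to == v]))
}

naive_cn <- function(g, v, u) {
  nv <- naive_neighbors(g, v)
  nu <- naive_neighbors(g, u)
  if (length(nv) == 0 || length(nu) == 0) return(0)
  sqrt(length(intersect(nv, nu))^2 / (length(nv) * length(nu)))
}

naive_avg_go <- function(ann, nodes) {
  cnt <- lengths(ann[names(ann) %in% nodes])
  cnt <- cnt[cnt >= 1]
  if (!length(cnt)) NA_real_ else sum(cnt) / length(cnt)
}

naive_go_sim <- function(ann, avg, v, u) {
  gv <- ann[[v]]; gu <- ann[[u]]
  if (is.null(gv) || is.null(gu)) return(0)
  k <- length(intersect(gv, gu))
  if (k == 0) return(0)
  k / max(min(length(gv), length(gu)), avg)
}

naive_weighted_edges <- function(g, ann) {
  avg <- naive_avg_go(ann, g$nodes)
  w <- numeric(nrow(g$edges))
  for (i in seq_len(nrow(g$edges))) {
    v <- g$edges$from[i]; u <- g$edges$to[i]
    go <- if (is.na(avg)) 0 else naive_go_sim(ann, avg, v, u)
    w[i] <- (naive_cn(g, v, u) + go) / 2
  }
  out <- g$edges
  out$weight <- w
  out[w > 0, , drop = FALSE]
}

naive_dw <- function(g, v) {
  sum(g$edges$weight[g$edges$from == v | g$edges$to == v])
}

naive_ngcc <- function(g, v) {
  vv <- c(v, naive_neighbors(g, v))
  k <- length(vv)
  if (k < 2) return(0)
  inside <- g$edges$from %in% vv & g$edges$to %in% vv
  sum(g$edges$weight[inside]) / (k * (k - 1) / 2)
}

naive_cluster <- function(g, members) {
  fin <- g$edges$from %in% members
  tin <- g$edges$to %in% members
  list(d_in = sum(g$edges$weight[fin & tin]),
       d_out = sum(g$edges$weight[xor(fin, tin)]))
}

naive_density <- function(g, members) {
  n <- length(members)
  if (n < 2) return(0)
  naive_cluster(g, members)$d_in / (n * (n - 1) / 2)
}

naive_modularity <- function(g, members) {
  cl <- naive_cluster(g, members)
  tot <- cl$d_in + cl$d_out
  if (tot == 0) 0 else cl$d_in / tot
}

naive_fitness <- function(g, members) {
  d <- naive_density(g, members)
  m <- naive_modularity(g, members)
  (d + m + sqrt(d * m)) / 3
}

naive_weight_avg <- function(g, members) {
  2 * naive_cluster(g, members)$d_in / length(members)
}

# exhaustive hypergeometric upper tail: group is {1..F} by symmetry
hyper_tail_enum <- function(k, N, F_, C) {
  if (C == 0) return(if (k <= 0) 1 else 0)
  subs <- combn(N, C)
  ov <- if (is.matrix(subs)) colSums(subs <= F_) else sum(subs <= F_)
  mean(ov >= k)
}

# no single permitted move passing its tests may improve fitness
assert_local_optimum <- function(g, members, cfg = detection_config()) {
  f0 <- naive_fitness(g, members)
  size <- length(members)
  nb_all <- unique(unlist(lapply(members, naive_neighbors, g = g)))
  for (p in setdiff(nb_all, members)) {
    links <- length(intersect(naive_neighbors(g, p), members))
    if (naive_fitness(g, c(members, p)) > f0 && links > f0 * size) {
      return(sprintf("addable node %s improves fitness", p))
    }
  }
  inner <- members[vapply(members, function(v)
    length(setdiff(naive_neighbors(g, v), members)) > 0, TRUE)]
  for (p in inner) {
    rest <- setdiff(members, p)
    links <- length(intersect(naive_neighbors(g, p), rest))
    conn <- if (cfg$removal_connectivity == "literal")
      links > f0 * size else links < f0 * size
    if (naive_fitness(g, rest) > f0 && conn) {
      return(sprintf("removable node %s improves fitness", p))
    }
  }
  TRUE
}

# edge data.frame view of an igraph for feeding the naive oracles
graph_as_df <- function(wnet) {
  df <- igraph::as_data_frame(wnet, what = "edges")
  list(nodes = igraph::V(wnet)$name, edges = df)
}
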