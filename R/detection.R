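#' Detection configuration
#'
#' @param min_size minimum complex size kept (default 3; smaller candidate
#'   clusters are discarded as spurious).
#' @param redundancy_threshold overlap-score threshold in (0, 1] above which
#'   a lower-fitness complex is discarded as redundant (default 0.8).
#' @param removal_connectivity connectivity test used when removing an inner
#'   node during the correct phase: `"literal"` requires the node's actual
#'   in-cluster edge count to exceed the expectation edge F(SG)*|SG| (the
#'   same direction as the addition test), `"inverted"` requires it to be
#'   strictly below. The fitness-increase condition dominates either way;
#'   `"literal"` is the default.
#' @param max_passes safety cap on extend/correct passes per seed (default
#'   100; typical growth converges in 2-3 passes, hitting the cap logs a
#'   warning).
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(min_size = 3L,
                             redundancy_threshold = 0.8,
                             removal_connectivity = c("literal", "inverted"),
                             max_passes = 100L) {
  removal_connectivity <- match.arg(removal_connectivity)
  stopifnot(min_size >= 1L,
            redundancy_threshold > 0, redundancy_threshold <= 1,
            max_passes >= 1L)
  structure(list(min_size = as.integer(min_size),
                 redundancy_threshold = redundancy_threshold,
                 removal_connectivity = removal_connectivity,
                 max_passes = as.integer(max_passes)),
            class = "detection_config")
}

#' Boundary neighbours of a cluster
#'
#' All nodes outside the cluster adjacent to at least one member.
#'
#' @param wnet a weighted network (igraph) or its adjacency list.
#' @param c a `ppi_cluster`.
#' @return character vector of node ids (sorted).
#' @export
neighbors_of_cluster <- function(wnet, c) {
  adj <- if (igraph::is_igraph(wnet)) wadj_list(wnet) else wnet
  nb <- unique(unlist(lapply(c$members, function(v) names(adj[[v]])),
                      use.names = FALSE))
  sort(setdiff(nb, c$members))
}

#' Inner nodes of a cluster
#'
#' Members having at least one neighbour outside the cluster; these are the
#' removal candidates of the correct phase.
#'
#' @param wnet a weighted network (igraph) or its adjacency list.
#' @param c a `ppi_cluster`.
#' @return character vector of node ids (sorted).
#' @export
inner_nodes <- function(wnet, c) {
  adj <- if (igraph::is_igraph(wnet)) wadj_list(wnet) else wnet
  sort(Filter(function(v) any(!(names(adj[[v]]) %in% c$members)),
              c$members))
}

# one extend or correct phase; returns list(cluster, f_trace, changed)
grow_phase <- function(adj, cl, cfg, phase = c("extend", "correct")) {
  phase <- match.arg(phase)
  f_trace <- numeric(0)
  changed <- FALSE
  repeat {
    cand <- if (phase == "extend") neighbors_of_cluster(adj, cl)
            else inner_nodes(adj, cl)
    if (length(cand) == 0L) break
    size <- length(cl$members)
    f_old <- cluster_fitness(cl)
    # priority: weight_avg of the cluster after the candidate move;
    # ties broken lexicographically (cand is sorted, which.max takes first)
    after <- lapply(cand, function(p)
      cluster_update(cl, p, if (phase == "extend") "add" else "remove", adj))
    prio <- vapply(after, function(x)
      if (length(x$members) == 0L) -Inf else cluster_weight_avg(x), 0)
    best <- which.max(prio)
    p <- cand[[best]]
    cl_new <- after[[best]]
    f_new <- cluster_fitness(cl_new)
    nb <- adj[[p]]
    if (phase == "extend") {
      n_links <- sum(names(nb) %in% cl$members)
      ok <- (f_new > f_old) && (n_links > f_old * size)
    } else {
      n_links <- sum(names(nb) %in% cl_new$members)
      conn_ok <- if (cfg$removal_connectivity == "literal")
        n_links > f_old * size else n_links < f_old * size
      ok <- (f_new > f_old) && conn_ok
    }
    if (!ok) break
    cl <- cl_new
    f_trace <- c(f_trace, f_new)
    changed <- TRUE
  }
  list(cluster = cl, f_trace = f_trace, changed = changed)
}

#' Grow a cluster from a seed node
#'
#' Starting from the single-node cluster {seed} (fitness 0), repeats an
#' extend phase followed by a correct phase until a full pass changes
#' nothing. The extend phase repeatedly takes the boundary neighbour
#' maximising [cluster_weight_avg] of the enlarged cluster and accepts it
#' iff (i) fitness strictly increases and (ii) the node's actual edge count
#' into the cluster exceeds the expectation edge F(SG)*|SG| (both computed
#' on the cluster before the move); the phase ends the first time the
#' top-priority candidate fails. The correct phase symmetrically removes
#' inner nodes (members with an outside neighbour) maximising the
#' weight-average of the shrunken cluster, accepting iff fitness strictly
#' increases and the connectivity test of the configuration holds. Every
#' accepted move strictly increases fitness, so growth terminates.
#'
#' @param wnet a weighted network (igraph) or its adjacency list.
#' @param seed a node id of `wnet`.
#' @param cfg a [detection_config].
#' @return a list: `cluster` (the locally optimal `ppi_cluster`), `fitness`,
#'   `f_trace` (fitness after each accepted move, strictly increasing),
#'   `passes` (extend/correct passes run), `hit_cap` (logical).
#' @export
grow_cluster <- function(wnet, seed, cfg = detection_config()) {
  adj <- if (igraph::is_igraph(wnet)) wadj_list(wnet) else wnet
  if (!(seed %in% names(adj))) stop("unknown seed: ", seed, call. = FALSE)
  cl <- structure(list(members = seed, d_in = 0, d_out = sum(adj[[seed]])),
                  class = "ppi_cluster")
  f_trace <- numeric(0)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    ext <- grow_phase(adj, cl, cfg, "extend")
    cor <- grow_phase(adj, ext$cluster, cfg, "correct")
    cl <- cor$cluster
    f_trace <- c(f_trace, ext$f_trace, cor$f_trace)
    if (!(ext$changed || cor$changed)) break
    if (passes >= cfg$max_passes) {
      warning("grow_cluster: pass cap (", cfg$max_passes,
              ") reached at seed ", seed, call. = FALSE)
      break
    }
  }
  list(cluster = cl, fitness = cluster_fitness(cl), f_trace = f_trace,
       passes = passes, hit_cap = passes >= cfg$max_passes)
}

#' Remove redundant complexes
#'
#' Processes complexes in non-increasing fitness order (ties: detection
#' order) and keeps a complex iff its overlap score ([overlap_score]) with
#' every already-kept complex is below `threshold`. Output preserves
#' detection order among the kept complexes.
#'
#' @param cs a [complex_set] whose `scores` hold per-complex fitness (a
#'   `NULL` score is treated as all-equal).
#' @param threshold overlap-score threshold in (0, 1].
#' @return the filtered [complex_set].
#' @export
remove_redundant <- function(cs, threshold = 0.8) {
  stopifnot(inherits(cs, "complex_set"), threshold > 0, threshold <= 1)
  n <- length(cs$complexes)
  if (n == 0L) return(cs)
  fit <- if (is.null(cs$scores)) rep(0, n) else cs$scores
  ord <- order(-fit, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    os <- vapply(kept, function(j)
      overlap_score(cs$complexes[[i]], cs$complexes[[j]]), 0)
    if (all(os < threshold)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  complex_set(cs$complexes[kept],
              if (is.null(cs$scores)) NULL else cs$scores[kept])
}

#' Detect protein complexes in a weighted network
#'
#' Runs the full seed-and-extend detection: builds the seed queue
#' ([build_seed_queue]), grows a cluster from every queue node not already
#' contained in a previously kept complex ([grow_cluster]), discards
#' clusters smaller than `min_size` and exact duplicates, and finally
#' filters redundant complexes by pairwise overlap score
#' ([remove_redundant]). Nodes are never removed from the network, so
#' complexes may overlap; only members of kept clusters are marked visited,
#' so the seeds of discarded small clusters remain eligible later.
#'
#' @param wnet a weighted network from [build_weighted_network].
#' @param cfg a [detection_config].
#' @param verbose emit a run summary.
#' @return a list of class `detection_result`: `complexes` (a [complex_set]
#'   with per-complex fitness in `scores`, in detection order), `seed_of`
#'   (seed node of each kept complex), `diagnostics` (data.frame of per-seed
#'   pass counts and outcomes).
#' @export
detect_complexes <- function(wnet, cfg = detection_config(),
                             verbose = getOption("ppicomplex.verbose", TRUE)) {
  queue <- build_seed_queue(wnet)
  adj <- wadj_list(wnet)
  visited <- character(0)
  members <- list()
  fitness <- numeric(0)
  seeds <- character(0)
  diag_seed <- character(0)
  diag_passes <- integer(0)
  diag_kept <- logical(0)
  n_small <- 0L
  seen_keys <- character(0)
  for (s in queue$node) {
    if (s %in% visited) next
    g <- grow_cluster(adj, s, cfg)
    diag_seed <- c(diag_seed, s)
    diag_passes <- c(diag_passes, g$passes)
    keep <- length(g$cluster$members) >= cfg$min_size
    if (keep) {
      key <- paste(g$cluster$members, collapse = "\r")
      if (key %in% seen_keys) keep <- FALSE else seen_keys <- c(seen_keys, key)
    } else {
      n_small <- n_small + 1L
    }
    diag_kept <- c(diag_kept, keep)
    if (keep) {
      members <- c(members, list(g$cluster$members))
      fitness <- c(fitness, g$fitness)
      seeds <- c(seeds, s)
      visited <- union(visited, g$cluster$members)
    }
  }
  candidates <- complex_set(if (length(members)) members else list(), fitness)
  final <- remove_redundant(candidates, cfg$redundancy_threshold)
  keep_idx <- match(vapply(final$complexes, paste, "", collapse = "\r"),
                    vapply(candidates$complexes, paste, "", collapse = "\r"))
  ppx_message("detect_complexes: ", length(diag_seed), " seeds grown, ",
              length(candidates$complexes), " candidates (", n_small,
              " below size ", cfg$min_size, "), ",
              length(final$complexes), " complexes after redundancy filter",
              verbose = verbose)
  structure(list(
    complexes = final,
    seed_of = seeds[keep_idx],
    diagnostics = data.frame(seed = diag_seed, passes = diag_passes,
                             kept = diag_kept, stringsAsFactors = FALSE)
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("<detection_result> ", length(x$complexes$complexes),
      " complexes; mean size ",
      if (length(x$complexes$complexes))
        signif(mean(lengths(x$complexes$complexes)), 4) else NA,
      "; mean passes ", signif(mean(x$diagnostics$passes), 4), "\n", sep = "")
  invisible(x)
}
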