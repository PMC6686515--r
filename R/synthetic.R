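#' Specification of a planted-complex benchmark network
#'
#' Describes a synthetic interaction network containing dense, modular,
#' functionally coherent planted complexes over a background of noise
#' interactions, used to test detection and evaluation end to end. The
#' defaults are the conditions of the package's recovery benchmark:
#' ten complexes of 4-8 proteins, within-complex edge probability 0.9,
#' background edge probability 0.02, and coherent per-complex annotations.
#'
#' @param n_complexes number of planted complexes (default 10).
#' @param size_range integer (min, max) complex sizes, min >= 3 (default
#'   c(4, 8)).
#' @param overlap_fraction fraction of complexes (beyond the first) that
#'   share one protein with a previously placed complex (default 0.2).
#' @param p_within edge probability inside a complex (default 0.9; must
#'   exceed `p_between`).
#' @param p_between background edge probability between any pair not inside
#'   a common complex (default 0.02).
#' @param n_background_nodes proteins belonging to no complex (default 40).
#' @param terms_per_complex private GO terms assigned to each complex
#'   (default 3).
#' @param annotation_coherence probability that a member carries each of
#'   its complex's terms (default 0.9).
#' @param noise_terms number of terms each background protein draws from a
#'   shared pool of noise terms (default 2; the pool holds 20 terms).
#' @param rng_seed integer seed making generation reproducible (default 1).
#' @return a list of class `planted_network_spec`.
#' @export
planted_network_spec <- function(n_complexes = 10L,
                                 size_range = c(4L, 8L),
                                 overlap_fraction = 0.2,
                                 p_within = 0.9,
                                 p_between = 0.02,
                                 n_background_nodes = 40L,
                                 terms_per_complex = 3L,
                                 annotation_coherence = 0.9,
                                 noise_terms = 2L,
                                 rng_seed = 1L) {
  stopifnot(n_complexes >= 1L, length(size_range) == 2L,
            size_range[1] >= 3L, size_range[2] >= size_range[1],
            overlap_fraction >= 0, overlap_fraction < 1,
            p_within > p_between, p_within <= 1, p_between >= 0,
            n_background_nodes >= 0L, terms_per_complex >= 0L,
            annotation_coherence >= 0, annotation_coherence <= 1,
            noise_terms >= 0L)
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 overlap_fraction = overlap_fraction,
                 p_within = p_within, p_between = p_between,
                 n_background_nodes = as.integer(n_background_nodes),
                 terms_per_complex = as.integer(terms_per_complex),
                 annotation_coherence = annotation_coherence,
                 noise_terms = as.integer(noise_terms),
                 rng_seed = as.integer(rng_seed)),
            class = "planted_network_spec")
}

# all unordered pairs of a node vector as a 2-column matrix
node_pairs <- function(nodes) {
  if (length(nodes) < 2L) {
    return(matrix(character(0), ncol = 2L))
  }
  t(utils::combn(sort(nodes), 2L))
}

#' Generate a planted-complex benchmark network
#'
#' Samples a network according to a [planted_network_spec]: complex members
#' are connected with probability `p_within` (resampled until each planted
#' complex is internally connected, since a disconnected complex could
#' never be recovered as one cluster), every other pair with probability
#' `p_between`. Each complex receives `terms_per_complex` private GO terms
#' carried by each member with probability `annotation_coherence`;
#' background proteins draw `noise_terms` terms from a shared noise pool,
#' giving the annotation-similarity weighting realistic signal and noise.
#'
#' @param spec a [planted_network_spec].
#' @return a list: `network` (raw igraph as from [read_edge_list]),
#'   `annotations` (a `go_annotations` object), `truth` (a [complex_set]
#'   of the planted complexes), `spec`.
#' @export
generate_planted_network <- function(spec = planted_network_spec()) {
  stopifnot(inherits(spec, "planted_network_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(spec$rng_seed)

  sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                  spec$n_complexes, replace = TRUE)
  n_members <- sum(sizes)
  all_ids <- sprintf("P%03d", seq_len(n_members + spec$n_background_nodes))
  complexes <- list()
  cursor <- 0L
  n_overlap <- round(spec$overlap_fraction * (spec$n_complexes - 1L))
  for (i in seq_len(spec$n_complexes)) {
    fresh <- sizes[i]
    members <- character(0)
    if (i > 1L && length(complexes) && i <= 1L + n_overlap) {
      # share one protein with a previously placed complex
      donor <- complexes[[sample.int(length(complexes), 1L)]]
      members <- sample(donor, 1L)
      fresh <- fresh - 1L
    }
    members <- c(members, all_ids[cursor + seq_len(fresh)])
    cursor <- cursor + fresh
    complexes[[i]] <- sort(members)
  }
  background <- all_ids[n_members + seq_len(spec$n_background_nodes)]
  used <- sort(unique(c(unlist(complexes), background)))

  # within-complex edges, resampled until connected
  edge_keys <- character(0)
  for (m in complexes) {
    pairs <- node_pairs(m)
    repeat {
      keep <- stats::runif(nrow(pairs)) < spec$p_within
      g <- igraph::graph_from_data_frame(
        data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L]),
        directed = FALSE,
        vertices = data.frame(name = m))
      if (igraph::is_connected(g)) break
    }
    edge_keys <- c(edge_keys, paste(pairs[keep, 1L], pairs[keep, 2L],
                                    sep = "\r"))
  }
  # background edges over all remaining pairs
  in_complex <- lapply(complexes, identity)
  pair_all <- node_pairs(used)
  key_all <- paste(pair_all[, 1L], pair_all[, 2L], sep = "\r")
  within_any <- rep(FALSE, nrow(pair_all))
  for (m in in_complex) {
    within_any <- within_any |
      (pair_all[, 1L] %in% m & pair_all[, 2L] %in% m)
  }
  bg_keep <- !within_any & stats::runif(nrow(pair_all)) < spec$p_between
  edge_keys <- unique(c(edge_keys, key_all[bg_keep]))
  parts <- strsplit(edge_keys, "\r", fixed = TRUE)
  ef <- vapply(parts, `[[`, "", 1L)
  et <- vapply(parts, `[[`, "", 2L)
  ord <- order(ef, et)
  network <- igraph::graph_from_data_frame(
    data.frame(from = ef[ord], to = et[ord], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(ef, et))),
                          stringsAsFactors = FALSE))

  # annotations: private coherent terms per complex + background noise terms
  ann <- list()
  add_term <- function(p, t) ann[[p]] <<- c(ann[[p]], t)
  for (i in seq_along(complexes)) {
    terms <- sprintf("GO:C%02d_%02d", i, seq_len(spec$terms_per_complex))
    for (p in complexes[[i]]) {
      carry <- stats::runif(spec$terms_per_complex) < spec$annotation_coherence
      for (t in terms[carry]) add_term(p, t)
    }
  }
  noise_pool <- sprintf("GO:N%02d", seq_len(20L))
  if (spec$noise_terms > 0L) {
    for (p in background) {
      for (t in sample(noise_pool, min(spec$noise_terms,
                                       length(noise_pool)))) {
        add_term(p, t)
      }
    }
  }
  ann <- lapply(ann, function(t) sort(unique(t)))
  ann <- ann[order(names(ann))]
  list(network = network,
       annotations = structure(ann, class = "go_annotations"),
       truth = complex_set(complexes),
       spec = spec)
}

#' Hand-built toy networks with known detection outcomes
#'
#' Small worked graphs used throughout the unit tests: each element carries
#' a weighted network (constructed directly, bypassing annotation
#' weighting) and, where applicable, the expected detection outcome.
#'
#' - `k4`: an isolated unit-weight 4-clique; growth from any seed yields
#'   the full clique with fitness exactly 1.
#' - `k4_pendant`: the 4-clique plus a pendant node `e` attached to `d`
#'   with weight 0.1; growth from inside the clique rejects the pendant.
#' - `two_k4`: two disjoint unit-weight 4-cliques; detection returns
#'   exactly the two cliques.
#' - `triangle_pendant`: a unit triangle with a 0.9-weight pendant; growth
#'   from the pendant stalls below the minimum size, so only the triangle
#'   is detected.
#' - `os100`: a pair of identical 11-protein complexes whose overlap score
#'   is exactly 1 (100 per cent).
#' - `empty`: an empty weighted network (0 complexes).
#'
#' @return a named list of fixtures; network fixtures hold `$wnet` (igraph
#'   with edge weights) and `$expected` (list of expected member sets),
#'   `os100` holds `$predicted` and `$reference`.
#' @export
toy_fixtures <- function() {
  wgraph <- function(from, to, w) {
    nodes <- sort(unique(c(from, to)))
    igraph::graph_from_data_frame(
      data.frame(from = from, to = to, weight = w,
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  }
  k4e <- t(utils::combn(c("a", "b", "c", "d"), 2L))
  k4 <- wgraph(k4e[, 1L], k4e[, 2L], rep(1, 6))
  k4_pendant <- wgraph(c(k4e[, 1L], "d"), c(k4e[, 2L], "e"),
                       c(rep(1, 6), 0.1))
  k4e2 <- t(utils::combn(c("w", "x", "y", "z"), 2L))
  two_k4 <- wgraph(c(k4e[, 1L], k4e2[, 1L]), c(k4e[, 2L], k4e2[, 2L]),
                   rep(1, 12))
  # pendant weight 0.9: heavy enough that growth from p stalls at {p, c}
  # (size 2, discarded), so detection returns the bare triangle
  triangle_pendant <- wgraph(c("a", "a", "b", "c"), c("b", "c", "c", "p"),
                             c(1, 1, 1, 0.9))
  eleven <- sprintf("RN%02d", 1:11)
  list(
    k4 = list(wnet = k4, expected = list(c("a", "b", "c", "d"))),
    k4_pendant = list(wnet = k4_pendant,
                      expected = list(c("a", "b", "c", "d"))),
    two_k4 = list(wnet = two_k4,
                  expected = list(c("a", "b", "c", "d"),
                                  c("w", "x", "y", "z"))),
    triangle_pendant = list(wnet = triangle_pendant,
                            expected = list(c("a", "b", "c"))),
    os100 = list(predicted = eleven, reference = eleven),
    empty = list(wnet = igraph::make_empty_graph(0, directed = FALSE),
                 expected = list())
  )
}

#' Write a generated benchmark to files
#'
#' Writes the edge list, annotation table and ground-truth complex file of
#' a generated planted network in the package's standard text formats.
#'
#' @param gen result of [generate_planted_network].
#' @param prefix output path prefix; writes `<prefix>_network.tsv`,
#'   `<prefix>_annotations.tsv`, `<prefix>_truth.txt`.
#' @return invisibly, the three file paths.
#' @export
write_planted_network <- function(gen, prefix) {
  et <- edge_table(gen$network)
  paths <- c(network = paste0(prefix, "_network.tsv"),
             annotations = paste0(prefix, "_annotations.tsv"),
             truth = paste0(prefix, "_truth.txt"))
  writeLines(sprintf("%s\t%s", et$from, et$to), paths[["network"]])
  ann <- gen$annotations
  writeLines(unlist(lapply(names(ann), function(p)
    sprintf("%s\t%s", p, ann[[p]])), use.names = FALSE),
    paths[["annotations"]])
  write_complexes(gen$truth, paths[["truth"]])
  invisible(paths)
}
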