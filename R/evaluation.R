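#' Overlap score between two complexes
#'
#' \deqn{OS(p, g) = |p \cap g|^2 / (|p| \cdot |g|)}
#' The squared-intersection form rewards matches that cover a large
#' fraction of both complexes; OS = 1 exactly for identical sets and 0 for
#' disjoint ones. A predicted/reference pair is conventionally called a
#' match when OS >= 0.2.
#'
#' @param p,g non-empty character vectors of protein ids.
#' @return numeric in [0, 1].
#' @export
overlap_score <- function(p, g) {
  p <- unique(p); g <- unique(g)
  if (length(p) == 0L || length(g) == 0L) {
    stop("overlap_score requires non-empty sets", call. = FALSE)
  }
  length(intersect(p, g))^2 / (length(p) * length(g))
}

#' Match predicted against reference complexes
#'
#' A predicted complex counts as matched if any reference complex reaches
#' overlap score >= `omega` with it (and symmetrically for references);
#' matching is one-to-many, with no bipartite assignment. Precision is the
#' matched fraction of predictions, recall the matched fraction of
#' references, and the F-measure their harmonic mean.
#'
#' @param pred,ref [complex_set]s (or plain lists of id vectors).
#' @param omega match threshold in (0, 1], inclusive (default 0.2).
#' @return a list of class `match_result`: `precision`, `recall`,
#'   `f_measure`, `ncp`, `ncg`, `best_os_pred`, `best_os_ref`,
#'   `best_ref_index` (reference attaining each prediction's best OS).
#' @export
match_and_score <- function(pred, ref, omega = 0.2) {
  stopifnot(omega > 0, omega <= 1)
  pc <- if (inherits(pred, "complex_set")) pred$complexes else pred
  rc <- if (inherits(ref, "complex_set")) ref$complexes else ref
  if (length(pc) == 0L || length(rc) == 0L) {
    warning("empty predicted or reference set; all metrics 0", call. = FALSE)
    return(structure(list(precision = 0, recall = 0, f_measure = 0,
                          ncp = 0L, ncg = 0L,
                          best_os_pred = numeric(0),
                          best_os_ref = numeric(0),
                          best_ref_index = integer(0)),
                     class = "match_result"))
  }
  os <- matrix(0, nrow = length(pc), ncol = length(rc))
  for (i in seq_along(pc)) for (j in seq_along(rc)) {
    os[i, j] <- overlap_score(pc[[i]], rc[[j]])
  }
  best_p <- apply(os, 1L, max)
  best_g <- apply(os, 2L, max)
  ncp <- sum(best_p >= omega)
  ncg <- sum(best_g >= omega)
  precision <- ncp / length(pc)
  recall <- ncg / length(rc)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f_measure = f,
                 ncp = as.integer(ncp), ncg = as.integer(ncg),
                 best_os_pred = best_p, best_os_ref = best_g,
                 best_ref_index = apply(os, 1L, which.max)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> P = %.4f (%d matched), R = %.4f (%d matched), F = %.4f\n",
              x$precision, x$ncp, x$recall, x$ncg, x$f_measure))
  invisible(x)
}

#' Size-weighted Jaccard measures
#'
#' For each predicted complex its Jaccard measure is the maximum Jaccard
#' coefficient |A n B| / |A u B| over all reference complexes; `jaccard_i`
#' averages these over predictions weighted by complex size. `jaccard_s` is
#' the symmetric quantity over references, and `jaccard` the harmonic mean
#' of the two (0 when both are 0). Unlike threshold matching, these measures
#' credit partial overlap continuously.
#'
#' @param pred,ref [complex_set]s (or plain lists of id vectors).
#' @return a list with `jaccard_i`, `jaccard_s`, `jaccard`.
#' @export
jaccard_measures <- function(pred, ref) {
  pc <- if (inherits(pred, "complex_set")) pred$complexes else pred
  rc <- if (inherits(ref, "complex_set")) ref$complexes else ref
  if (length(pc) == 0L || length(rc) == 0L) {
    warning("empty predicted or reference set; Jaccard measures 0",
            call. = FALSE)
    return(list(jaccard_i = 0, jaccard_s = 0, jaccard = 0))
  }
  jac <- matrix(0, nrow = length(pc), ncol = length(rc))
  for (i in seq_along(pc)) for (j in seq_along(rc)) {
    a <- pc[[i]]; b <- rc[[j]]
    jac[i, j] <- length(intersect(a, b)) / length(union(a, b))
  }
  wp <- lengths(pc)
  wr <- lengths(rc)
  ji <- sum(wp * apply(jac, 1L, max)) / sum(wp)
  js <- sum(wr * apply(jac, 2L, max)) / sum(wr)
  j <- if (ji + js == 0) 0 else 2 * ji * js / (ji + js)
  list(jaccard_i = ji, jaccard_s = js, jaccard = j)
}

#' Evaluate a prediction against a reference catalogue
#'
#' Convenience wrapper computing both the threshold-matching metrics
#' ([match_and_score]) and the size-weighted Jaccard measures
#' ([jaccard_measures]).
#'
#' @param pred,ref [complex_set]s.
#' @param omega overlap-score match threshold (default 0.2).
#' @return a list with `precision`, `recall`, `f_measure`, `ncp`, `ncg`,
#'   `jaccard_i`, `jaccard_s`, `jaccard`.
#' @export
evaluate_complexes <- function(pred, ref, omega = 0.2) {
  m <- match_and_score(pred, ref, omega)
  j <- jaccard_measures(pred, ref)
  list(precision = m$precision, recall = m$recall, f_measure = m$f_measure,
       ncp = m$ncp, ncg = m$ncg,
       jaccard_i = j$jaccard_i, jaccard_s = j$jaccard_s, jaccard = j$jaccard)
}

#' Hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k` members of a functional group of
#' size `group_size` when sampling a complex of `complex_size` proteins
#' without replacement from a network of `network_size` proteins:
#' \deqn{p = 1 - \sum_{i=0}^{k-1} \binom{F}{i} \binom{N-F}{C-i} / \binom{N}{C}}
#' evaluated stably as the upper tail of the hypergeometric distribution.
#'
#' @param k observed members of the group in the complex (0 <= k <=
#'   min(group_size, complex_size)).
#' @param network_size N, proteins in the network.
#' @param group_size F, proteins of the network annotated with the term.
#' @param complex_size C, size of the complex.
#' @return numeric p-value in [0, 1]; `k = 0` gives exactly 1.
#' @export
enrichment_pvalue <- function(k, network_size, group_size, complex_size) {
  if (any(k < 0) || any(group_size > network_size) ||
      any(complex_size > network_size) ||
      any(k > pmin(group_size, complex_size))) {
    stop("infeasible hypergeometric arguments", call. = FALSE)
  }
  stats::phyper(k - 1, group_size, network_size - group_size, complex_size,
                lower.tail = FALSE)
}

#' Functional enrichment of detected complexes
#'
#' For every complex and every GO term annotating at least one of its
#' members, computes the hypergeometric tail p-value
#' ([enrichment_pvalue]) with N = the number of proteins in the analysed
#' network, F = the network proteins carrying the term, C = the complex
#' size and k = the complex members carrying the term. p-values are
#' Bonferroni-corrected; by default the correction factor is the number of
#' terms tested for that complex (per-query correction, as enrichment web
#' tools apply), optionally the global number of tests. A complex is
#' significant when its minimum corrected p-value is below `alpha`.
#'
#' @param pred a [complex_set] of detected complexes.
#' @param annot a `go_annotations` object.
#' @param network_nodes character vector of the proteins of the analysed
#'   network (the enrichment universe).
#' @param alpha significance level (default 0.01).
#' @param correction `"per_complex"` (default) or `"global"` Bonferroni
#'   scope.
#' @return a list of class `enrichment_result`: `tests` (data.frame with
#'   complex index, term, k, C, F, N, p, p_adj), `per_complex` (data.frame
#'   with min corrected p, best term and significance per complex),
#'   `n_significant`, `bins` (counts of complexes with min corrected p
#'   below 1e-15, 1e-10, 1e-5 and `alpha`), `mean_p` (arithmetic mean of
#'   per-complex minimum corrected p-values over tested complexes).
#' @export
enrich_complexes <- function(pred, annot, network_nodes, alpha = 0.01,
                             correction = c("per_complex", "global")) {
  correction <- match.arg(correction)
  pc <- if (inherits(pred, "complex_set")) pred$complexes else pred
  network_nodes <- unique(as.character(network_nodes))
  n_net <- length(network_nodes)
  ann <- annot[names(annot) %in% network_nodes]
  # term -> network frequency
  all_terms <- unlist(ann, use.names = FALSE)
  term_freq <- table(all_terms)
  rows <- list()
  for (i in seq_along(pc)) {
    cx <- intersect(pc[[i]], network_nodes)
    csize <- length(pc[[i]])
    terms <- sort(unique(unlist(ann[cx], use.names = FALSE)))
    if (length(terms) == 0L) next
    k <- vapply(terms, function(t)
      sum(vapply(ann[cx], function(ts) t %in% ts, TRUE)), 0L)
    f <- as.integer(term_freq[terms])
    p <- enrichment_pvalue(k, n_net, f, csize)
    rows[[length(rows) + 1L]] <- data.frame(
      complex = i, term = terms, k = as.integer(k), C = csize, F = f,
      N = n_net, p = p, stringsAsFactors = FALSE, row.names = NULL)
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex = integer(0), term = character(0), k = integer(0),
               C = integer(0), F = integer(0), N = integer(0),
               p = numeric(0), stringsAsFactors = FALSE)
  m_global <- nrow(tests)
  if (nrow(tests)) {
    m <- if (correction == "global") m_global else
      stats::ave(tests$p, tests$complex, FUN = length)
    tests$p_adj <- pmin(1, tests$p * m)
  } else {
    tests$p_adj <- numeric(0)
  }
  per <- data.frame(complex = seq_along(pc),
                    min_p_adj = NA_real_,
                    best_term = NA_character_,
                    significant = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tests)) {
    for (i in unique(tests$complex)) {
      sub <- tests[tests$complex == i, , drop = FALSE]
      b <- which.min(sub$p_adj)
      per$min_p_adj[i] <- sub$p_adj[b]
      per$best_term[i] <- sub$term[b]
      per$significant[i] <- sub$p_adj[b] < alpha
    }
  }
  tested <- !is.na(per$min_p_adj)
  bins <- c(`<1e-15` = sum(per$min_p_adj[tested] < 1e-15),
            `<1e-10` = sum(per$min_p_adj[tested] < 1e-10),
            `<1e-5` = sum(per$min_p_adj[tested] < 1e-5),
            significant = sum(per$significant))
  structure(list(tests = tests, per_complex = per,
                 n_significant = sum(per$significant),
                 bins = bins,
                 mean_p = if (any(tested)) mean(per$min_p_adj[tested])
                          else NA_real_,
                 alpha = alpha),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", nrow(x$per_complex), " complexes, ",
      x$n_significant, " significant at alpha = ", x$alpha,
      "; mean min p_adj = ", signif(x$mean_p, 3), "\n", sep = "")
  invisible(x)
}
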