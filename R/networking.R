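# Molecular networking: pairwise MS/MS similarity with forward/reverse
# coverage, thresholded edges, per-node top-K pruning and cluster capping.

#' Molecular-networking parameters
#'
#' Defaults follow the quality-controlled settings under which all panel
#' standards interconnect: minimum similarity score 20 (0-100 scale),
#' minimum forward-or-reverse coverage 20%, at least 3 matched fragments,
#' at most 10 connections per node, cluster size capped at 100.
#'
#' @param min_score Minimum similarity score (0-100) to store an edge.
#' @param min_coverage_percent Minimum of max(forward, reverse) coverage.
#' @param min_matched_fragments Minimum matched fragment ions.
#' @param max_edges_per_node Top-K edge retention per node.
#' @param max_cluster_size Connected-component size cap.
#' @param fragment_tolerance_ppm Fragment matching tolerance.
#' @param coverage One of `"intensity"` (matched intensity fraction) or
#'   `"count"` (matched peak fraction).
#' @return list of class `network_params`.
#' @export
network_params <- function(min_score = 20, min_coverage_percent = 20,
                           min_matched_fragments = 3,
                           max_edges_per_node = 10, max_cluster_size = 100,
                           fragment_tolerance_ppm = 5,
                           coverage = c("intensity", "count")) {
  stopifnot(min_score >= 0, min_coverage_percent >= 0,
            min_matched_fragments >= 0, max_edges_per_node >= 0,
            max_cluster_size >= 2)
  structure(list(min_score = min_score,
                 min_coverage_percent = min_coverage_percent,
                 min_matched_fragments = min_matched_fragments,
                 max_edges_per_node = max_edges_per_node,
                 max_cluster_size = max_cluster_size,
                 fragment_tolerance_ppm = fragment_tolerance_ppm,
                 coverage = match.arg(coverage)),
            class = "network_params")
}

#' Spectral similarity of two MS/MS spectra
#'
#' Greedy best-pair fragment matching within a ppm tolerance (pairs taken in
#' decreasing order of intensity product, each peak used once), followed by
#' an intensity-weighted cosine over the matched pairs with norms taken over
#' all peaks, scaled to 0-100. Forward coverage is the matched share of
#' spectrum `a` (intensity-weighted by default), reverse coverage that of
#' `b`; swapping the arguments swaps the coverages and preserves the score.
#'
#' @param a,b `spectrum_record`s with at least one peak each.
#' @param tolerance_ppm Fragment matching tolerance.
#' @param coverage `"intensity"` or `"count"`.
#' @return list(`score`, `forward_coverage`, `reverse_coverage`,
#'   `n_matched`).
#' @export
spectral_similarity <- function(a, b, tolerance_ppm = 5,
                                coverage = c("intensity", "count")) {
  coverage <- match.arg(coverage)
  pa <- a$peaks; pb <- b$peaks
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop("spectral similarity of an empty spectrum", call. = FALSE)
  }
  ppm <- abs(outer(pa$mz, pb$mz, function(x, y) (x - y) / y * 1e6))
  cand <- which(ppm <= tolerance_ppm, arr.ind = TRUE)
  n_matched <- 0L
  dot <- 0
  int_a <- 0; int_b <- 0
  if (nrow(cand)) {
    prod_int <- pa$intensity[cand[, 1]] * pb$intensity[cand[, 2]]
    ord <- order(-prod_int,
                 abs(pa$mz[cand[, 1]] - pb$mz[cand[, 2]]))
    used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      n_matched <- n_matched + 1L
      dot <- dot + pa$intensity[i] * pb$intensity[j]
      int_a <- int_a + pa$intensity[i]
      int_b <- int_b + pb$intensity[j]
    }
    if (coverage == "count") {
      int_a <- sum(used_a); int_b <- sum(used_b)
    }
  }
  norm <- sqrt(sum(pa$intensity^2)) * sqrt(sum(pb$intensity^2))
  denom_a <- if (coverage == "intensity") sum(pa$intensity) else nrow(pa)
  denom_b <- if (coverage == "intensity") sum(pb$intensity) else nrow(pb)
  list(score = 100 * dot / norm,
       forward_coverage = 100 * int_a / denom_a,
       reverse_coverage = 100 * int_b / denom_b,
       n_matched = n_matched)
}

#' Build a molecular network
#'
#' Computes all pairwise similarities, keeps a candidate edge iff score >=
#' `min_score` AND max(forward, reverse coverage) >= `min_coverage_percent`
#' AND matched fragments >= `min_matched_fragments`; prunes to the top
#' `max_edges_per_node` edges per node (an edge survives if either endpoint
#' retains it); and enforces the cluster-size cap by iteratively removing
#' the weakest edge (lowest score, ties by lexicographic edge id) inside any
#' oversized connected component. Deterministic under node reordering:
#' nodes are addressed by their (unique) names.
#'
#' @param spectra Named-or-unnamed list of `spectrum_record` (>= 2); node
#'   ids default to spectrum names.
#' @param params [network_params()].
#' @param labels Optional named character vector of annotation labels (e.g.
#'   `"PA"`) per node id.
#' @return Object of class `spectral_graph`: list(`graph` igraph, `edges`
#'   data.frame, `nodes` data.frame with `cluster` membership).
#' @export
build_network <- function(spectra, params = network_params(),
                          labels = NULL) {
  stopifnot(length(spectra) >= 2L)
  ids <- names(spectra)
  if (is.null(ids)) {
    ids <- vapply(spectra, function(s) s$name, character(1))
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  ord <- order(ids)          # canonical node order for determinism
  spectra <- spectra[ord]; ids <- ids[ord]
  n <- length(spectra)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sim <- spectral_similarity(spectra[[i]], spectra[[j]],
                                 params$fragment_tolerance_ppm,
                                 params$coverage)
      if (sim$score >= params$min_score &&
          max(sim$forward_coverage, sim$reverse_coverage) >=
            params$min_coverage_percent &&
          sim$n_matched >= params$min_matched_fragments) {
        edges[[length(edges) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], score = sim$score,
          forward_coverage = sim$forward_coverage,
          reverse_coverage = sim$reverse_coverage,
          n_matched = sim$n_matched, stringsAsFactors = FALSE)
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0), score = numeric(0),
               forward_coverage = numeric(0), reverse_coverage = numeric(0),
               n_matched = integer(0), stringsAsFactors = FALSE)

  # per-node top-K pruning: an edge survives if either endpoint keeps it
  if (nrow(edf) && is.finite(params$max_edges_per_node)) {
    keep <- rep(FALSE, nrow(edf))
    for (v in ids) {
      inc <- which(edf$a == v | edf$b == v)
      if (!length(inc)) next
      inc <- inc[order(-edf$score[inc], edf$a[inc], edf$b[inc])]
      keep[inc[seq_len(min(length(inc), params$max_edges_per_node))]] <- TRUE
    }
    edf <- edf[keep, , drop = FALSE]
  }

  # cluster cap: drop weakest edge inside oversized components
  repeat {
    g <- igraph::graph_from_data_frame(edf[, c("a", "b")], directed = FALSE,
                                       vertices = data.frame(name = ids))
    comp <- igraph::components(g)
    big <- which(comp$csize > params$max_cluster_size)
    if (!length(big) || !nrow(edf)) break
    members <- names(comp$membership)[comp$membership %in% big]
    inside <- edf$a %in% members & edf$b %in% members
    cand <- which(inside)
    cand <- cand[order(edf$score[cand], edf$a[cand], edf$b[cand])]
    edf <- edf[-cand[1], , drop = FALSE]
  }
  rownames(edf) <- NULL
  for (col in c("score", "forward_coverage", "reverse_coverage",
                "n_matched")) {
    g <- igraph::set_edge_attr(g, col, value = edf[[col]])
  }
  comp <- igraph::components(g)
  nodes <- data.frame(id = ids,
                      cluster = comp$membership[ids],
                      label = if (is.null(labels)) NA_character_ else
                        unname(labels[ids]),
                      stringsAsFactors = FALSE)
  g <- igraph::set_vertex_attr(g, "label", value = nodes$label)
  structure(list(graph = g, edges = edf, nodes = nodes, params = params),
            class = "spectral_graph")
}

#' @export
print.spectral_graph <- function(x, ...) {
  cat(sprintf("<spectral_graph> %d nodes, %d edges, %d clusters (max size %d)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$cluster)),
              max(table(x$nodes$cluster))))
  invisible(x)
}

#' Cluster membership of a query node
#'
#' Returns the query's connected component and the annotation labels of its
#' members; the query is flagged a putative PA when its cluster contains at
#' least `min_annotated` members labelled `"PA"` (candidate-reduction rule).
#'
#' @param graph `spectral_graph`.
#' @param query_node Node id.
#' @param min_annotated Flagging threshold m (default 3).
#' @return list(`cluster`, `members`, `labels`, `n_annotated_pa`,
#'   `putative_pa`).
#' @export
cluster_membership <- function(graph, query_node, min_annotated = 3L) {
  i <- match(query_node, graph$nodes$id)
  if (is.na(i)) stop("unknown node '", query_node, "'", call. = FALSE)
  cl <- graph$nodes$cluster[i]
  members <- graph$nodes$id[graph$nodes$cluster == cl]
  labels <- graph$nodes$label[graph$nodes$cluster == cl]
  n_pa <- sum(labels == "PA" & members != query_node, na.rm = TRUE)
  list(cluster = cl, members = members, labels = labels,
       n_annotated_pa = n_pa, putative_pa = n_pa >= min_annotated)
}

#' Export a network
#'
#' @param graph `spectral_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}
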