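# Master-regulator search: bounded reverse BFS from each active TF, a
# distance-decayed key-node score with a hub penalty, and a permutation
# null over random same-size TF sets giving Z-scores and an empirical
# rank FDR.

#' Parameters of the master-regulator search
#'
#' @param radius Maximum number of upstream steps (default 12).
#' @param beta Distance decay in `(0, 1]` (default 0.5).
#' @param n_permutations Random TF-set draws for the null (default 1000;
#'   at least 100 are required for FDR output).
#' @param fdr_cut FDR selection cutoff (default 0.05).
#' @param seed Integer seed for the permutation draws.
#' @return A list of validated parameters.
#' @export
mr_params <- function(radius = 12L, beta = 0.5, n_permutations = 1000L,
                      fdr_cut = 0.05, seed = 1L) {
  stopifnot(radius >= 1L, beta > 0, beta <= 1, n_permutations >= 1L,
            fdr_cut > 0)
  list(radius = as.integer(radius), beta = beta,
       n_permutations = as.integer(n_permutations), fdr_cut = fdr_cut,
       seed = as.integer(seed))
}

#' Shortest upstream distances from every node to a TF set
#'
#' Runs a breadth-first search from each TF along reversed edges, to
#' depth `radius`: node u is at distance d from TF t iff the shortest
#' directed path u -> ... -> t has length d <= radius. A TF reaches
#' itself at distance 0.
#'
#' @param network A `signaling_network`.
#' @param tf_set TFs to search from (subset of `network$tf_nodes`).
#' @param radius Maximum path length.
#' @return Numeric matrix nodes x TFs of distances (`Inf` = unreached).
#' @export
upstream_reach <- function(network, tf_set, radius = 12L) {
  if (length(tf_set) == 0L) stop("empty tf_set", call. = FALSE)
  stopifnot(all(tf_set %in% network$tf_nodes))
  radj <- split(network$edges$source, network$edges$target)  # incoming
  D <- matrix(Inf, length(network$nodes), length(tf_set),
              dimnames = list(network$nodes, tf_set))
  for (tf in tf_set) {
    d <- bfs_levels(radj, tf, network$nodes)
    d[d > radius] <- Inf
    D[, tf] <- d
  }
  D
}

#' Key-node scores from an upstream-distance matrix
#'
#' `S(u) = sum_t beta^d(u,t) / log2(2 + outdegree(u))`: a node scores
#' higher the more TFs it reaches and the shorter the paths, with a
#' logarithmic penalty against indiscriminate hubs.
#'
#' @param distances Matrix from [upstream_reach()].
#' @param out_degree Named integer vector of node out-degrees.
#' @param beta Distance decay in `(0, 1]`.
#' @return Named numeric vector of scores.
#' @export
key_node_score <- function(distances, out_degree, beta = 0.5) {
  reach <- beta^distances        # Inf -> 0
  reach[!is.finite(distances)] <- 0
  s <- rowSums(reach) / log2(2 + out_degree[rownames(distances)])
  setNames(as.numeric(s), rownames(distances))
}

# internal: out-degree of every node
network_out_degree <- function(network) {
  tab <- table(network$edges$source)
  deg <- setNames(rep(0L, length(network$nodes)), network$nodes)
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Null key-node scores from random TF sets
#'
#' Draws `n_permutations` TF sets of the observed size uniformly without
#' replacement from `network$tf_nodes` and scores every node against
#' each. Distances to all TFs are computed once; each permutation is a
#' column subset.
#'
#' @param network A `signaling_network`.
#' @param set_size Size of the observed TF set.
#' @param params An [mr_params()] list.
#' @return Matrix nodes x permutations of null scores.
#' @export
permutation_null <- function(network, set_size, params = mr_params()) {
  if (set_size > length(network$tf_nodes))
    stop("set_size exceeds number of TF nodes", call. = FALSE)
  set.seed(params$seed)
  D_all <- upstream_reach(network, network$tf_nodes, params$radius)
  deg <- network_out_degree(network)
  pen <- log2(2 + deg[rownames(D_all)])
  reach <- params$beta^D_all
  reach[!is.finite(D_all)] <- 0
  null <- matrix(0, nrow(D_all), params$n_permutations,
                 dimnames = list(rownames(D_all), NULL))
  for (b in seq_len(params$n_permutations)) {
    cols <- sample.int(ncol(reach), set_size)
    null[, b] <- rowSums(reach[, cols, drop = FALSE]) / pen
  }
  null
}

#' Rank nodes, attach Z-scores and empirical FDR, and select
#'
#' Nodes are ranked by decreasing score (ties broken by node id). Each
#' node's Z-score uses its own null mean and sd (sd of zero yields an
#' `Inf` sentinel). The FDR at rank r is the null-average count of
#' permutation scores among the top r that meet or exceed the observed
#' score at rank r, divided by r, clipped to `[0,1]` and made monotone
#' non-decreasing down the ranking. Selection is `fdr < fdr_cut`; FDR is
#' only reported with at least 100 permutations.
#'
#' @param scores Named observed scores (from [key_node_score()]).
#' @param null Matrix from [permutation_null()].
#' @param params An [mr_params()] list.
#' @param n_tfs_reached Optional named vector with the number of TFs each
#'   node reaches, carried into the result.
#' @return An `mr_result` data.frame: `node`, `score`, `n_tfs_reached`,
#'   `z_score`, `fdr`, `rank`, `selected`.
#' @export
rank_and_select <- function(scores, null, params = mr_params(),
                            n_tfs_reached = NULL) {
  keep <- scores > 0
  nodes <- names(scores)[keep]
  ord <- order(-scores[keep], nodes)
  nodes <- nodes[ord]
  s <- unname(scores[nodes])
  nm <- rowMeans(null)[nodes]
  nsd <- apply(null[nodes, , drop = FALSE], 1L, sd)
  nsd[is.na(nsd)] <- 0   # single-permutation null: fall back to sentinel
  z <- ifelse(nsd == 0, ifelse(s > nm, Inf, 0), (s - nm) / nsd)
  n_rank <- length(nodes)
  if (ncol(null) >= 100L && n_rank > 0L) {
    # per permutation: its node scores sorted decreasing
    sorted_null <- apply(null, 2L, sort, decreasing = TRUE)
    if (is.null(dim(sorted_null)))
      sorted_null <- matrix(sorted_null, nrow = 1L)
    fdr <- vapply(seq_len(n_rank), function(r) {
      thr <- s[[r]]
      top <- sorted_null[seq_len(min(r, nrow(sorted_null))), , drop = FALSE]
      mean(colSums(top >= thr)) / r
    }, numeric(1))
    fdr <- cummax(pmin(pmax(fdr, 0), 1))
  } else {
    fdr <- rep(NA_real_, n_rank)
  }
  res <- data.frame(node = nodes, score = s,
                    n_tfs_reached = if (is.null(n_tfs_reached))
                      rep(NA_integer_, n_rank)
                    else unname(n_tfs_reached[nodes]),
                    z_score = unname(z), fdr = fdr,
                    rank = seq_len(n_rank),
                    selected = !is.na(fdr) & fdr < params$fdr_cut,
                    stringsAsFactors = FALSE)
  structure(res, class = c("mr_result", "data.frame"), params = params)
}

#' Full master-regulator search for one TF set
#'
#' Computes observed key-node scores, the permutation null, Z-scores and
#' empirical FDR, and selects candidate master regulators.
#'
#' @param network A `signaling_network`.
#' @param tf_set Active TFs (subset of `network$tf_nodes`).
#' @param params An [mr_params()] list.
#' @param direction Optional `"up"`/`"down"` label attached to the
#'   result (the two DEG directions are searched independently).
#' @return An `mr_result` data.frame.
#' @export
find_master_regulators <- function(network, tf_set, params = mr_params(),
                                   direction = NA_character_) {
  D <- upstream_reach(network, tf_set, params$radius)
  deg <- network_out_degree(network)
  scores <- key_node_score(D, deg, params$beta)
  n_reached <- setNames(as.integer(rowSums(is.finite(D))),
                        rownames(D))
  null <- permutation_null(network, length(tf_set), params)
  res <- rank_and_select(scores, null, params, n_tfs_reached = n_reached)
  res$direction <- direction
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("mr_result: %d scored nodes, %d selected (fdr < %g)\n",
              nrow(x), sum(x$selected, na.rm = TRUE),
              attr(x, "params")$fdr_cut))
  NextMethod()
}

#' @export
summary.mr_result <- function(object, n = 10L, ...) {
  cat(sprintf("Top %d candidate master regulators:\n",
              min(n, nrow(object))))
  print(head(as.data.frame(object), n), row.names = FALSE)
  invisible(object)
}
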