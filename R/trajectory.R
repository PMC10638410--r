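## Cluster-based minimum-spanning-tree pseudotime construction: k-means on
## the harmonized embedding, MST over cluster centers, branch enumeration
## from a user-specified origin, orthogonal projection pseudotime.

#' Cluster cells in the embedding
#'
#' K-means clustering of the cell embedding. When `k` is absent it is chosen
#' by an elbow rule: the smallest k in 2..25 whose relative drop in
#' within-cluster sum of squares (to k+1) falls below 10%.
#'
#' @param embedding cells x D numeric matrix (rownames = cell ids).
#' @param k optional fixed cluster number (>= 2).
#' @param seed RNG seed (k-means uses 10 restarts).
#' @param k_range candidate range for the elbow search.
#' @param elbow_threshold relative-drop threshold (default 0.1).
#' @return list with `cluster_of_cell` (named integer vector) and `centers`
#'   (k x D matrix).
#' @export
cluster_cells <- function(embedding, k = NULL, seed = 1,
                          k_range = 2:25, elbow_threshold = 0.1) {
  embedding <- as.matrix(embedding)
  input_order <- rownames(embedding)
  if (!is.null(input_order))              # canonical order: invariant to the
    embedding <- embedding[order(input_order), , drop = FALSE]
  n <- nrow(embedding)                    # caller's cell ordering
  if (is.null(k)) {
    kmax <- min(max(k_range), n - 1L)
    wss <- with_seed(seed, vapply(seq_len(kmax + 1L), function(kk)
      stats::kmeans(embedding, kk, nstart = 10,
                    iter.max = 50)$tot.withinss, numeric(1)))
    k <- max(min(k_range), elbow_k(wss, elbow_threshold))
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("fewer cells than clusters")
  km <- with_seed(seed, stats::kmeans(embedding, k, nstart = 10,
                                      iter.max = 100))
  cl <- stats::setNames(km$cluster, rownames(embedding))
  if (!is.null(input_order)) cl <- cl[input_order]
  list(cluster_of_cell = cl, centers = km$centers, k = k)
}

#' Minimum spanning tree over cluster centers
#'
#' Euclidean-weight MST; with tied weights (e.g. duplicate centers) the tie
#' is broken deterministically by lower cluster index.
#'
#' @param centers k x D matrix of cluster centers.
#' @return data.frame edge list (`from`, `to`, `weight`) with k - 1 rows.
#' @export
build_mst <- function(centers) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k < 2L) stop("need at least 2 centers")
  if (any(!is.finite(centers))) stop("centers must be finite")
  d <- as.matrix(stats::dist(centers))
  if (any(d[upper.tri(d)] == 0))
    td_log("duplicate centers: tie broken by lower cluster index")
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(mst, names = FALSE)
  el <- t(apply(el, 1L, sort))
  ord <- order(el[, 1L], el[, 2L])
  data.frame(from = as.integer(el[ord, 1L]), to = as.integer(el[ord, 2L]),
             weight = igraph::E(mst)$weight[ord])
}

mst_graph <- function(mst_edges, k) {
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  igraph::add_edges(g, rbind(mst_edges$from, mst_edges$to))
}

#' Enumerate branches from the trajectory origin
#'
#' Roots the MST at the origin cluster and enumerates one branch per
#' root-to-leaf path (branching wherever a node has degree > 2). The origin
#' is given either as a cluster id or as a marker gene list, in which case
#' the cluster with the highest mean marker expression is used.
#'
#' @param mst_edges edge list from [build_mst()].
#' @param k number of clusters.
#' @param origin_spec origin cluster id, or character vector of marker genes
#'   (requires `dataset` and `cluster_of_cell`).
#' @param dataset,cluster_of_cell needed for marker-based origin lookup.
#' @return list of integer cluster sequences, each starting at the origin.
#' @export
root_and_enumerate <- function(mst_edges, k, origin_spec, dataset = NULL,
                               cluster_of_cell = NULL) {
  if (is.character(origin_spec)) {
    if (is.null(dataset) || is.null(cluster_of_cell))
      stop("marker-based origin needs dataset and cluster assignments")
    missing_g <- setdiff(origin_spec, dataset$gene_ids)
    if (length(missing_g))
      stop("marker gene(s) not found: ", paste(missing_g, collapse = ", "))
    expr <- get_expression(dataset, origin_spec)
    expr <- expr[, names(cluster_of_cell), drop = FALSE]
    means <- vapply(seq_len(k), function(cl)
      mean(expr[, cluster_of_cell == cl, drop = FALSE]), numeric(1))
    origin <- which.max(means)
  } else {
    origin <- as.integer(origin_spec)
    if (origin < 1L || origin > k) stop("origin cluster out of range")
  }
  g <- mst_graph(mst_edges, k)
  deg <- igraph::degree(g)
  leaves <- setdiff(which(deg == 1L), origin)
  if (!length(leaves)) leaves <- setdiff(seq_len(k), origin)
  paths <- igraph::shortest_paths(g, from = origin, to = leaves)$vpath
  branches <- lapply(paths, function(p) as.integer(p))
  attr(branches, "origin") <- origin
  branches
}

#' Pseudotime by orthogonal projection onto the branch backbone
#'
#' Each member cell is projected onto the nearest segment between
#' consecutive centers flanking its own cluster; pseudotime is the arc
#' length from the origin end to the projection (raw units of embedding
#' distance). A `[0, 1]` rescaling is applied per branch for modeling.
#'
#' @param branch_clusters integer cluster sequence from the origin.
#' @param cluster_of_cell named cluster assignment.
#' @param centers cluster centers.
#' @param embedding cells x D matrix.
#' @return object of class `td_branch`: `clusters`, `cells`,
#'   `pseudotime_raw`, `pseudotime` (rescaled to \[0, 1\]).
#' @export
assign_pseudotime <- function(branch_clusters, cluster_of_cell, centers,
                              embedding) {
  if (!length(branch_clusters)) stop("empty branch")
  cells <- sort(names(cluster_of_cell)[cluster_of_cell %in% branch_clusters])
  L <- length(branch_clusters)
  if (L == 1L) {
    ptraw <- stats::setNames(rep(0, length(cells)), cells)
  } else {
    seglen <- vapply(seq_len(L - 1L), function(i)
      sqrt(sum((centers[branch_clusters[i + 1L], ] -
                  centers[branch_clusters[i], ])^2)), numeric(1))
    cum0 <- c(0, cumsum(seglen))
    pos <- match(cluster_of_cell[cells], branch_clusters)
    ptraw <- numeric(length(cells))
    for (ci in seq_along(cells)) {
      i <- pos[ci]
      segs <- intersect(c(i - 1L, i), seq_len(L - 1L))
      z <- embedding[cells[ci], ]
      best <- Inf; best_pt <- 0
      for (sg in segs) {
        a <- centers[branch_clusters[sg], ]
        b <- centers[branch_clusters[sg + 1L], ]
        ab <- b - a
        len2 <- sum(ab^2)
        tt <- if (len2 > 0) min(max(sum((z - a) * ab) / len2, 0), 1) else 0
        proj <- a + tt * ab
        d2 <- sum((z - proj)^2)
        if (d2 < best - 1e-15) {     # ties resolved toward the earlier segment
          best <- d2
          best_pt <- cum0[sg] + tt * sqrt(len2)
        }
      }
      ptraw[ci] <- best_pt
    }
    names(ptraw) <- cells
  }
  rng <- range(ptraw)
  pt <- if (diff(rng) > 0) (ptraw - rng[1L]) / diff(rng)
        else stats::setNames(rep(0, length(ptraw)), names(ptraw))
  b <- list(clusters = branch_clusters, cells = cells,
            pseudotime_raw = ptraw, pseudotime = pt)
  class(b) <- "td_branch"
  b
}

#' @export
print.td_branch <- function(x, ...) {
  cat(sprintf("branch %s: %d cells\n",
              paste(x$clusters, collapse = " -> "), length(x$cells)))
  invisible(x)
}

#' Build the full pseudotemporal trajectory
#'
#' Runs clustering, MST construction, branch enumeration from the origin and
#' per-branch pseudotime assignment.
#'
#' @param dataset an `msd` dataset with an embedding.
#' @param origin origin cluster id or marker gene vector.
#' @param k optional fixed number of clusters (elbow-selected otherwise).
#' @param seed RNG seed.
#' @return object of class `trajectory_tree`: `n_clusters`,
#'   `cluster_of_cell`, `centers`, `mst_edges`, `origin_cluster`, `branches`
#'   (list of `td_branch`).
#' @export
infer_trajectory <- function(dataset, origin, k = NULL, seed = 1) {
  stopifnot(inherits(dataset, "msd"))
  if (is.null(dataset$embedding)) stop("dataset has no embedding")
  cl <- cluster_cells(dataset$embedding, k = k, seed = seed)
  mst <- build_mst(cl$centers)
  seqs <- root_and_enumerate(mst, cl$k, origin, dataset, cl$cluster_of_cell)
  branches <- lapply(seqs, assign_pseudotime,
                     cluster_of_cell = cl$cluster_of_cell,
                     centers = cl$centers, embedding = dataset$embedding)
  names(branches) <- vapply(seqs, function(p)
    paste(p, collapse = "-"), character(1))
  tree <- list(n_clusters = cl$k, cluster_of_cell = cl$cluster_of_cell,
               centers = cl$centers, mst_edges = mst,
               origin_cluster = attr(seqs, "origin"), branches = branches)
  class(tree) <- "trajectory_tree"
  tree
}

#' @export
print.trajectory_tree <- function(x, ...) {
  cat(sprintf("trajectory_tree: %d clusters, origin %d, %d branch(es)\n",
              x$n_clusters, x$origin_cluster, length(x$branches)))
  for (nm in names(x$branches))
    cat(sprintf("  %s (%d cells)\n", nm, length(x$branches[[nm]]$cells)))
  invisible(x)
}

# Mean pseudotime of each cell over the branches containing it (used as the
# reference ordering when re-rooting bootstrap trajectories).
global_pseudotime <- function(tree) {
  acc <- list()
  for (b in tree$branches)
    for (ci in seq_along(b$cells))
      acc[[b$cells[ci]]] <- c(acc[[b$cells[ci]]], b$pseudotime[ci])
  vapply(acc, mean, numeric(1))
}

#' Export the trajectory as plain tables
#' @param tree a `trajectory_tree`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_trajectory <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tree$mst_edges, file.path(dir, "tree_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- do.call(rbind, lapply(names(tree$branches), function(nm) {
    b <- tree$branches[[nm]]
    data.frame(cell_id = b$cells, branch_id = nm,
               pseudotime_raw = as.numeric(b$pseudotime_raw),
               pseudotime_scaled = as.numeric(b$pseudotime))
  }))
  utils::write.table(rows, file.path(dir, "branches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
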