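#' Minimum spanning tree of a PLI connectivity matrix (Kruskal)
#'
#' Link distance is `1 - PLI`, so the minimum spanning tree is the
#' maximum-connectivity backbone: the unique acyclic sub-graph joining all
#' `N` nodes with `m = N - 1` links of minimal total distance. Kruskal's
#' algorithm sorts candidate links by distance and adds each unless it closes
#' a cycle (union-find). Ties are broken lexicographically by node pair so
#' the result is deterministic; alternatively a seeded jitter at the 1e-12
#' scale enforces strict weight uniqueness.
#'
#' @param pli symmetric channels x channels PLI matrix (values in `[0, 1]`).
#' @param jitter_seed optional integer; if given, adds deterministic uniform
#'   jitter of magnitude 1e-12 to the distances before sorting.
#' @return Object of class `spanning_tree`: list with `n_nodes`, `m`,
#'   `edges` (data.frame `i`, `j`, `pli`), `labels`.
#' @export
kruskal_mst <- function(pli, jitter_seed = NULL) {
  pli <- as.matrix(pli)
  n <- nrow(pli)
  if (n < 2L) stop("need at least 2 nodes")
  if (ncol(pli) != n || !isSymmetric(unname(pli), tol = 1e-12))
    stop("PLI matrix must be square and symmetric")
  idx <- which(upper.tri(pli), arr.ind = TRUE)
  d <- 1 - pli[upper.tri(pli)]
  if (!is.null(jitter_seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(jitter_seed)
    d <- d + stats::runif(length(d), 0, 1e-12)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  ord <- order(d, idx[, 1], idx[, 2])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ei <- integer(n - 1L); ej <- integer(n - 1L); ew <- numeric(n - 1L)
  k <- 0L
  for (r in ord) {
    a <- find(idx[r, 1]); b <- find(idx[r, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      ei[k] <- idx[r, 1]; ej[k] <- idx[r, 2]; ew[k] <- pli[idx[r, 1], idx[r, 2]]
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) stop("could not span all nodes (non-finite distances?)")
  structure(list(n_nodes = n, m = n - 1L,
                 edges = data.frame(i = ei, j = ej, pli = ew),
                 labels = rownames(pli) %||% as.character(seq_len(n))),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d links, mean link PLI %.4f\n",
              x$n_nodes, x$m, mean(x$edges$pli)))
  invisible(x)
}

# adjacency list of a spanning_tree
tree_adjacency <- function(tree) {
  adj <- vector("list", tree$n_nodes)
  for (r in seq_len(tree$m)) {
    i <- tree$edges$i[r]; j <- tree$edges$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# hop distances from one node by BFS
tree_bfs_depths <- function(adj, root, n) {
  depth <- rep.int(NA_integer_, n)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (u in adj[[v]]) if (is.na(depth[u])) {
      depth[u] <- depth[v] + 1L
      nxt <- c(nxt, u)
    }
    frontier <- nxt
  }
  depth
}

# subtree sizes hanging off each node: betweenness of u on a tree counts the
# node pairs whose unique path crosses u = sum over distinct component pairs.
tree_betweenness <- function(adj, n) {
  bc <- numeric(n)
  for (u in seq_len(n)) {
    comp_sizes <- integer(0)
    seen <- rep.int(FALSE, n)
    seen[u] <- TRUE
    for (v in adj[[u]]) {
      if (seen[v]) next
      # BFS component containing v with u removed
      size <- 0L
      frontier <- v
      seen[v] <- TRUE
      while (length(frontier)) {
        size <- size + length(frontier)
        nxt <- integer(0)
        for (w in frontier) for (x in adj[[w]]) if (!seen[x]) {
          seen[x] <- TRUE
          nxt <- c(nxt, x)
        }
        frontier <- nxt
      }
      comp_sizes <- c(comp_sizes, size)
    }
    s <- sum(comp_sizes)
    bc[u] <- (s^2 - sum(comp_sizes^2)) / 2
  }
  # pair normalization: fraction of the (N-1)(N-2)/2 pairs not involving u
  bc / ((n - 1) * (n - 2) / 2)
}

#' Topological metrics of a spanning tree
#'
#' Computes the standard MST summary metrics. With `N` nodes and `m = N - 1`
#' links: maximum degree (raw and / m); leaf number `L` (degree-1 nodes,
#' bounded by `2 <= L <= N - 1`) and leaf fraction `L / m`; diameter in hops
#' (longest shortest path, bounded above by `m - L + 2`) and mean
#' eccentricity, both raw and / m; betweenness centrality (pair-normalised to
#' `[0, 1]`; leaves have 0), summarised by its maximum and mean; tree
#' hierarchy `T_H = L / (2 m BC_max)`, the balance between short paths and
#' hub overload (0.5 for a star); degree correlation `R`, the Pearson
#' correlation of degrees over connected node pairs counted in both
#' directions (`NA` when endpoint degrees have zero variance, e.g. a star);
#' kappa `<k^2>/<k>`, the degree-distribution width (`>= 2(N-1)/N`); and the
#' MST mean, the mean PLI weight of the tree links.
#'
#' @param tree a [kruskal_mst] result with at least 3 nodes.
#' @return Named list of class `tree_metrics`.
#' @export
tree_metrics <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- tree$n_nodes
  if (n < 3L) stop("tree metrics need at least 3 nodes")
  m <- tree$m
  deg <- tabulate(c(tree$edges$i, tree$edges$j), nbins = n)
  leaves <- sum(deg == 1L)
  adj <- tree_adjacency(tree)
  ecc <- vapply(seq_len(n), function(v)
    max(tree_bfs_depths(adj, v, n)), integer(1))
  diam <- max(ecc)
  bc <- tree_betweenness(adj, n)
  bc_max <- max(bc)
  th <- leaves / (2 * m * bc_max)
  # degree correlation over symmetrized link endpoint pairs
  x <- c(deg[tree$edges$i], deg[tree$edges$j])
  y <- c(deg[tree$edges$j], deg[tree$edges$i])
  r <- if (stats::var(x) > 0) stats::cor(x, y) else NA_real_
  structure(list(
    n_nodes = n, m = m,
    degree_max = max(deg), degree_max_norm = max(deg) / m,
    leaf_number = leaves, leaf_fraction = leaves / m,
    diameter = diam, diameter_norm = diam / m,
    eccentricity_mean = mean(ecc), eccentricity_mean_norm = mean(ecc) / m,
    eccentricity_max = max(ecc),
    bc_max = bc_max, bc_mean = mean(bc),
    tree_hierarchy = th,
    degree_correlation = r,
    kappa = mean(deg^2) / mean(deg),
    mst_mean = mean(tree$edges$pli)
  ), class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<tree_metrics> N=%d m=%d | L=%d (%.3f) d=%d (%.3f) deg_max=%d\n",
    "  BC_max=%.3f T_H=%.3f R=%s kappa=%.3f mst_mean=%.4f\n"),
    x$n_nodes, x$m, x$leaf_number, x$leaf_fraction, x$diameter,
    x$diameter_norm, x$degree_max, x$bc_max, x$tree_hierarchy,
    ifelse(is.na(x$degree_correlation), "NA",
           sprintf("%.3f", x$degree_correlation)),
    x$kappa, x$mst_mean))
  invisible(x)
}

# metric names carried through epoch averaging and the statistical layer
metric_names <- function() {
  c("degree_max_norm", "leaf_fraction", "diameter_norm",
    "eccentricity_mean_norm", "bc_max", "tree_hierarchy",
    "degree_correlation", "kappa", "mst_mean")
}

#' Per-epoch MST metrics averaged over epochs
#'
#' For one band-filtered subject-by-condition recording: per epoch, compute
#' the PLI matrix, its MST and the tree metrics, then average each metric
#' arithmetically over epochs (never a tree of the average matrix). The mean
#' total PLI over all pairs is carried alongside. An undefined degree
#' correlation (zero variance) is excluded from its average; the count of
#' defined epochs is reported.
#'
#' @param rec_band band-filtered [eeg_recording].
#' @return one-row data.frame: `pli` (mean total PLI), the averaged metrics
#'   of [tree_metrics], and `r_defined` (epochs with defined R).
#' @export
subject_band_metrics <- function(rec_band) {
  mats <- pli_epochs(rec_band)
  rows <- lapply(mats, function(m) {
    tm <- tree_metrics(kruskal_mst(m))
    unlist(tm[metric_names()])
  })
  tab <- do.call(rbind, rows)
  out <- colMeans(tab, na.rm = TRUE)
  out["degree_correlation"] <-
    if (all(is.na(tab[, "degree_correlation"]))) NA_real_ else
      mean(tab[, "degree_correlation"], na.rm = TRUE)
  df <- as.data.frame(as.list(out))
  df$r_defined <- sum(!is.na(tab[, "degree_correlation"]))
  df$pli <- mean_total_pli(mats)
  df[, c("pli", metric_names(), "r_defined")]
}
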