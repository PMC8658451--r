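# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# all labeled spanning trees of n nodes via Pruefer sequences (n^(n-2) trees)
all_spanning_trees <- function(n) {
  if (n == 2L) return(list(cbind(1L, 2L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(r) pruefer_to_edges(seqs[r, ], n))
}

pruefer_to_edges <- function(pr, n) {
  degree <- rep.int(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(pr)) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, pr[k])
    degree[leaf] <- degree[leaf] - 1L
    degree[pr[k]] <- degree[pr[k]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# minimum total 1-PLI distance over an exhaustive tree enumeration
brute_force_mst_distance <- function(pli) {
  n <- nrow(pli)
  trees <- all_spanning_trees(n)
  min(vapply(trees, function(ed)
    sum(1 - pli[cbind(ed[, 1], ed[, 2])]), numeric(1)))
}

# step-up FDR from the definition: largest i with p_(i) <= i q / m
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thr <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(thr)) rej[o[seq_len(max(thr))]] <- TRUE
  rej
}

# random symmetric PLI-like matrix with unique weights
random_pli_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

# path / star PLI matrices: consecutive (or hub) pairs strong, others weak
path_pli <- function(n, strong = 0.9, weak = 0.1) {
  m <- matrix(weak, n, n); diag(m) <- 0
  for (i in seq_len(n - 1L)) m[i, i + 1L] <- m[i + 1L, i] <- strong
  m
}
star_pli <- function(n, strong = 0.9, weak = 0.1) {
  m <- matrix(weak, n, n); diag(m) <- 0
  m[1, -1] <- m[-1, 1] <- strong
  m
}

# igraph view of a spanning_tree, for cross-checks
tree_to_igraph <- function(tree) {
  igraph::graph_from_edgelist(as.matrix(tree$edges[, c("i", "j")]),
                              directed = FALSE)
}
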