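# shared fixtures, built in code at test time

# small hand-checkable trees
tree_2tip <- function() parse_newick("(A:1.0,B:1.0);")
tree_3tip <- function() parse_newick("((A:1,B:1):1,C:2);")
tree_star3 <- function() parse_newick("(A:1,B:1,C:1);")

# the canonical 14-taxon study-scale tree used across tests
tree_14 <- function() generate_yule_tree(14, birth_rate = 1, seed = 1)

# brute-force patristic distances: shortest weighted path over the edge
# graph by Floyd-Warshall, independent of ape's cophenetic
brute_patristic <- function(tree) {
  n_node <- max(tree$edge)
  d <- matrix(Inf, n_node, n_node)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    d[a, b] <- d[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(n_node)) {
    for (i in seq_len(n_node)) {
      dk <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], dk)
    }
  }
  n_tip <- length(tree$tip.label)
  out <- d[seq_len(n_tip), seq_len(n_tip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# direct double-sum Moran's I, independent of ape
brute_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(W)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / s0) * num / sum(z^2)
}

# standardized random matrices for PLSR tests
rand_xy <- function(n, p, q, seed) {
  set.seed(seed)
  list(X = scale(matrix(rnorm(n * p), n)), Y = scale(matrix(rnorm(n * q), n)))
}
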