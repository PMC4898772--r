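# Independent oracles used to verify the package's algorithms. These are
# deliberately naive (enumeration, textbook recursions, generic matrix
# exponentials) and share no code with the implementation they check.

# Exhaustive Mk likelihood: sum the joint probability over every
# assignment of states to internal nodes, using the ER transition matrix
# built by generic matrix exponentiation of the rate generator.
enum_er_matrix <- function(q, t, S) {
  G <- matrix(q, S, S)
  diag(G) <- -(S - 1) * q
  as.matrix(Matrix::expm(G * t))
}

enum_mk <- function(tree, states, q, S = 4L) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  st <- states[tree$tip.label]
  ids <- (ntip + 1L):(ntip + nnode)
  Pe <- lapply(seq_len(nrow(tree$edge)), function(i)
    enum_er_matrix(q, tree$edge.length[i], S))
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nnode)))
  lik_of <- function(assign_int) {
    full <- integer(ntip + nnode)
    full[seq_len(ntip)] <- st
    full[ids] <- assign_int
    p <- 1 / S # uniform root prior
    for (i in seq_len(nrow(tree$edge))) {
      a <- full[tree$edge[i, 1L]]
      b <- full[tree$edge[i, 2L]]
      p <- p * Pe[[i]][a, b]
    }
    p
  }
  liks <- apply(grid, 1L, lik_of)
  total <- sum(liks)
  # marginal posterior at each node (tips included, trivially indicators)
  marg <- matrix(0, ntip + nnode, S)
  marg[cbind(seq_len(ntip), st)] <- 1
  for (j in seq_len(nnode)) {
    for (s in seq_len(S)) {
      marg[ids[j], s] <- sum(liks[grid[, j] == s]) / total
    }
  }
  list(loglik = log(total), marginals = marg)
}

# Textbook de Boor recursion for one B-spline basis function B_{i,d} on an
# extended knot vector (0-based index i).
de_boor_basis <- function(x, knots, i, d) {
  if (d == 0) {
    return(as.numeric(knots[i + 1] <= x & x < knots[i + 2]))
  }
  denom1 <- knots[i + d + 1] - knots[i + 1]
  denom2 <- knots[i + d + 2] - knots[i + 2]
  a <- if (denom1 > 0) (x - knots[i + 1]) / denom1 *
    de_boor_basis(x, knots, i, d - 1) else 0
  b <- if (denom2 > 0) (knots[i + d + 2] - x) / denom2 *
    de_boor_basis(x, knots, i + 1, d - 1) else 0
  a + b
}

# A random rooted tree with exponential branch lengths (not necessarily
# ultrametric) and a random tip-state draw, for property tests.
random_tree <- function(n_tips, mean_bl = 0.5) {
  tr <- ape::rtree(n_tips, br = function(n) rexp(n, 1 / mean_bl))
  tr
}

random_states <- function(tree, S = 4L) {
  setNames(sample.int(S, length(tree$tip.label), replace = TRUE),
           tree$tip.label)
}

# Unordered comparison of rooted clade structures (bipartition sets) plus
# branch lengths: trees are isomorphic iff the multiset of
# (clade tip-set, subtending branch length) pairs matches.
tree_signature <- function(tree) {
  ntip <- length(tree$tip.label)
  key <- callspace:::clade_keys(tree)
  bl <- numeric(ntip + tree$Nnode)
  bl[tree$edge[, 2L]] <- tree$edge.length
  sig <- data.frame(clade = key, len = round(bl, 9))
  sig[order(sig$clade), ]
}
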