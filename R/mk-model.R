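#' Equal-rates Mk transition probability matrix
#'
#' Under the equal-rates (ER, "Mk1") model every transition between the S
#' character states has the same instantaneous rate `q`; the generator has
#' off-diagonal `q` and diagonal `-(S-1)q`. Its matrix exponential has the
#' closed form
#' \deqn{P_{ii}(t) = 1/S + \frac{S-1}{S} e^{-Sqt}, \qquad
#'       P_{ij}(t) = 1/S - \frac{1}{S} e^{-Sqt}.}
#'
#' @param q transition rate (per branch-length unit), `>= 0`.
#' @param t branch length, `>= 0`.
#' @param S number of states, `>= 2`.
#' @return an `S x S` symmetric stochastic matrix.
#' @export
er_transition_probability <- function(q, t, S = 4L) {
  if (!is.finite(q) || q < 0) stop("rate q must be >= 0")
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  if (S < 2) stop("S must be >= 2")
  e <- exp(-S * q * t)
  P <- matrix((1 - e) / S, S, S)
  diag(P) <- 1 / S + (S - 1) / S * e
  P
}

# Multiply the ER transition matrix into a conditional-likelihood vector
# without forming the matrix: (P v)_i = e*v_i + (1-e)*sum(v)/S.
er_prob_push <- function(v, q, t, S) {
  e <- exp(-S * q * t)
  e * v + (1 - e) * sum(v) / S
}

# Postorder pruning pass. Returns the matrix of scaled conditional
# likelihoods ("down" vectors: data in the subtree below each node), the
# accumulated log scaling factor per node, and the tree in postorder.
mk_down_pass <- function(tree, states, q, S) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  st <- match_tip_states(tree, states, S)
  tr <- if (ntip > 1L) ape::reorder.phylo(tree, "postorder") else tree
  ntot <- ntip + nnode
  D <- matrix(1, ntot, S)
  D[seq_len(ntip), ] <- 0
  D[cbind(seq_len(ntip), st)] <- 1
  logsc <- numeric(ntot)
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]
    ch <- tr$edge[i, 2L]
    pl <- er_prob_push(D[ch, ], q, tr$edge.length[i], S)
    D[par, ] <- D[par, ] * pl
    m <- max(D[par, ])
    if (m <= 0) stop("zero likelihood encountered during pruning")
    if (m < 1e-6) {
      D[par, ] <- D[par, ] / m
      logsc[par] <- logsc[par] + log(m)
    }
    logsc[par] <- logsc[par] + logsc[ch]
    logsc[ch] <- 0 # folded into the parent; avoid double counting
  }
  list(D = D, logsc = logsc, tree = tr, ntip = ntip, states = st)
}

#' Pruning log-likelihood of tip states under the ER Mk model
#'
#' Felsenstein's pruning algorithm with per-node scaling and a uniform
#' `1/S` root prior (the ER stationary distribution).
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @param states named integer vector of tip states (values in `1..S`).
#' @inheritParams er_transition_probability
#' @return the log-likelihood (a single finite number `<= 0`).
#' @export
mk_loglik <- function(tree, states, q, S = 4L) {
  if (!is.finite(q) || q < 0) stop("rate q must be >= 0")
  dp <- mk_down_pass(tree, states, q, S)
  root <- dp$ntip + 1L
  log(sum(dp$D[root, ]) / S) + dp$logsc[root]
}

#' Fit the single rate of the ER Mk model by maximum likelihood
#'
#' One-dimensional Brent search of the pruning log-likelihood over
#' `log10(q)` in `[-6, 3]` (covering any sane branch-length scale),
#' tolerance 1e-8 on the log10 scale. When all tips share one state the
#' likelihood is monotone decreasing in `q`; the boundary value is
#' returned with `converged = FALSE`.
#'
#' @inheritParams mk_loglik
#' @param interval search interval for `log10(q)`.
#' @return an object of class `"mk_fit"`: list with `q`, `S`,
#'   `log_likelihood`, `converged`, plus the tree and states for reuse by
#'   [ancestral_marginals()].
#' @export
fit_mk <- function(tree, states, S = 4L, interval = c(-6, 3)) {
  st <- match_tip_states(tree, states, S)
  if (length(unique(st)) == 1L) {
    q <- 10^interval[1L]
    fit <- list(q = q, S = S, log_likelihood = mk_loglik(tree, states, q, S),
                converged = FALSE, tree = tree, states = states)
    class(fit) <- "mk_fit"
    return(fit)
  }
  negll <- function(lq) -mk_loglik(tree, states, 10^lq, S)
  opt <- optimize(negll, interval = interval, tol = 1e-8)
  q <- 10^opt$minimum
  conv <- opt$minimum > interval[1L] + 1e-4 && opt$minimum < interval[2L] - 1e-4
  fit <- list(q = q, S = S, log_likelihood = -opt$objective,
              converged = conv, tree = tree, states = states)
  class(fit) <- "mk_fit"
  fit
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Equal-rates Mk model fit (", x$S, " states, ",
      length(x$tree$tip.label), " tips)\n", sep = "")
  cat(sprintf("  rate q         : %.6g\n", x$q))
  cat(sprintf("  log-likelihood : %.4f\n", x$log_likelihood))
  if (!x$converged) cat("  (rate at search boundary; not converged)\n")
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) c(q = object$q)

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 1L, class = "logLik")
}

#' Marginal ancestral state probabilities under the ER Mk model
#'
#' Computes, for every node, the posterior probability of each state given
#' all tip data — the quantity the "rerooting method" produces by placing
#' the root at each node in turn. Because the ER model is reversible with
#' a uniform stationary distribution, a single down pass (conditional
#' likelihood of the data below each node) combined with an up pass
#' (likelihood of the data above) yields the identical marginals in one
#' traversal. Tip rows are the observed indicator vectors.
#'
#' @param fit an `"mk_fit"` object, or a tree (with `states` and `q` then
#'   required).
#' @param states,q,S used when `fit` is a tree.
#' @return a matrix with one row per node (tips first, ape numbering) and
#'   `S` columns; every row sums to 1. Attribute `"tree"` carries the tree.
#' @export
ancestral_marginals <- function(fit, states = NULL, q = NULL, S = 4L) {
  if (inherits(fit, "mk_fit")) {
    tree <- fit$tree; states <- fit$states; q <- fit$q; S <- fit$S
  } else {
    tree <- fit
    if (is.null(states) || is.null(q))
      stop("supply 'states' and 'q' when the first argument is a tree")
  }
  dp <- mk_down_pass(tree, states, q, S)
  tr <- dp$tree
  ntip <- dp$ntip
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L

  # children contributions: for each edge, P(t_e) %*% D_child
  nedge <- nrow(tr$edge)
  PL <- matrix(0, nedge, S)
  for (i in seq_len(nedge))
    PL[i, ] <- er_prob_push(dp$D[tr$edge[i, 2L], ], q, tr$edge.length[i], S)

  U <- matrix(0, ntot, S)
  U[root, ] <- 1
  kids <- split(seq_len(nedge), tr$edge[, 1L])
  # preorder over edges = reverse postorder
  for (i in rev(seq_len(nedge))) {
    par <- tr$edge[i, 1L]
    ch <- tr$edge[i, 2L]
    sibs <- setdiff(kids[[as.character(par)]], i)
    w <- U[par, ]
    for (j in sibs) w <- w * PL[j, ]
    u <- er_prob_push(w, q, tr$edge.length[i], S)  # P symmetric: P^T = P
    s <- sum(u)
    if (s <= 0) stop("zero likelihood encountered during up pass")
    U[ch, ] <- u / s
  }

  M <- dp$D * U
  M <- M / rowSums(M)
  M[seq_len(ntip), ] <- 0
  M[cbind(seq_len(ntip), dp$states)] <- 1
  dimnames(M) <- list(NULL, paste0("state", seq_len(S)))
  attr(M, "tree") <- tree
  attr(M, "q") <- q
  M
}
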