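# Per-node clade keys: the sorted tip-label set below each node, used to
# match nodes across trees that differ in topology (rooted bipartitions).
clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  tr <- if (ntip > 1L) ape::reorder.phylo(tree, "postorder") else tree
  sets <- vector("list", ntot)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
}

#' Summarize ancestral reconstructions over a sample of trees
#'
#' Runs [ancestral_marginals()] on every tree (posterior sample or
#' bootstrap set), matches internal nodes across trees by their rooted
#' bipartition (the frozen set of tip labels they subtend), and reports
#' for every clade seen in at least one tree the mean marginal vector over
#' the trees containing it and its coverage (fraction of trees containing
#' it). This mirrors how node support is summarized on a maximum clade
#' credibility tree.
#'
#' @param trees a list / `"multiPhylo"` of rooted trees sharing one tip set.
#' @param states named tip-state vector (shared across trees).
#' @param S number of states.
#' @param rate_policy `"per-tree-ML"` (default) refits the Mk rate on each
#'   tree; `"fixed"` uses the supplied `q` on all trees (faster on large
#'   samples).
#' @param q rate used when `rate_policy = "fixed"`.
#' @return a `data.frame`: `clade` (tip-set key), `n_tips`, `coverage`,
#'   `p_state1..p_stateS`, sorted by clade size then coverage.
#' @export
summarize_ancestral <- function(trees, states, S = 4L,
                                rate_policy = c("per-tree-ML", "fixed"),
                                q = NULL) {
  rate_policy <- match.arg(rate_policy)
  if (rate_policy == "fixed" && is.null(q))
    stop("rate_policy = 'fixed' requires q")
  if (inherits(trees, "phylo")) trees <- list(trees)
  tipset <- sort(trees[[1L]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), tipset))
      stop("trees do not share a common tip set")
  acc <- new.env(parent = emptyenv())
  for (tr in trees) {
    qk <- if (rate_policy == "fixed") q else fit_mk(tr, states, S)$q
    M <- ancestral_marginals(tr, states = states, q = qk, S = S)
    keys <- clade_keys(tr)
    ntip <- length(tr$tip.label)
    for (v in (ntip + 1L):(ntip + tr$Nnode)) {
      k <- keys[v]
      cur <- acc[[k]]
      if (is.null(cur)) cur <- list(sum = numeric(S), n = 0L)
      acc[[k]] <- list(sum = cur$sum + M[v, ], n = cur$n + 1L)
    }
  }
  ks <- ls(acc)
  out <- data.frame(
    clade = ks,
    n_tips = lengths(strsplit(ks, "|", fixed = TRUE)),
    coverage = vapply(ks, function(k) acc[[k]]$n, 0L) / length(trees),
    stringsAsFactors = FALSE
  )
  P <- t(vapply(ks, function(k) acc[[k]]$sum / acc[[k]]$n, numeric(S)))
  colnames(P) <- paste0("p_state", seq_len(S))
  out <- cbind(out, P)
  rownames(out) <- NULL
  out[order(-out$n_tips, -out$coverage), , drop = FALSE]
}

#' Count inferred character-state changes on a tree
#'
#' Assigns every node its maximum-marginal state and counts edges whose
#' endpoint assignments differ, keyed by (parent state -> child state).
#' Ties at a node are broken toward the already-assigned parent state
#' (processed root-to-tips); a tie at the root goes to the lowest state
#' index. Tip assignments are the observed states.
#'
#' @param marginals matrix from [ancestral_marginals()] (carries the tree).
#' @param tol tie tolerance on the marginal probabilities.
#' @return an object of class `"change_summary"`: list with `changes`
#'   (S x S matrix of counts, rows = parent state), `n_changes`,
#'   `assignments` (per-node states), and `events` (data.frame of changed
#'   edges).
#' @export
count_changes <- function(marginals, tol = 1e-9) {
  tree <- attr(marginals, "tree")
  if (is.null(tree)) stop("marginals must carry their tree (attribute 'tree')")
  S <- ncol(marginals)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  tr <- if (ntip > 1L) ape::reorder.phylo(tree, "postorder") else tree
  parent <- integer(ntot)
  for (i in seq_len(nrow(tr$edge))) parent[tr$edge[i, 2L]] <- tr$edge[i, 1L]
  assign <- integer(ntot)
  root <- ntip + 1L
  pick <- function(v, prefer = NA_integer_) {
    cand <- which(v >= max(v) - tol)
    if (!is.na(prefer) && prefer %in% cand) prefer else min(cand)
  }
  assign[root] <- pick(marginals[root, ])
  for (i in rev(seq_len(nrow(tr$edge)))) { # preorder: parents before children
    ch <- tr$edge[i, 2L]
    assign[ch] <- pick(marginals[ch, ], prefer = assign[tr$edge[i, 1L]])
  }
  changes <- matrix(0L, S, S,
                    dimnames = list(from = paste0("state", seq_len(S)),
                                    to = paste0("state", seq_len(S))))
  ev <- list()
  for (i in seq_len(nrow(tr$edge))) {
    a <- assign[tr$edge[i, 1L]]; b <- assign[tr$edge[i, 2L]]
    if (a != b) {
      changes[a, b] <- changes[a, b] + 1L
      ev[[length(ev) + 1L]] <- data.frame(parent = tr$edge[i, 1L],
                                          child = tr$edge[i, 2L],
                                          from = a, to = b)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(parent = integer(), child = integer(),
                            from = integer(), to = integer())
  out <- list(changes = changes, n_changes = sum(changes),
              assignments = assign, events = events)
  class(out) <- "change_summary"
  out
}

#' @export
print.change_summary <- function(x, ...) {
  cat("Inferred state changes:", x$n_changes, "\n")
  if (x$n_changes > 0) {
    idx <- which(x$changes > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      cat(sprintf("  %d -> %d : %d edge(s)\n", idx[r, 1L], idx[r, 2L],
                  x$changes[idx[r, 1L], idx[r, 2L]]))
  }
  invisible(x)
}

#' Aggregate change counts across a tree sample
#'
#' @param summaries list of `"change_summary"` objects (one per tree).
#' @return list with `mean_changes` (mean total per tree), `mode_changes`
#'   (modal total), `n_possible_changes` (number of distinct from->to
#'   pairs observed in at least one tree), and `pair_mean` (S x S matrix
#'   of mean per-tree counts).
#' @export
summarize_changes <- function(summaries) {
  if (!length(summaries)) stop("no change summaries supplied")
  tot <- vapply(summaries, function(s) s$n_changes, 0L)
  pm <- Reduce(`+`, lapply(summaries, function(s) s$changes)) /
    length(summaries)
  seen <- Reduce(`+`, lapply(summaries, function(s) (s$changes > 0) * 1L))
  tab <- table(tot)
  list(mean_changes = mean(tot),
       mode_changes = as.integer(names(tab)[which.max(tab)]),
       n_possible_changes = sum(seen > 0),
       pair_mean = pm)
}
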