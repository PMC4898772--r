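test_that("summary over identical trees reduces to single-tree marginals", {
  set.seed(14)
  tr <- simulate_yule_tree(6)
  st <- setNames(c(1L, 1L, 2L, 3L, 3L, 3L), tr$tip.label)
  trees <- replicate(10, tr, simplify = FALSE)
  out <- summarize_ancestral(trees, st)
  expect_true(all(out$coverage == 1))
  M <- ancestral_marginals(tr, states = st, q = fit_mk(tr, st)$q)
  keys <- callspace:::clade_keys(tr)
  ntip <- length(tr$tip.label)
  for (v in (ntip + 1L):(ntip + tr$Nnode)) {
    row <- out[out$clade == keys[v], ]
    expect_equal(as.numeric(row[paste0("p_state", 1:4)]),
                 unname(M[v, ]), tolerance = 1e-10)
  }
})

test_that("a disputed clade has coverage 0.5 across two trees", {
  t1 <- read_newick(text = "(((A:1,B:1):1,C:2):1,D:3);")
  t2 <- read_newick(text = "(((A:1,C:1):1,B:2):1,D:3);")
  st <- c(A = 1L, B = 1L, C = 2L, D = 2L)
  out <- summarize_ancestral(list(t1, t2), st, rate_policy = "fixed",
                             q = 0.2)
  expect_equal(out$coverage[out$clade == "A|B"], 0.5)
  expect_equal(out$coverage[out$clade == "A|C"], 0.5)
  expect_equal(out$coverage[out$clade == "A|B|C"], 1)
  expect_equal(out$coverage[out$clade == "A|B|C|D"], 1)
  expect_error(summarize_ancestral(list(t1, read_newick(text = "(A:1,B:1);")),
                                   st), "common tip set")
})

test_that("tree-sample summary matches an independent per-tree average", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  base <- simulate_yule_tree(8)
  st <- setNames(sample(1:4, 8, replace = TRUE), base$tip.label)
  # jitter the posterior-like sample with random NNI moves
  trees <- lapply(1:20, function(i) {
    tr <- base
    if (i > 1) tr <- phangorn::rNNI(base, moves = sample(1:2, 1L))
    tr
  })
  out <- summarize_ancestral(trees, st, rate_policy = "fixed", q = 0.3)
  # loop oracle: average the root rows by hand over all trees
  rootkey <- paste(sort(base$tip.label), collapse = "|")
  acc <- numeric(4L)
  for (tr in trees) {
    M <- ancestral_marginals(tr, states = st, q = 0.3)
    acc <- acc + M[length(tr$tip.label) + 1L, ]
  }
  expect_equal(as.numeric(out[out$clade == rootkey,
                              paste0("p_state", 1:4)]),
               unname(acc / length(trees)), tolerance = 1e-10)
})

test_that("change counting: no variation means no changes", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  M <- ancestral_marginals(tr, states = c(A = 2L, B = 2L, C = 2L, D = 2L),
                           q = 0.01)
  cc <- count_changes(M)
  expect_equal(cc$n_changes, 0L)
})

test_that("a lone derived tip yields exactly one pendant-edge change", {
  # one three-note tip among four-note relatives: the only inferable
  # change is 4 -> 3 on its pendant edge
  tr <- read_newick(
    text = "(((Pan:1,T1:1):1,(T2:1,T3:1):1):1,(T4:2,T5:2):1);")
  st <- c(Pan = 3L, T1 = 4L, T2 = 4L, T3 = 4L, T4 = 4L, T5 = 4L)
  M <- ancestral_marginals(tr, states = st, q = 0.02)
  cc <- count_changes(M)
  expect_equal(cc$n_changes, 1L)
  expect_equal(cc$changes[4L, 3L], 1L)
  expect_equal(cc$events$child, which(tr$tip.label == "Pan"))
})

test_that("counted changes recover simulated history at low rate", {
  set.seed(71)
  hits <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    tr <- simulate_yule_tree(6)
    sim <- simulate_mk_character(tr, q = 0.05, S = 4L, root_state = 4L)
    M <- ancestral_marginals(tr, states = sim$tip_states, q = 0.05)
    cc <- count_changes(M)
    if (cc$n_changes == nrow(sim$changes)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("change summaries aggregate across trees", {
  tr <- read_newick(
    text = "(((Pan:1,T1:1):1,(T2:1,T3:1):1):1,(T4:2,T5:2):1);")
  st <- c(Pan = 3L, T1 = 4L, T2 = 4L, T3 = 4L, T4 = 4L, T5 = 4L)
  M <- ancestral_marginals(tr, states = st, q = 0.02)
  agg <- summarize_changes(list(count_changes(M), count_changes(M)))
  expect_equal(agg$mean_changes, 1)
  expect_equal(agg$mode_changes, 1L)
  expect_equal(agg$n_possible_changes, 1L)
  expect_equal(agg$pair_mean[4L, 3L], 1)
})

test_that("marginals agree with the reference rerooting implementation", {
  skip_if_not_installed("phytools")
  set.seed(88)
  tr <- ape::rtree(7)
  st <- setNames(sample(1:3, 7, replace = TRUE), tr$tip.label)
  while (length(unique(st)) < 2)
    st <- setNames(sample(1:3, 7, replace = TRUE), tr$tip.label)
  q <- 0.4
  M <- ancestral_marginals(tr, states = st, q = q, S = 3L)
  ref <- phytools::rerootingMethod(tr,
                                   setNames(as.character(st), names(st)),
                                   model = matrix(c(0, 1, 1, 1, 0, 1,
                                                    1, 1, 0), 3L),
                                   fixedQ = q *
                                     (matrix(1, 3L, 3L) - diag(3L) * 1) -
                                     diag(2L * q, 3L))
  ntip <- length(tr$tip.label)
  expect_lt(max(abs(M[(ntip + 1L):(ntip + tr$Nnode), ] -
                      ref$marginal.anc[as.character((ntip + 1L):(ntip +
                                                                   tr$Nnode)), ])),
            1e-6)
})
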