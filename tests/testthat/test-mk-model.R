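test_that("ER transition matrix limits and closed form", {
  S <- 4L
  expect_equal(er_transition_probability(0.7, 0, S), diag(S))
  P <- er_transition_probability(1, 1e6, S)
  expect_true(all(abs(P - 0.25) < 1e-12))
  # q=1, t=0.5, S=4: frozen values from the generic expm oracle
  P <- er_transition_probability(1, 0.5, 4L)
  expect_equal(unname(diag(P)), rep(0.3515014624, 4L), tolerance = 1e-9)
  expect_equal(P[1L, 2L], 0.2161661792, tolerance = 1e-9)
  expect_error(er_transition_probability(-1, 1), "q must be")
  expect_error(er_transition_probability(1, -1), "t must be")
})

test_that("closed form matches a generic matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(101)
  for (i in 1:100) {
    q <- runif(1, 0, 3)
    t <- runif(1, 0, 5)
    S <- sample(2:6, 1L)
    expect_lt(max(abs(er_transition_probability(q, t, S) -
                        enum_er_matrix(q, t, S))), 1e-10)
  }
})

test_that("Chapman-Kolmogorov holds for the ER family", {
  set.seed(7)
  for (i in 1:100) {
    q <- runif(1, 0, 2); s <- runif(1, 0, 3); t <- runif(1, 0, 3)
    S <- sample(2:5, 1L)
    lhs <- er_transition_probability(q, s, S) %*%
      er_transition_probability(q, t, S)
    expect_lt(max(abs(lhs - er_transition_probability(q, s + t, S))), 1e-10)
  }
})

test_that("pruning likelihood: degenerate and closed-form cases", {
  single <- read_newick(text = "(A:1);")
  expect_equal(mk_loglik(single, c(A = 2L), q = 0.7, S = 4L), log(1 / 4))

  two <- read_newick(text = "(A:1,B:1);")
  q <- 0.5; S <- 2L
  P <- er_transition_probability(q, 1, S)
  # sum over the 2 root states of prior * P(root->A) * P(root->B)
  byhand <- log(sum(vapply(1:2, function(r)
    0.5 * P[r, 1L] * P[r, 2L], 0)))
  expect_equal(mk_loglik(two, c(A = 1L, B = 2L), q, S), byhand,
               tolerance = 1e-12)
})

test_that("pruning and marginals equal exhaustive enumeration", {
  skip_if_not_installed("Matrix")
  set.seed(33)
  for (i in 1:50) {
    n <- sample(3:6, 1L)
    tr <- random_tree(n)
    st <- random_states(tr)
    q <- runif(1, 0.05, 1)
    oracle <- enum_mk(tr, st, q)
    expect_equal(mk_loglik(tr, st, q), oracle$loglik, tolerance = 1e-10)
    M <- ancestral_marginals(tr, states = st, q = q)
    expect_lt(max(abs(unclass(M)[, ] - oracle$marginals)), 1e-10)
  }
})

test_that("likelihood is invariant to root placement (ER reversibility)", {
  set.seed(5)
  for (i in 1:10) {
    tr <- random_tree(6)
    st <- random_states(tr)
    q <- 0.3
    base <- mk_loglik(tr, st, q)
    node <- sample((length(tr$tip.label) + 2L):(length(tr$tip.label) +
                                                  tr$Nnode), 1L)
    rerooted <- ape::root(tr, node = node, resolve.root = TRUE)
    expect_equal(mk_loglik(rerooted, st, q), base, tolerance = 1e-10)
  }
})

test_that("marginals are invariant to child-order shuffling", {
  set.seed(9)
  tr <- random_tree(6)
  st <- random_states(tr)
  M1 <- ancestral_marginals(tr, states = st, q = 0.4)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  M2 <- ancestral_marginals(rot, states = st, q = 0.4)
  # match nodes between orderings through their clade tip sets
  k1 <- callspace:::clade_keys(tr)
  k2 <- callspace:::clade_keys(rot)
  expect_lt(max(abs(unclass(M1)[match(k2, k1), ] - unclass(M2)[, ])), 1e-10)
})

test_that("marginal reconstruction limiting cases", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # identical tips, tiny rate: internal nodes nearly certain
  M <- ancestral_marginals(tr, states = c(A = 3L, B = 3L, C = 3L, D = 3L),
                           q = 0.01)
  expect_true(all(M[5:7, 3L] > 0.99))
  # two-tip symmetric conflict: root marginal (0.5, 0.5)
  two <- read_newick(text = "(A:1,B:1);")
  M2 <- ancestral_marginals(two, states = c(A = 1L, B = 2L), q = 0.5, S = 2L)
  expect_equal(unname(M2[3L, ]), c(0.5, 0.5), tolerance = 1e-12)
  # tips are indicator rows
  expect_equal(unname(M2[1L, ]), c(1, 0))
})

test_that("rate fitting finds a local maximum and handles constant data", {
  set.seed(21)
  tr <- simulate_yule_tree(40, 1)
  sim <- simulate_mk_character(tr, q = 0.5, S = 4L, root_state = 2L)
  f <- fit_mk(tr, sim$tip_states)
  expect_true(f$converged)
  ll <- function(q) mk_loglik(tr, sim$tip_states, q)
  expect_gte(f$log_likelihood, ll(f$q * 1.1) - 1e-8)
  expect_gte(f$log_likelihood, ll(f$q * 0.9) - 1e-8)
  expect_gte(f$log_likelihood, ll(f$q * 2) - 1e-8)
  expect_gte(f$log_likelihood, ll(f$q / 2) - 1e-8)

  const <- fit_mk(tr, setNames(rep(3L, 40), tr$tip.label))
  expect_false(const$converged)
  expect_equal(const$q, 1e-6)
})

test_that("mk_fit methods behave like a model object", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  f <- fit_mk(tr, c(A = 1L, B = 2L, C = 2L))
  expect_named(coef(f), "q")
  expect_s3_class(logLik(f), "logLik")
  expect_output(print(f), "Equal-rates Mk")
  expect_lte(f$log_likelihood, 0)
})
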