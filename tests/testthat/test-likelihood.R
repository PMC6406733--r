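test_that("transition probabilities follow the 3-state closed form", {
  expect_equal(mk_transition_prob(0), diag(3))
  expect_equal(mk_transition_prob(50), matrix(1 / 3, 3, 3), tolerance = 1e-8)
  b <- seq(0, 5, by = 0.25)
  psame <- vapply(b, function(x) mk_transition_prob(x)[1, 1], numeric(1))
  expect_true(all(diff(psame) < 0))
  for (x in c(0.1, 1, 7))
    expect_equal(rowSums(mk_transition_prob(x)), rep(1, 3))
  expect_error(mk_transition_prob(-0.1), "non-negative")
})

test_that("two identical taxa have the closed-form likelihood", {
  cm <- char_matrix(matrix(c(2L, 2L), 2, 1, dimnames = list(c("x", "y"), NULL)))
  b <- 0.8
  tr <- read_newick(text = sprintf("(x:%g,y:%g);", b / 2, b / 2))
  expect_equal(tree_log_likelihood(tr, cm),
               log((1 / 3) * (1 / 3 + (2 / 3) * exp(-1.5 * b))))
})

test_that("pattern probabilities sum to one over all leaf-state patterns", {
  set.seed(51)
  for (n in 4:5) {
    tr <- random_tree(n)
    pats <- as.matrix(expand.grid(rep(list(0:2), n)))
    tot <- sum(apply(pats, 1, function(p) {
      cm <- char_matrix(matrix(as.integer(p), n, 1,
                               dimnames = list(LETTERS[1:n], NULL)))
      exp(tree_log_likelihood(tr, cm))
    }))
    expect_equal(tot, 1, tolerance = 1e-8)
  }
})

test_that("pruning equals brute-force summation over internal states", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(4:5, 1)
    tr <- random_tree(n)
    cm <- random_cm(n, 6)
    expect_equal(tree_log_likelihood(tr, cm), oracle_loglik(tr, cm),
                 tolerance = 1e-12)
  }
})

test_that("likelihood is invariant to rerooting and matches phangorn", {
  set.seed(53)
  tr <- random_tree(6)
  cm <- random_cm(6, 15)
  base <- tree_log_likelihood(tr, cm)
  for (og in c("A", "D", "F"))
    expect_equal(tree_log_likelihood(root_at(tr, og), cm), base, tolerance = 1e-8)
  pd <- phangorn::phyDat(matrix(as.character(unclass(cm)), 6,
                                dimnames = dimnames(cm)),
                         type = "USER", levels = c("0", "1", "2"))
  expect_equal(base, phangorn::pml(tr, pd)$logLik, tolerance = 1e-8)
})

test_that("missing branch lengths are refused", {
  tr <- read_newick(text = "((A,B),(C,D));")
  expect_error(tree_log_likelihood(tr, random_cm(4, 3)), "missing branch length")
})

test_that("branch-length optimization finds analytic optima", {
  # all-constant data: no change is most likely, all lengths collapse to 0
  const <- char_matrix(matrix(1L, 4, 5, dimnames = list(LETTERS[1:4], NULL)))
  opt <- optimize_branch_lengths(read_newick(text = "((A,B),(C,D));"), const)
  expect_equal(opt$edge.length, rep(0, 6))

  # two taxa differing in fraction f < 2/3: optimum solves P_same(b) = 1 - f
  cm <- char_matrix(matrix(c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 0L, 1L, 0L), 2, 5,
                           dimnames = list(c("x", "y"), NULL)))
  f <- mean(unclass(cm)[1, ] != unclass(cm)[2, ])
  opt2 <- optimize_branch_lengths(read_newick(text = "(x:0.1,y:0.1);"), cm)
  b_closed <- -log((1 - f - 1 / 3) / (2 / 3)) / 1.5
  expect_equal(sum(opt2$edge.length), b_closed, tolerance = 1e-4)

  # duplicating every character scales the likelihood but moves no optimum
  cm2 <- char_matrix(cbind(unclass(cm), unclass(cm)))
  opt3 <- optimize_branch_lengths(read_newick(text = "(x:0.1,y:0.1);"), cm2)
  expect_equal(sum(opt3$edge.length), sum(opt2$edge.length), tolerance = 1e-4)
  expect_equal(attr(opt3, "loglik"), 2 * attr(opt2, "loglik"), tolerance = 1e-6)
})

test_that("ML search resolves clean quartet signal and ranks topologies sensibly", {
  m <- matrix(rep(c(2L, 2L, 0L, 0L), 25), 4, 25,
              dimnames = list(LETTERS[1:4], NULL))
  res <- ml_search(char_matrix(m), "exhaustive")
  expect_equal(tree_splits(res$tree), "C|D")

  # an uninformative constant character cannot separate topologies
  const <- char_matrix(matrix(2L, 4, 1, dimnames = list(LETTERS[1:4], NULL)))
  lls <- vapply(phangorn::allTrees(4, rooted = FALSE, tip.label = LETTERS[1:4]),
                function(tr) {
                  tr$edge.length <- rep(0.3, nrow(tr$edge))
                  tree_log_likelihood(tr, const)
                }, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-6)

  expect_error(ml_search(random_cm(8, 5), "exhaustive"), "nni_from_nj")
})

test_that("ML and parsimony agree on strong homoplasy-free signal", {
  m <- cbind(matrix(rep(c(2L, 2L, 0L, 0L, 0L, 0L), 10), 6),
             matrix(rep(c(1L, 1L, 1L, 1L, 2L, 2L), 10), 6))
  rownames(m) <- LETTERS[1:6]
  cm <- char_matrix(m)
  mp <- parsimony_search(cm, "exhaustive")
  ml <- ml_search(cm, "nni_from_nj")
  expect_equal(rf_distance(mp$trees[[1L]], ml$tree), 0L)
})

test_that("ML recovers the generating topology from simulated characters", {
  set.seed(55)
  gen <- random_tree(6)
  # moderate lengths: long branches saturate a 3-state model (P_same -> 1/3)
  gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 0.4)
  hits <- 0L
  n_rep <- 8L
  for (i in seq_len(n_rep)) {
    cm <- simulate_characters(gen, 300)
    fit <- ml_search(cm, "nni_from_nj")
    hits <- hits + (rf_distance(fit$tree, gen) == 0L)
  }
  expect_gte(hits, n_rep - 1L)
})
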