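test_that("major clades are the root children after outgroup pruning", {
  # 9-time-point caterpillar rooted at t0
  nwk <- paste0("((((((((t8:1,t7:1):1,t6:1):1,t5:1):1,t4:1):1,t3:1):1,",
                "t2:1):1,t1:1):1,t0:1);")
  tr <- read_newick(text = nwk)
  sp <- split_major_clades(tr, exclude_outgroup = TRUE, outgroup = "t0")
  expect_true(setequal(c(sp$clade_a, sp$clade_b), sprintf("t%d", 1:8)))
  expect_true("t1" %in% sp$clade_b && length(sp$clade_b) == 1L ||
              "t1" %in% sp$clade_a && length(sp$clade_a) == 1L)

  bal <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  spb <- split_major_clades(bal)
  expect_true(setequal(spb$clade_a, c("A", "B")) || setequal(spb$clade_a, c("C", "D")))

  expect_error(split_major_clades(ape::unroot(tr)), "rooted")
})

test_that("the defining edge's bootstrap support is carried into the split", {
  tr <- read_newick(text = "((A:1,B:1)95:1,(C:1,D:1)88:1);")
  sp <- split_major_clades(tr)
  expect_true(sp$support %in% c(88L, 95L))
})

test_that("Welch mode flags clade-separated genes and matches a BH oracle", {
  set.seed(71)
  vals <- matrix(rnorm(50 * 8, 8, 0.3), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  vals[1:5, 5:8] <- vals[1:5, 5:8] + 4      # strong separation for g01-g05
  vals[50, ] <- 6                            # perfectly constant gene
  em <- expr_matrix(vals, log2_scale = TRUE)
  sp <- structure(list(clade_a = sprintf("s%d", 1:4),
                       clade_b = sprintf("s%d", 5:8), support = NA_integer_),
                  class = "clade_split")
  dg <- differential_genes(em, sp, "welch_bh")
  expect_true(all(dg$significant[1:5]))
  expect_equal(dg$statistic[50], 0)
  expect_equal(dg$p[50], 1)
  expect_equal(dg$q, oracle_bh(dg$p))
  expect_true(all(dg$q >= dg$p - 1e-12))
  expect_equal(dg$direction[1], "up_in_b")

  small <- structure(list(clade_a = "s1", clade_b = sprintf("s%d", 2:8),
                          support = NA_integer_), class = "clade_split")
  expect_error(differential_genes(em, small, "welch_bh"), "synapomorphy")
})

test_that("synapomorphy mode requires within-clade uniformity and between-clade difference", {
  m <- rbind(s1 = c(2L, 2L, 1L), s2 = c(2L, 0L, 1L), s3 = c(0L, 1L, 1L),
             s4 = c(0L, 2L, 1L))
  colnames(m) <- c("gA", "gB", "gC")
  cm <- char_matrix(m)
  sp <- structure(list(clade_a = c("s1", "s2"), clade_b = c("s3", "s4"),
                       support = NA_integer_), class = "clade_split")
  dg <- differential_genes(NULL, sp, "synapomorphy", cm = cm)
  expect_equal(dg$significant, c(TRUE, FALSE, FALSE))  # gC constant, gB mixed
  expect_equal(dg$direction[1], "up_in_a")
})

test_that("permuted clade labels yield a near-nominal false-positive rate", {
  sim <- simulate_time_course(n_genes = 500, signal_fraction = 0, seed = 72)
  em <- sim$expr
  ids <- colnames(em$values)
  set.seed(73)
  rates <- replicate(20, {
    grp <- sample(ids)
    sp <- structure(list(clade_a = grp[1:13], clade_b = grp[14:27],
                         support = NA_integer_), class = "clade_split")
    mean(differential_genes(em, sp, "welch_bh")$significant)
  })
  expect_lte(mean(rates), 0.05)
})

test_that("hypergeometric tail probabilities are exact", {
  expect_equal(hypergeometric_p(3, 5, 3, 10), 10 / 120)
  expect_equal(hypergeometric_p(0, 5, 3, 10), 1)
  expect_equal(hypergeometric_p(4, 4, 10, 10), 1)  # query is the whole universe
  set.seed(74)
  for (i in 1:20) {
    U <- sample(10:60, 1)
    s <- sample(1:(U - 1), 1)
    q <- sample(1:(U - 1), 1)
    ov <- sample(0:min(s, q), 1)
    expect_equal(hypergeometric_p(ov, s, q, U), oracle_hyper(ov, s, q, U))
  }
  expect_error(hypergeometric_p(5, 3, 10, 10), "inconsistent")
})

test_that("permutation-adjusted p-values match an independent Monte-Carlo oracle", {
  set.seed(75)
  uni <- sprintf("G%02d", 1:50)
  sets <- list(A = uni[1:10], B = uni[11:25], C = uni[30:34])
  coll <- gene_set_collection(sets)
  query <- c(uni[1:6], uni[40:43])
  res <- enrichment(query, coll, uni, n_perm = 2000, seed = 76)
  oracle <- oracle_adjusted_p(query, sets, uni, n_rep = 10000, seed = 77)
  for (s in res$set)
    expect_equal(res$adj_p[res$set == s], unname(oracle[s]), tolerance = 0.03)
  # adjusted p is monotone in raw p
  expect_true(all(diff(res$adj_p[order(res$p)]) >= 0))
})

test_that("degenerate enrichment inputs behave as the definition demands", {
  uni <- sprintf("G%02d", 1:20)
  coll <- gene_set_collection(list(ALL = uni))
  res <- enrichment(uni, coll, uni, n_perm = 50, seed = 1)
  expect_equal(res$p, 1)
  expect_equal(res$adj_p, 1)
  expect_error(enrichment(character(0), coll, uni), "empty query")
  expect_error(enrichment("NOT_THERE", coll, uni), "outside the universe")
})

test_that("the family-wise adjusted p is super-uniform under the null", {
  set.seed(78)
  uni <- sprintf("G%02d", 1:50)
  coll <- gene_set_collection(list(A = uni[1:10], B = uni[11:25], C = uni[30:34]))
  hits <- replicate(200, {
    q <- sample(uni, 8)
    min(enrichment(q, coll, uni, n_perm = 400, seed = NULL)$adj_p) <= 0.05
  })
  expect_lte(mean(hits), 0.07)
})
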