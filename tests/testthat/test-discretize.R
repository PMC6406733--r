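make_ratio <- function(m, outgroup = "t0") {
  structure(m, class = c("ratio_matrix", "matrix"), outgroup = outgroup)
}

test_that("log ratios subtract the outgroup mean gene-wise", {
  vals <- matrix(c(8, 7, 9, 8, 9, 8), 2, 3,
                 dimnames = list(c("g1", "g2"), c("o1", "o2", "s1")))
  meta <- data.frame(sample_id = c("o1", "o2", "s1"), time_rank = c(0, 0, 1),
                     replicate = c("r1", "r2", "r1"),
                     is_outgroup = c(TRUE, TRUE, FALSE))
  em <- expr_matrix(vals, meta, log2_scale = TRUE)
  r <- log_ratio_matrix(em)
  # g1: outgroup reps 8 and 9 -> mean 8.5, sample 9 -> +0.5
  # g2: outgroup reps 7 and 8 -> mean 7.5, sample 8 -> +0.5
  expect_equal(unname(r[, "s1"]), c(0.5, 0.5))

  # sample equal to the outgroup mean -> all-zero ratios
  vals2 <- vals; vals2[, "s1"] <- rowMeans(vals2[, c("o1", "o2")])
  em2 <- expr_matrix(vals2, meta, log2_scale = TRUE)
  expect_equal(unname(log_ratio_matrix(em2)[, "s1"]), c(0, 0))

  em3 <- expr_matrix(vals, log2_scale = TRUE)
  expect_error(log_ratio_matrix(em3), "no outgroup designated")
})

test_that("discretization maps ratios to the three states at the threshold", {
  r <- make_ratio(matrix(c(1.2, -1.3, 0.2), 1, 3,
                         dimnames = list("g1", c("s1", "s2", "s3"))))
  cm <- discretize(r, tau = 1, add_outgroup = FALSE)
  expect_equal(unname(unclass(cm)[, "g1"]), c(2L, 0L, 1L))

  cm2 <- discretize(r, tau = 5, add_outgroup = FALSE)
  expect_true(all(unclass(cm2) == 1L))

  expect_error(discretize(r, tau = 0), "positive")
  expect_error(discretize(r, tau = -1), "positive")
})

test_that("raising the threshold never increases the non-constant cell count", {
  set.seed(5)
  r <- make_ratio(matrix(rnorm(200), 20, 10,
                         dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10))))
  taus <- c(0.1, 0.5, 1, 1.5, 2.5)
  counts <- vapply(taus, function(tau)
    sum(unclass(discretize(r, tau, add_outgroup = FALSE)) != 1L), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("informative-site counting follows the two-states-twice rule", {
  cm1 <- char_matrix(matrix(c(2L, 2L, 0L, 0L, 1L), 5, 1,
                            dimnames = list(LETTERS[1:5], NULL)))
  expect_equal(count_informative(cm1), 1L)

  cm2 <- char_matrix(matrix(c(2L, 0L, 1L, 1L, 1L), 5, 1,
                            dimnames = list(LETTERS[1:5], NULL)))
  expect_equal(count_informative(cm2), 0L)

  cm3 <- char_matrix(matrix(1L, 5, 8, dimnames = list(LETTERS[1:5], NULL)))
  expect_equal(count_informative(cm3), 0L)

  cm4 <- char_matrix(matrix(0:2, 3, 4, dimnames = list(LETTERS[1:3], NULL)))
  expect_error(count_informative(cm4), ">= 4 taxa")
})

test_that("informative count matches a per-character histogram oracle and is order-invariant", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    cm <- random_cm(n, sample(5:20, 1))
    oracle <- sum(apply(unclass(cm), 2, function(col)
      sum(table(col) >= 2) >= 2))
    expect_identical(count_informative(cm), oracle)
    perm <- char_matrix(unclass(cm)[sample(n), sample(ncol(cm)), drop = FALSE])
    expect_identical(count_informative(perm), oracle)
  }
})

test_that("threshold search scans the grid and breaks ties toward the smallest tau", {
  # worked 2-gene x 4-taxon example
  r <- make_ratio(matrix(c(1.2, 1.1, -1.3, -1.2,
                           0.2, 0.3, -0.2, -0.3), 4, 2,
                         dimnames = list(sprintf("s%d", 1:4), c("g1", "g2")),
                         byrow = FALSE) |> t())
  res <- select_threshold(r, grid = c(0.15, 1.0), include_outgroup = FALSE)
  expect_equal(res$informative, c(2L, 1L))
  expect_equal(res$tau, 0.15)

  rz <- make_ratio(matrix(0, 2, 4, dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4))))
  resz <- select_threshold(rz, grid = c(0.3, 0.9), include_outgroup = FALSE)
  expect_equal(resz$informative, c(0L, 0L))
  expect_equal(resz$tau, 0.3)

  res1 <- select_threshold(r, grid = 0.7, include_outgroup = FALSE)
  expect_equal(res1$tau, 0.7)

  expect_error(select_threshold(r, grid = numeric(0)), "non-empty")
  expect_error(select_threshold(r, grid = c(-1, 1)), "positive")
})

test_that("the informative count is not monotone in tau, so the whole grid matters", {
  # g1 informative only at the larger threshold (constant pair appears);
  # g2/g3 informative only at the smaller one
  m <- rbind(g1 = c(1, 1, 0.5, 0.5),
             g2 = c(0.4, 0.4, -0.4, -0.4),
             g3 = c(1, 1, 0.5, 0.5))
  colnames(m) <- sprintf("s%d", 1:4)
  r <- make_ratio(m)
  res <- select_threshold(r, grid = c(0.3, 0.7), include_outgroup = FALSE)
  expect_equal(res$informative, c(1L, 2L))  # count rises with tau here
  expect_equal(res$tau, 0.7)
})
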