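test_that("NODF hits its analytic endpoints", {
  expect_equal(nodf(staircase_matrix(13))$value, 1)
  expect_equal(nodf(staircase_matrix(5))$value, 1)
  # all rows and columns tie on marginals: decreasing fill zeroes every pair
  expect_equal(nodf(matrix(1, 4, 4))$value, 0)
  expect_equal(nodf(rbind(c(1, 0), c(1, 0), c(1, 0)))$value, 0)
  expect_equal(nodf(staircase_matrix(4), scale = "percent")$value, 100)
  expect_error(nodf(matrix(2, 3, 3)), "binary")
  expect_error(nodf(matrix(1, 1, 5)), "at least 2")
})

test_that("NODF equals the literal pair-enumeration oracle", {
  withr::with_seed(13, {
    for (i in 1:100) {
      nr <- sample(2:8, 1); nc <- sample(2:8, 1)
      m <- random_binary_matrix(nr, nc, runif(1, 0.2, 0.8))
      expect_equal(nodf(m)$value, nodf_oracle(m))
    }
  })
})

test_that("NODF agrees with vegan's implementation", {
  withr::with_seed(14, {
    for (i in 1:20) {
      m <- random_binary_matrix(sample(3:10, 1), sample(3:10, 1), 0.5)
      # avoid empty rows/cols: conventions for them differ across programs
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      ref <- unname(vegan::nestednodf(m, order = TRUE)$statistic["NODF"]) / 100
      expect_equal(nodf(m)$value, ref, tolerance = 1e-12)
    }
  })
})

test_that("NODF is invariant to permutations, transpose and degree sorting", {
  withr::with_seed(15, {
    for (i in 1:20) {
      m <- random_binary_matrix(sample(3:8, 1), sample(3:8, 1), 0.5)
      v <- nodf(m)$value
      expect_equal(nodf(t(m))$value, v)
      perm <- m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
      expect_equal(nodf(perm)$value, v)
      expect_equal(nodf(degree_sort(m))$value, v)
    }
  })
})

test_that("degree_sort orders margins decreasingly and is idempotent", {
  m <- infection_matrix(rbind(c(0, 1, 0), c(1, 1, 1), c(1, 1, 0)),
                        host_ids = c("a", "b", "c"), virus_ids = c("x", "y", "z"))
  s <- degree_sort(m)
  expect_true(all(diff(rowSums(s)) <= 0))
  expect_true(all(diff(colSums(s)) <= 0))
  expect_identical(unclass(degree_sort(s)), unclass(s))
  expect_equal(rownames(s)[1], "b")
})

test_that("Qb matches hand evaluation and the formula oracle", {
  # perfect 2-block 4x4: within-module cells contribute (1 - 2*2/8) each
  block <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  part <- list(rows = c(1, 1, 2, 2), cols = c(1, 1, 2, 2))
  expect_equal(qb(block, part)$value, 0.5)
  # one module scores exactly zero on any matrix
  withr::with_seed(16, {
    for (i in 1:10) {
      m <- random_binary_matrix(sample(3:7, 1), sample(3:7, 1), 0.5)
      if (sum(m) == 0) next
      one <- list(rows = rep(1, nrow(m)), cols = rep(1, ncol(m)))
      expect_equal(qb(m, one)$value, 0)
      rows <- sample(1:3, nrow(m), replace = TRUE)
      cols <- sample(1:3, ncol(m), replace = TRUE)
      expect_equal(qb(m, list(rows = rows, cols = cols))$value,
                   qb_oracle(m, rows, cols))
    }
  })
  expect_error(qb(matrix(0, 3, 3), part), "empty")
  expect_error(qb(block, list(rows = c(1, 2), cols = c(1, 1, 2, 2))), "dimensions")
})

test_that("module detection recovers planted blocks and degenerate cases", {
  block <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  p <- detect_modules(block)
  expect_equal(p$n_modules, 2)
  expect_equal(p$qb, 0.5)
  expect_equal(p$rows[1], p$rows[2])
  expect_equal(p$rows[1], p$cols[1])
  expect_true(p$rows[1] != p$rows[3])

  ones <- matrix(1, 3, 4)
  p1 <- detect_modules(ones)
  expect_equal(p1$n_modules, 1)
  expect_equal(p1$qb, 0)

  # never below the trivial partition
  withr::with_seed(17, {
    for (i in 1:20) {
      m <- random_binary_matrix(sample(3:8, 1), sample(3:8, 1), runif(1, 0.2, 0.8))
      if (sum(m) == 0) next
      expect_gte(detect_modules(m)$qb, 0)
    }
  })
})

test_that("brute force finds forced optima and guards its size", {
  ident <- diag(2)
  p <- brute_force_modules(ident)
  expect_equal(p$n_modules, 2)
  expect_equal(p$rows[1], p$cols[1])
  expect_equal(p$rows[2], p$cols[2])
  expect_equal(brute_force_modules(ident, max_modules = 1)$qb, 0)
  expect_error(brute_force_modules(matrix(1, 7, 6)), "12")
})

test_that("the spectral detector reaches near-optimal modularity on small matrices", {
  withr::with_seed(18, {
    for (i in 1:15) {
      nr <- sample(3:6, 1); nc <- sample(3:6, 1)
      m <- random_binary_matrix(nr, nc, runif(1, 0.25, 0.6))
      if (sum(m) == 0 || nr + nc > 12) next
      opt <- brute_force_modules(m, max_modules = 3)$qb
      got <- detect_modules(m)$qb
      if (opt > 0) expect_gte(got, 0.95 * opt) else expect_gte(got, 0)
    }
  })
})
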