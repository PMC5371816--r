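test_that("pearson matches the reference implementation to 1e-10", {
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- rnorm(20); y <- 0.3 * x + rnorm(20)
      mine <- pearson(x, y)
      ref <- stats::cor.test(x, y)
      expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter))
    }
  })
})

test_that("pearson handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson(x, -x)$statistic, -1)
  expect_equal(pearson(x, 2 * x + 1)$p, 0)
  expect_error(pearson(x, rep(1, 10)), "constant")
  expect_error(pearson(x, 1:9), "equal length")
  # symmetry
  withr::with_seed(5, { a <- rnorm(12); b <- rnorm(12) })
  expect_equal(pearson(a, b)$statistic, pearson(b, a)$statistic)
})

test_that("one-way ANOVA matches the reference implementation to 1e-10", {
  withr::with_seed(6, {
    for (i in 1:5) {
      g <- list(rnorm(8), rnorm(6, 0.5), rnorm(7, 1))
      mine <- one_way_anova(g)
      d <- data.frame(y = unlist(g), grp = factor(rep(1:3, times = lengths(g))))
      ref <- stats::anova(stats::lm(y ~ grp, data = d))
      expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
      expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
      expect_equal(mine$df, ref$Df)
    }
  })
})

test_that("ANOVA identities and invariances hold", {
  withr::with_seed(7, { a <- rnorm(9); b <- rnorm(9, 1) })
  # two groups: F equals the square of the pooled-variance t statistic
  f <- one_way_anova(list(a, b))$statistic
  t2 <- unname(stats::t.test(a, b, var.equal = TRUE)$statistic)^2
  expect_equal(f, t2, tolerance = 1e-12)
  # identical group means with nonzero spread give F = 0
  expect_equal(one_way_anova(list(c(1, 3), c(3, 1)))$statistic, 0)
  # shift and positive rescale leave F unchanged
  g <- list(a, b, rnorm(5))
  f0 <- one_way_anova(g)$statistic
  expect_equal(one_way_anova(lapply(g, function(x) x + 7))$statistic, f0)
  expect_equal(one_way_anova(lapply(g, function(x) x * 3.5))$statistic, f0)
  expect_error(one_way_anova(list(a)), "two groups")
  expect_error(one_way_anova(list(a, 1)), "two values")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "identical")
})

test_that("ANOVA type-I error is nominal under the null", {
  rejections <- withr::with_seed(8, {
    vapply(seq_len(2000), function(i) {
      g <- list(rnorm(6), rnorm(6), rnorm(6))
      one_way_anova(g)$p < 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(rate, 0.05 - ci_half)
  expect_lt(rate, 0.05 + ci_half)
})

test_that("isolation-period split assigns the cutoff year to the younger group", {
  md <- tibble::tibble(
    strain_id = c("a", "b", "c", "d"), role = "host",
    isolation_year = c(2005L, 2009L, 2012L, NA), origin = NA)
  sp <- split_by_year(md, 2009)
  expect_equal(sp$older, "a")
  expect_equal(sp$younger, c("b", "c"))
  expect_equal(sp$unknown, "d")

  all_na <- md; all_na$isolation_year <- NA
  expect_warning(sp2 <- split_by_year(all_na), "empty")
  expect_length(sp2$older, 0)
  expect_length(sp2$younger, 0)
  expect_equal(sp2$unknown, md$strain_id)
})

test_that("a planted viral-production shift across the cutoff year is detected", {
  sim <- simulate_experiment(sim_config(young_burst_fold = 6, seed = 12))
  ph <- phenotype_table(sim$counts)
  scr <- screen(ph, sim$metadata, k = 5)
  row <- scr[scr$comparison == "maxVp_by_year", ]
  expect_lt(row$p, 0.05)
})

test_that("the screen battery reports every comparison with valid statistics", {
  sim <- default_sim()
  ph <- phenotype_table(sim$counts)
  scr <- screen(ph, sim$metadata, k = 5)
  expect_setequal(
    scr$comparison,
    c("R1_vs_mu", "R2_vs_mu", "Vp_vs_R1", "maxVp_vs_R2", "Vp_vs_mu",
      "generalist_vs_specialist_Vp", "maxVp_by_year", "mu_by_year",
      "R1_by_year", "R2_by_year"))
  expect_true(all(scr$p >= 0 & scr$p <= 1))
  expect_true(all(abs(scr$statistic[scr$test == "pearson"]) <= 1))
  expect_true(all(scr$statistic[scr$test == "anova"] >= 0))
})
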