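test_that("growth rate matches the exponential-phase formula", {
  expect_equal(growth_rate(1e5, 1e5, 3), 0)
  expect_equal(growth_rate(1e5, 1e5 * exp(3), 3), 1)
  # noise-free exponential series is exact to floating point
  mu <- 0.73
  expect_equal(growth_rate(2e5, 2e5 * exp(mu * 3), 3), mu)
  expect_error(growth_rate(0, 1e5, 3), "positive")
  expect_error(growth_rate(1e5, 1e5, 0), "positive")
})

test_that("per-pair resistance is the clipped surviving-cell ratio", {
  expect_equal(r1_pair(5e5, 1e6), 0.5)
  expect_equal(r1_pair(2e6, 1e6), 1)   # denser than control clips to 1
  expect_equal(r1_pair(0, 1e6), 0)     # fully lysed
  expect_error(r1_pair(1e5, 0), "positive")
})

test_that("overall R1 is the unweighted mean of per-virus ratios", {
  # one host, three viruses with survival fractions 0.1, 0.6, 1.0 of control
  counts <- build_counts("h", c("v1", "v2", "v3"),
                         lysed = matrix(FALSE, 1, 3))
  grown <- 1e5 * exp(0.5 * 3)
  frac <- c(0.1, 0.6, 1.0)
  for (i in 1:3) {
    sel <- counts$challenge_id == paste0("v", i) & counts$timepoint_h == 72
    counts$cell_conc[sel] <- frac[i] * grown
  }
  res <- r1_overall(counts, "h")
  expect_equal(res$mean, mean(frac))
  expect_equal(res$sd, sd(frac))
  expect_error(r1_overall(counts, "nope"), "unknown host")

  # boundary regimes: all-resistant ~ 1, all-lysed ~ 0
  res1 <- r1_overall(build_counts("h", c("v1", "v2"), lysed = matrix(FALSE, 1, 2)), "h")
  expect_equal(res1$mean, 1)
  res0 <- r1_overall(build_counts("h", c("v1", "v2"), lysed = matrix(TRUE, 1, 2)), "h")
  expect_equal(res0$mean, 0.1)  # lysed wells retain 10% of control in the fixture
})

test_that("viral production is the signed final-minus-initial difference", {
  expect_equal(vp_pair(5e7, 1e6), 4.9e7)
  expect_equal(vp_pair(1e6, 1e6), 0)
  expect_equal(vp_pair(5e5, 1e6), -5e5)  # decay retained
})

test_that("vp summaries match exhaustive enumeration on a hand matrix", {
  # 3 hosts x 2 viruses with distinct hand-set burst outcomes
  prog <- rbind(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, FALSE))
  counts <- build_counts(c("a", "b", "c"), c("x", "y"), lysed = prog)
  vfinal <- rbind(c(8e7, 0.9e6), c(3e7, 6e7), c(0.9e6, 0.9e6))
  for (h in 1:3) for (v in 1:2) {
    sel <- counts$host_id == c("a", "b", "c")[h] &
      counts$challenge_id == c("x", "y")[v] & counts$timepoint_h == 72
    counts$virus_conc[sel] <- vfinal[h, v]
  }
  s <- vp_summaries(counts)
  expected_vp <- vfinal - 1e6
  expect_equal(unname(s$vp), unname(expected_vp))
  expect_equal(s$viruses$avg_vp, unname(colMeans(expected_vp)))
  expect_equal(s$viruses$max_vp, unname(apply(expected_vp, 2, max)))
  expect_equal(s$hosts$max_vp_host, unname(apply(expected_vp, 1, max)))
  expect_true(all(s$viruses$max_vp >= s$viruses$avg_vp))

  # degenerate single host: average equals maximum
  one <- build_counts("a", c("x", "y"), lysed = matrix(TRUE, 1, 2))
  s1 <- vp_summaries(one)
  expect_equal(s1$viruses$avg_vp, s1$viruses$max_vp)
})

test_that("lysis and progeny calls follow their thresholds and are monotone", {
  lysed <- rbind(c(TRUE, FALSE), c(FALSE, TRUE))
  counts <- build_counts(c("a", "b"), c("x", "y"), lysed = lysed)
  expect_equal(call_lysis(counts, "a", "x"), 1)
  expect_equal(call_lysis(counts, "a", "y"), 0)
  expect_equal(call_progeny(counts, "b", "y"), 1)
  expect_equal(call_progeny(counts, "b", "x"), 0)

  # raising theta can only add lysis calls; raising rho only removes progeny
  sim <- simulate_experiment(sim_config(n_hosts = 6, n_viruses = 4, seed = 9))
  ph_lo <- phenotype_table(sim$counts, theta = 0.5, rho = 1.2)
  ph_hi <- phenotype_table(sim$counts, theta = 0.9, rho = 5)
  expect_true(all(ph_hi$lysis >= ph_lo$lysis))
  expect_true(all(ph_hi$progeny <= ph_lo$progeny))
})

test_that("R2 and host range equal the call-matrix margins", {
  sim <- simulate_experiment(sim_config(n_hosts = 6, n_viruses = 4, seed = 11))
  ph <- phenotype_table(sim$counts)
  expect_equal(ph$hosts$R2, unname(rowSums(ph$progeny)))
  expect_equal(ph$viruses$host_range, unname(colSums(ph$lysis)))
  h <- ph$hosts$host_id[2]; v <- ph$viruses$virus_id[3]
  expect_equal(r2(sim$counts, h), sum(ph$progeny[h, ]))
  expect_equal(host_range(sim$counts, v), sum(ph$lysis[, v]))

  # a host susceptible to the full panel scores R2 = n_viruses
  all_sus <- build_counts("s", paste0("v", 1:13), lysed = matrix(TRUE, 1, 13))
  expect_equal(r2(all_sus, "s"), 13)
  none <- build_counts("r", paste0("v", 1:13), lysed = matrix(FALSE, 1, 13))
  expect_equal(r2(none, "r"), 0)
})

test_that("generalist/specialist split ranks by host range with lexicographic ties", {
  ranges <- c(a = 10L, b = 9L, c = 8L, z = 2L, d = 1L, e = 1L)
  sp <- split_generalists_specialists(ranges, 2)
  expect_equal(sp$generalists, c("a", "b"))
  expect_equal(sp$specialists, c("d", "e"))
  expect_equal(split_generalists_specialists(ranges, 0),
               list(generalists = character(), specialists = character()))
  expect_error(split_generalists_specialists(ranges, 4), "half")

  # on a nested truth the generalists are exactly the widest ground-truth ranges
  sim <- default_sim()
  truth_ranges <- colSums(sim$truth$matrix)
  ph <- phenotype_table(sim$counts)
  sp <- split_generalists_specialists(
    setNames(ph$viruses$host_range, ph$viruses$virus_id), 5)
  top_truth <- names(sort(truth_ranges, decreasing = TRUE))[1:5]
  expect_setequal(sp$generalists, top_truth)
})

test_that("phenotypes recover the generator's ground truth on the default panel", {
  sim <- default_sim()
  ph <- phenotype_table(sim$counts)
  expect_lt(mean(unclass(ph$lysis) != unclass(sim$truth$matrix)), 0.05)
  expect_gt(cor(ph$hosts$mu, sim$truth$mu[ph$hosts$host_id]), 0.95)
  # mu estimates stay within the generating range up to noise
  expect_true(all(abs(ph$hosts$mu - sim$truth$mu[ph$hosts$host_id]) < 0.15))
  expect_true(all(ph$hosts$R1 >= 0 & ph$hosts$R1 <= 1))
  # progeny-call row sums match ground-truth susceptibility counts
  expect_equal(ph$hosts$R2, unname(rowSums(sim$truth$matrix)))
})
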