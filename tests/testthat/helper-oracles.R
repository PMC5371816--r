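# Independent oracles and fixture builders shared across the suite.
# The oracles re-implement the definitions literally (nested loops over
# pairs / cells) so they stay independent of the vectorised code paths
# they check.

# literal NODF: loop over every ordered row pair and column pair,
# counting overlap / k_smaller only under strictly decreasing fill
nodf_oracle <- function(m) {
  axis_sum <- function(a) {
    k <- rowSums(a)
    total <- 0
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(a))) {
        if (i != j && k[i] > k[j] && k[j] > 0) {
          shared <- sum(a[i, ] == 1 & a[j, ] == 1)
          total <- total + shared / k[j]
        }
      }
    }
    total
  }
  n <- nrow(m); p <- ncol(m)
  (axis_sum(m) + axis_sum(t(m))) / (n * (n - 1) / 2 + p * (p - 1) / 2)
}

# literal Barber modularity: explicit double loop over all cells
qb_oracle <- function(m, rows, cols) {
  fill <- sum(m)
  k <- rowSums(m); d <- colSums(m)
  total <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (rows[i] == cols[j]) {
        total <- total + m[i, j] - k[i] * d[j] / fill
      }
    }
  }
  total / fill
}

random_binary_matrix <- function(nr, nc, p = 0.5) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

staircase_matrix <- function(n) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) m[i, seq_len(i)] <- 1L
  m
}

# Rand index between two flat partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# tiny hand-built counts table: `lysed` and `progeny` are logical matrices
# (hosts x viruses) declaring the intended outcome of each pair
build_counts <- function(hosts, viruses, mu = 0.5, lysed, progeny = lysed,
                         replicates = 3, cell_init = 1e5, virus_init = 1e6,
                         t_hours = 72) {
  t_days <- t_hours / 24
  rows <- list()
  for (h in seq_along(hosts)) {
    grown <- cell_init * exp(mu * t_days)
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        host_id = hosts[h], challenge_id = "CONTROL", replicate = r,
        timepoint_h = c(0, t_hours), cell_conc = c(cell_init, grown),
        virus_conc = NA_real_)
      for (v in seq_along(viruses)) {
        cell_tf <- if (lysed[h, v]) 0.1 * grown else grown
        virus_tf <- if (progeny[h, v]) 50 * virus_init else 0.9 * virus_init
        rows[[length(rows) + 1]] <- data.frame(
          host_id = hosts[h], challenge_id = viruses[v], replicate = r,
          timepoint_h = c(0, t_hours), cell_conc = c(cell_init, cell_tf),
          virus_conc = c(virus_init, virus_tf))
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# one default 49x13 simulated experiment, computed once per test run
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(sim_config(seed = 101))
    cache
  }
})
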