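#' Configuration for a simulated cross-infectivity experiment
#'
#' Collects every parameter of the synthetic plate experiment. The
#' defaults reproduce the design of a full coccolithophore-virus
#' challenge panel: 49 host strains x 13 virus strains in triplicate,
#' two timepoints 72 h apart, inocula of 1e5 cells/mL and 1e6
#' particles/mL, and host growth rates spanning 0.12-1.11 per day.
#'
#' @param n_hosts,n_viruses panel dimensions (defaults 49 and 13).
#' @param replicates wells per (host, challenge) series (default 3).
#' @param t_hours incubation time in hours (default 72).
#' @param mu_range host growth-rate interval, per day (default c(0.12, 1.11)).
#' @param cell_init initial cell concentration, cells/mL (default 1e5).
#' @param virus_init viral inoculum, particles/mL (default 1e6).
#' @param structure ground-truth interaction structure: `"nested"`,
#'   `"modular"` or `"random"`.
#' @param fill target fraction of 1s in the interaction matrix
#'   (nested / random structures; default 0.4).
#' @param n_blocks,within_p,between_p modular-structure parameters:
#'   number of balanced host/virus groups and the within- / between-group
#'   interaction probabilities.
#' @param flip_noise probability of flipping each ground-truth interaction
#'   before simulating wells (default 0).
#' @param lysis_survival fraction of the control cell yield surviving a
#'   successful infection (default 0.1).
#' @param burst_fold median fold-increase of virions on successful
#'   infection (default 50), with per-pair lognormal spread `burst_sdlog`.
#' @param burst_sdlog lognormal sdlog of per-pair burst heterogeneity
#'   (default 0.5).
#' @param decay_fold passive viral decay factor on non-infections
#'   (default 0.9).
#' @param meas_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise applied to every enumeration (default 0.10).
#' @param year_range isolation-year span for the simulated metadata
#'   (default c(1990, 2015)).
#' @param young_burst_fold extra burst multiplier for hosts isolated in or
#'   after `cutoff_year`; 1 (default) plants no domestication effect.
#' @param cutoff_year isolation-period boundary (default 2009).
#' @param seed integer seed driving every random draw.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_hosts = 49, n_viruses = 13, replicates = 3,
                       t_hours = 72, mu_range = c(0.12, 1.11),
                       cell_init = 1e5, virus_init = 1e6,
                       structure = c("nested", "modular", "random"),
                       fill = 0.4, n_blocks = 3, within_p = 0.9,
                       between_p = 0.05, flip_noise = 0,
                       lysis_survival = 0.1, burst_fold = 50,
                       burst_sdlog = 0.5, decay_fold = 0.9, meas_cv = 0.10,
                       year_range = c(1990, 2015), young_burst_fold = 1,
                       cutoff_year = 2009, seed = 1) {
  structure_type <- match.arg(structure)
  stopifnot(n_hosts >= 2, n_viruses >= 2, replicates >= 1, t_hours > 0,
            length(mu_range) == 2, mu_range[1] < mu_range[2],
            cell_init > 0, virus_init > 0,
            fill >= 0, fill <= 1, flip_noise >= 0, flip_noise <= 1,
            lysis_survival > 0, lysis_survival < 1,
            burst_fold > 0, decay_fold > 0, meas_cv >= 0,
            young_burst_fold > 0)
  if (structure_type == "modular" &&
      !(n_blocks <= min(n_hosts, n_viruses) && between_p < within_p &&
        between_p >= 0 && within_p <= 1)) {
    stop("modular structure needs n_blocks <= min(n_hosts, n_viruses) and 0 <= between_p < within_p <= 1",
         call. = FALSE)
  }
  out <- as.list(environment())
  out$structure <- structure_type
  out$structure_type <- NULL
  class(out) <- "sim_config"
  out
}

#' Ground-truth interaction matrices
#'
#' `make_nested_matrix()` builds a perfectly nested matrix at a requested
#' fill by a threshold rule: hosts receive a random susceptibility
#' ranking, viruses receive host-range sizes summing to the target fill,
#' and virus v infects exactly the hosts with the r_v lowest resistance
#' ranks. Row supports are therefore totally ordered by inclusion.
#' `make_modular_matrix()` splits hosts and viruses into balanced groups
#' and draws interactions with probability `within_p` inside matched
#' groups and `between_p` elsewhere. `make_random_matrix()` places the
#' target number of 1s uniformly.
#'
#' All three use the current RNG state.
#'
#' @inheritParams sim_config
#' @return a binary matrix (hosts x viruses) with generated labels.
#' @export
make_nested_matrix <- function(n_hosts, n_viruses, fill) {
  target <- round(fill * n_hosts * n_viruses)
  if (target < 0 || target > n_hosts * n_viruses) {
    stop("impossible fill for this shape", call. = FALSE)
  }
  rank_h <- sample.int(n_hosts)            # 1 = most susceptible
  # distinct range sizes where the shape allows, so marginals rarely tie
  sizes <- sample(0:n_hosts, n_viruses, replace = n_viruses > n_hosts + 1)
  pick <- function(idx) idx[sample.int(length(idx), 1)]
  # nudge range sizes until they sum to the target fill, preferring moves
  # that keep the sizes distinct (tied marginals dilute nestedness scores)
  while (sum(sizes) != target) {
    step <- if (sum(sizes) > target) -1L else 1L
    ok <- if (step < 0) sizes > 0 else sizes < n_hosts
    free <- ok & !((sizes + step) %in% sizes)
    i <- if (any(free)) pick(which(free)) else pick(which(ok))
    sizes[i] <- sizes[i] + step
  }
  m <- outer(rank_h, sizes, "<=") * 1L
  dimnames(m) <- list(default_ids("H", n_hosts), default_ids("V", n_viruses))
  m
}

#' @rdname make_nested_matrix
#' @export
make_modular_matrix <- function(n_hosts, n_viruses, n_blocks,
                                within_p = 0.9, between_p = 0.05) {
  if (!(n_blocks <= min(n_hosts, n_viruses))) {
    stop("n_blocks must not exceed min(n_hosts, n_viruses)", call. = FALSE)
  }
  if (!(between_p >= 0 && between_p < within_p && within_p <= 1)) {
    stop("need 0 <= between_p < within_p <= 1", call. = FALSE)
  }
  gh <- sort(rep_len(seq_len(n_blocks), n_hosts))
  gv <- sort(rep_len(seq_len(n_blocks), n_viruses))
  p <- ifelse(outer(gh, gv, "=="), within_p, between_p)
  m <- (array(runif(n_hosts * n_viruses), dim(p)) < p) * 1L
  dimnames(m) <- list(default_ids("H", n_hosts), default_ids("V", n_viruses))
  attr(m, "host_blocks") <- gh
  attr(m, "virus_blocks") <- gv
  m
}

#' @rdname make_nested_matrix
#' @export
make_random_matrix <- function(n_hosts, n_viruses, fill) {
  target <- round(fill * n_hosts * n_viruses)
  m <- matrix(0L, n_hosts, n_viruses,
              dimnames = list(default_ids("H", n_hosts), default_ids("V", n_viruses)))
  m[sample.int(length(m), target)] <- 1L
  m
}

default_ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

#' Simulate the full two-timepoint cross-infectivity experiment
#'
#' Generates a ground-truth interaction matrix and host growth rates,
#' then simulates every well of the plate design: control series grow
#' exponentially (N0 e^(mu t)); inoculated wells either lyse (final cells
#' at `lysis_survival` of the control expectation, virions at
#' `virus_init` times a per-pair lognormal burst fold) or track the
#' control while the inoculum decays by `decay_fold`. Every enumeration
#' is multiplied by independent lognormal measurement noise with
#' CV `meas_cv`. Isolation years span the `cutoff_year` boundary, and a
#' viral-production shift for younger strains can be planted via
#' `young_burst_fold`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (tidy tibble, one row per well and
#'   timepoint), `metadata` (strain tibble) and `truth` (ground truth:
#'   the realised interaction matrix, the pre-flip structure matrix,
#'   named growth rates `mu`, the per-pair burst-fold matrix, host
#'   isolation years and the config).
#' @examples
#' sim <- simulate_experiment(sim_config(n_hosts = 4, n_viruses = 3, seed = 7))
#' head(sim$counts)
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_experiment_(config))
}

simulate_experiment_ <- function(cfg) {
  hosts <- default_ids("H", cfg$n_hosts)
  viruses <- default_ids("V", cfg$n_viruses)
  t_days <- cfg$t_hours / 24

  structure_m <- switch(cfg$structure,
    nested = make_nested_matrix(cfg$n_hosts, cfg$n_viruses, cfg$fill),
    modular = make_modular_matrix(cfg$n_hosts, cfg$n_viruses, cfg$n_blocks,
                                  cfg$within_p, cfg$between_p),
    random = make_random_matrix(cfg$n_hosts, cfg$n_viruses, cfg$fill))
  truth_m <- structure_m
  if (cfg$flip_noise > 0) {
    flips <- array(runif(length(truth_m)) < cfg$flip_noise, dim(truth_m))
    truth_m[flips] <- 1L - truth_m[flips]
  }

  mu <- setNames(runif(cfg$n_hosts, cfg$mu_range[1], cfg$mu_range[2]), hosts)
  years <- setNames(sample(seq(cfg$year_range[1], cfg$year_range[2]),
                           cfg$n_hosts, replace = TRUE), hosts)
  oceans <- c("North Atlantic", "South Pacific", "Norwegian fjord",
              "English Channel", "Mediterranean")
  origins <- setNames(sample(oceans, cfg$n_hosts, replace = TRUE), hosts)

  sdlog <- cfg$burst_sdlog
  burst <- cfg$burst_fold *
    array(rlnorm(cfg$n_hosts * cfg$n_viruses, -sdlog^2 / 2, sdlog),
          dim = dim(truth_m), dimnames = dimnames(truth_m))
  young <- years >= cfg$cutoff_year
  burst[young, ] <- burst[young, , drop = FALSE] * cfg$young_burst_fold

  grid <- expand.grid(host_id = hosts,
                      challenge_id = c(CONTROL_TOKEN, viruses),
                      replicate = seq_len(cfg$replicates),
                      timepoint_h = c(0, cfg$t_hours),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$host_id, grid$challenge_id, grid$replicate,
                     grid$timepoint_h), ]

  is_ctrl <- grid$challenge_id == CONTROL_TOKEN
  is_t0 <- grid$timepoint_h == 0
  mu_g <- mu[grid$host_id]
  infected <- !is_ctrl &
    truth_m[cbind(grid$host_id, ifelse(is_ctrl, viruses[1], grid$challenge_id))] == 1
  grown <- cfg$cell_init * exp(mu_g * t_days)

  cell_expect <- ifelse(is_t0, cfg$cell_init,
                        ifelse(infected, cfg$lysis_survival * grown, grown))
  burst_g <- burst[cbind(grid$host_id, ifelse(is_ctrl, viruses[1], grid$challenge_id))]
  virus_expect <- ifelse(is_ctrl, NA_real_,
                         ifelse(is_t0, cfg$virus_init,
                                ifelse(infected, cfg$virus_init * burst_g,
                                       cfg$virus_init * cfg$decay_fold)))

  n <- nrow(grid)
  counts <- tibble::tibble(
    host_id = grid$host_id,
    challenge_id = grid$challenge_id,
    replicate = grid$replicate,
    timepoint_h = grid$timepoint_h,
    cell_conc = cell_expect * rlnorm_cv(n, cfg$meas_cv),
    virus_conc = virus_expect * rlnorm_cv(n, cfg$meas_cv))

  metadata <- tibble::tibble(
    strain_id = c(hosts, viruses),
    role = c(rep("host", cfg$n_hosts), rep("virus", cfg$n_viruses)),
    isolation_year = c(years,
                       sample(seq(cfg$year_range[1], cfg$year_range[2]),
                              cfg$n_viruses, replace = TRUE)),
    origin = c(origins, sample(oceans, cfg$n_viruses, replace = TRUE)))

  truth <- list(matrix = infection_matrix(truth_m),
                structure_matrix = infection_matrix(structure_m),
                mu = mu, burst = burst, years = years, config = cfg)
  list(counts = counts, metadata = metadata, truth = truth)
}
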