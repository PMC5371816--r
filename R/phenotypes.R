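#' Exponential growth rate from two cell counts
#'
#' The specific growth rate of an uninfected culture between two
#' timepoints, mu = ln(N2/N1) / t, in per-day units. Negative rates
#' (declining controls) are retained.
#'
#' @param n1,n2 cell concentrations (cells/mL) at the start and end of the
#'   incubation; must be positive. Vectorised.
#' @param t incubation time in days (> 0).
#' @return growth rate(s), per day.
#' @examples
#' growth_rate(1e5, 1e5 * exp(3), t = 3)  # 1 /d
#' @export
growth_rate <- function(n1, n2, t) {
  if (any(t <= 0)) stop("incubation time must be positive", call. = FALSE)
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("cell concentrations must be positive to compute a growth rate", call. = FALSE)
  }
  log(n2 / n1) / t
}

#' Per-pair resistance: surviving-cell ratio against the control
#'
#' Resistance of a host to one virus is the fraction of cells left after
#' the incubation relative to the uninfected control, clipped to \[0, 1\]:
#' `min(1, infected_final / control_final)`. A fully lysed culture scores
#' 0; a culture indistinguishable from (or denser than) its control
#' scores 1.
#'
#' @param infected_final replicate-mean final cell concentration in the
#'   inoculated well (cells/mL).
#' @param control_final replicate-mean final cell concentration in the
#'   control (> 0).
#' @return resistance fraction in \[0, 1\]. Vectorised.
#' @export
r1_pair <- function(infected_final, control_final) {
  if (any(control_final <= 0)) stop("control_final must be positive", call. = FALSE)
  pmin(1, infected_final / control_final)
}

#' Per-pair viral production
#'
#' Viral production for one host-virus pair is the plain difference
#' between final and initial viral concentrations (particles/mL).
#' Negative values (net viral decay) are retained.
#'
#' @param v_final,v_initial replicate-mean viral concentrations at the end
#'   and start of the incubation.
#' @return signed production, particles/mL. Vectorised.
#' @export
vp_pair <- function(v_final, v_initial) {
  v_final - v_initial
}

# replicate-mean wide table: one row per (host, challenge) with cell/virus
# concentrations at both timepoints, plus per-replicate control rates
summarise_wells <- function(counts, control = CONTROL_TOKEN) {
  counts <- validate_counts(counts, control = control)
  tps <- sort(unique(counts$timepoint_h))
  t0 <- tps[1]; tf <- tps[2]
  agg <- dplyr::summarise(
    dplyr::group_by(counts, .data$host_id, .data$challenge_id, .data$timepoint_h),
    cell = mean(.data$cell_conc), virus = mean(.data$virus_conc),
    cell_sd = sd(.data$cell_conc), .groups = "drop")
  wide <- tidyr::pivot_wider(agg,
    names_from = "timepoint_h", values_from = c("cell", "virus", "cell_sd"))
  names(wide) <- sub(paste0("_", t0, "$"), "_t0", names(wide))
  names(wide) <- sub(paste0("_", tf, "$"), "_tf", names(wide))
  attr(wide, "t_days") <- (tf - t0) / 24
  attr(wide, "control") <- control
  wide
}

# per-replicate control growth rates for one summarised counts table
control_mu <- function(counts, control = CONTROL_TOKEN) {
  tps <- sort(unique(counts$timepoint_h))
  t_days <- (tps[2] - tps[1]) / 24
  ctrl <- counts[counts$challenge_id == control, ]
  wide <- tidyr::pivot_wider(
    ctrl[c("host_id", "replicate", "timepoint_h", "cell_conc")],
    names_from = "timepoint_h", values_from = "cell_conc")
  mu <- growth_rate(wide[[as.character(tps[1])]], wide[[as.character(tps[2])]], t_days)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(host_id = wide$host_id, mu = mu), .data$host_id),
    mu_mean = mean(.data$mu), mu_sd = sd(.data$mu), .groups = "drop")
}

#' Overall resistance of one host (R1)
#'
#' The per-virus surviving-cell ratios ([r1_pair()]) of a host against
#' every virus in the panel, averaged (unweighted) into one overall
#' resistance capacity, with the standard deviation across viruses.
#'
#' @param counts a validated counts table.
#' @param host host strain id.
#' @param control control token.
#' @return named list with `mean` and `sd`.
#' @export
r1_overall <- function(counts, host, control = CONTROL_TOKEN) {
  wide <- summarise_wells(counts, control = control)
  h <- wide[wide$host_id == host, ]
  if (nrow(h) == 0) stop("unknown host: ", host, call. = FALSE)
  ctrl <- h[h$challenge_id == control, ]
  inf <- h[h$challenge_id != control, ]
  if (nrow(inf) == 0) stop("host ", host, " has no virus challenges", call. = FALSE)
  vals <- r1_pair(inf$cell_tf, ctrl$cell_tf)
  list(mean = mean(vals), sd = sd(vals))
}

#' Binary lysis and progeny calls for one host-virus pair
#'
#' `call_lysis()` scores lysis from the cell side: 1 when the replicate-mean
#' final cell count in the inoculated well falls below `theta` times the
#' control mean (default theta = 0.75). `call_progeny()` scores successful
#' viral replication from the virus side: 1 when the mean final viral count
#' reaches at least `rho` times the measured initial count (default
#' rho = 1.5). Both thresholds act on replicate means; raising `theta` can
#' only add lysis calls, raising `rho` can only remove progeny calls.
#'
#' @param counts a validated counts table.
#' @param host,virus strain ids.
#' @param theta lysis threshold as a fraction of the control (0 < theta).
#' @param rho progeny threshold as a fold factor over the inoculum.
#' @param control control token.
#' @return 0 or 1.
#' @export
call_lysis <- function(counts, host, virus, theta = 0.75, control = CONTROL_TOKEN) {
  wide <- summarise_wells(counts, control = control)
  lysis_calls(wide, theta = theta)[host, virus]
}

#' @rdname call_lysis
#' @export
call_progeny <- function(counts, host, virus, rho = 1.5, control = CONTROL_TOKEN) {
  wide <- summarise_wells(counts, control = control)
  progeny_calls(wide, rho = rho)[host, virus]
}

# full lysis-call matrix from a summarised wide table
lysis_calls <- function(wide, theta = 0.75) {
  control <- attr(wide, "control")
  ctrl <- wide[wide$challenge_id == control, c("host_id", "cell_tf")]
  names(ctrl)[2] <- "control_tf"
  if (any(ctrl$control_tf <= 0)) {
    stop("control final cell count is zero for host ",
         ctrl$host_id[which(ctrl$control_tf <= 0)[1]], call. = FALSE)
  }
  inf <- dplyr::left_join(wide[wide$challenge_id != control, ], ctrl, by = "host_id")
  calls <- as.integer(inf$cell_tf < theta * inf$control_tf)
  build_call_matrix(inf, calls)
}

# full progeny-call matrix; falls back to the nominal inoculum when the
# measured t0 viral count is absent
progeny_calls <- function(wide, rho = 1.5, v_nominal = 1e6) {
  control <- attr(wide, "control")
  inf <- wide[wide$challenge_id != control, ]
  v0 <- ifelse(is.na(inf$virus_t0), v_nominal, inf$virus_t0)
  if (any(v0 <= 0)) {
    stop("initial viral concentration is zero for pair (",
         inf$host_id[which(v0 <= 0)[1]], ", ",
         inf$challenge_id[which(v0 <= 0)[1]], ")", call. = FALSE)
  }
  calls <- as.integer(inf$virus_tf >= rho * v0)
  build_call_matrix(inf, calls)
}

build_call_matrix <- function(inf, values) {
  hosts <- sort(unique(inf$host_id))
  viruses <- sort(unique(inf$challenge_id))
  m <- matrix(NA_real_, length(hosts), length(viruses),
              dimnames = list(hosts, viruses))
  m[cbind(inf$host_id, inf$challenge_id)] <- values
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing host-virus pair: (", hosts[idx[1]], ", ", viruses[idx[2]], ")",
         call. = FALSE)
  }
  m
}

# signed viral-production matrix (particles/mL), measured t0 with nominal fallback
vp_matrix_ <- function(wide, v_nominal = 1e6) {
  control <- attr(wide, "control")
  inf <- wide[wide$challenge_id != control, ]
  v0 <- ifelse(is.na(inf$virus_t0), v_nominal, inf$virus_t0)
  build_call_matrix(inf, vp_pair(inf$virus_tf, v0))
}

#' Viral-production summaries across the panel
#'
#' Aggregates the per-pair production matrix: per virus the mean and
#' maximum production over hosts ("Maximum viral production"), and per
#' host the maximum over viruses.
#'
#' @param counts a validated counts table.
#' @param v_nominal nominal inoculum (particles/mL) used when no t0 viral
#'   count was measured.
#' @param control control token.
#' @return list with tibbles `viruses` (`virus_id`, `avg_vp`, `max_vp`) and
#'   `hosts` (`host_id`, `avg_vp_host`, `max_vp_host`) and the `vp` matrix.
#' @export
vp_summaries <- function(counts, v_nominal = 1e6, control = CONTROL_TOKEN) {
  wide <- summarise_wells(counts, control = control)
  vp <- vp_matrix_(wide, v_nominal = v_nominal)
  list(
    viruses = tibble::tibble(
      virus_id = colnames(vp),
      avg_vp = unname(colMeans(vp)),
      max_vp = unname(apply(vp, 2, max))),
    hosts = tibble::tibble(
      host_id = rownames(vp),
      avg_vp_host = unname(rowMeans(vp)),
      max_vp_host = unname(apply(vp, 1, max))),
    vp = vp)
}

#' Host resistance count (R2) and virus host range
#'
#' `r2()` counts the virus strains that successfully produced progeny on a
#' host (a low count means high resistance); `host_range()` counts the
#' hosts a virus lysed. They are the row sums of the progeny-call matrix
#' and the column sums of the lysis-call matrix respectively.
#'
#' @inheritParams call_lysis
#' @inheritParams call_progeny
#' @return an integer count.
#' @export
r2 <- function(counts, host, rho = 1.5, control = CONTROL_TOKEN) {
  wide <- summarise_wells(counts, control = control)
  m <- progeny_calls(wide, rho = rho)
  if (!host %in% rownames(m)) stop("unknown host: ", host, call. = FALSE)
  sum(m[host, ])
}

#' @rdname r2
#' @export
host_range <- function(counts, virus, theta = 0.75, control = CONTROL_TOKEN) {
  wide <- summarise_wells(counts, control = control)
  m <- lysis_calls(wide, theta = theta)
  if (!virus %in% colnames(m)) stop("unknown virus: ", virus, call. = FALSE)
  sum(m[, virus])
}

#' Rank viruses into generalists and specialists
#'
#' Viruses are ranked by host range; the top `k` are the generalists and
#' the bottom `k` the specialists. Ties are broken lexicographically by
#' strain id, so the split is deterministic.
#'
#' @param host_ranges named integer vector of host ranges (names are virus ids).
#' @param k number of strains per group; must satisfy `k <= length(host_ranges) / 2`.
#' @return list with character vectors `generalists` and `specialists`.
#' @export
split_generalists_specialists <- function(host_ranges, k) {
  if (k < 0 || k > length(host_ranges) / 2) {
    stop("k must be between 0 and half the number of viruses", call. = FALSE)
  }
  if (k == 0) return(list(generalists = character(), specialists = character()))
  ids <- names(host_ranges)
  top <- ids[order(-host_ranges, ids)][seq_len(k)]
  bottom <- ids[order(host_ranges, ids)][seq_len(k)]
  list(generalists = top, specialists = bottom)
}

#' Per-strain phenotype table of a cross-infectivity experiment
#'
#' Computes every per-strain metric of the panel in one pass: for each
#' host the control growth rate mu (with SD across replicates), overall
#' resistance R1 (mean surviving-cell ratio over viruses, with SD),
#' resistance count R2 (viruses producing progeny), and mean / maximum
#' viral production across viruses; for each virus the host range (lysis
#' calls), mean and maximum production across hosts. Also returns the two
#' binary matrices (lysis and progeny calls) that feed the network
#' analysis, and the signed production matrix.
#'
#' @inheritParams call_lysis
#' @param rho progeny threshold fold factor.
#' @param v_nominal nominal inoculum fallback (particles/mL).
#' @return object of class `phenotype_table`: list with tibbles `hosts`
#'   and `viruses`, matrices `lysis`, `progeny` (as [infection_matrix()])
#'   and `vp`, and the thresholds used.
#' @examples
#' sim <- simulate_experiment(sim_config(n_hosts = 6, n_viruses = 4, seed = 1))
#' ph <- phenotype_table(sim$counts)
#' ph$hosts
#' @export
phenotype_table <- function(counts, theta = 0.75, rho = 1.5, v_nominal = 1e6,
                            control = CONTROL_TOKEN) {
  wide <- summarise_wells(counts, control = control)
  mu_tab <- control_mu(counts, control = control)
  lys <- lysis_calls(wide, theta = theta)
  prog <- progeny_calls(wide, rho = rho, v_nominal = v_nominal)
  vp <- vp_matrix_(wide, v_nominal = v_nominal)

  ctrl <- wide[wide$challenge_id == control, c("host_id", "cell_tf")]
  names(ctrl)[2] <- "control_tf"
  inf <- dplyr::left_join(wide[wide$challenge_id != control, ], ctrl, by = "host_id")
  inf$r1 <- r1_pair(inf$cell_tf, inf$control_tf)
  r1 <- dplyr::summarise(dplyr::group_by(inf, .data$host_id),
                         R1 = mean(.data$r1), R1_sd = sd(.data$r1),
                         .groups = "drop")

  hosts <- tibble::tibble(
    host_id = rownames(lys),
    mu = mu_tab$mu_mean[match(rownames(lys), mu_tab$host_id)],
    mu_sd = mu_tab$mu_sd[match(rownames(lys), mu_tab$host_id)],
    R1 = r1$R1[match(rownames(lys), r1$host_id)],
    R1_sd = r1$R1_sd[match(rownames(lys), r1$host_id)],
    R2 = unname(as.integer(rowSums(prog))),
    avg_vp_host = unname(rowMeans(vp)),
    max_vp_host = unname(apply(vp, 1, max)))
  viruses <- tibble::tibble(
    virus_id = colnames(lys),
    host_range = unname(as.integer(colSums(lys))),
    avg_vp = unname(colMeans(vp)),
    max_vp = unname(apply(vp, 2, max)))

  structure(list(hosts = hosts, viruses = viruses,
                 lysis = infection_matrix(lys),
                 progeny = infection_matrix(prog),
                 vp = vp, theta = theta, rho = rho),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotypes: %d hosts x %d viruses (theta = %.2f, rho = %.2f)\n",
              nrow(x$hosts), nrow(x$viruses), x$theta, x$rho))
  cat(sprintf("  mu range %.3g-%.3g /d; lysis fill %.2f; progeny fill %.2f\n",
              min(x$hosts$mu), max(x$hosts$mu), mean(x$lysis), mean(x$progeny)))
  invisible(x)
}
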