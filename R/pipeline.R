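#' Configuration for a full pipeline run
#'
#' Bundles inputs, thresholds and seeds for [run_all()]. Inputs are
#' either a [sim_config()] (the experiment is simulated) or paths /
#' tables for counts and metadata. A seed is mandatory whenever any
#' stochastic step (simulation or null models) is requested, so that a
#' rerun with the same configuration is byte-identical.
#'
#' @param simulate a [sim_config()], or `NULL` to read real inputs.
#' @param counts counts CSV path or tibble (ignored when simulating).
#' @param metadata metadata CSV path or tibble.
#' @param out_dir output directory (created if needed).
#' @param theta,rho lysis and progeny call thresholds.
#' @param n_null null-ensemble size per metric (default 100).
#' @param seed master seed; required when `simulate` is set or `n_null > 0`.
#' @param cutoff_year isolation-period boundary (default 2009).
#' @param k generalist/specialist group size (default 5).
#' @param metrics structure metrics to test against the null.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = NULL, counts = NULL, metadata = NULL,
                       out_dir = tempfile("vhinet-run-"), theta = 0.75,
                       rho = 1.5, n_null = 100, seed = NULL,
                       cutoff_year = 2009, k = 5,
                       metrics = c("NODF", "Qb")) {
  if (is.null(simulate) && is.null(counts)) {
    stop("either a simulation config or a counts input is required", call. = FALSE)
  }
  if ((!is.null(simulate) || n_null > 0) && is.null(seed)) {
    stop("a seed is required for stochastic steps (simulation or null models)",
         call. = FALSE)
  }
  stopifnot(theta > 0, rho > 0, n_null >= 0,
            all(metrics %in% c("NODF", "Qb")))
  structure(list(simulate = simulate, counts = counts, metadata = metadata,
                 out_dir = out_dir, theta = theta, rho = rho,
                 n_null = n_null, seed = seed, cutoff_year = cutoff_year,
                 k = k, metrics = metrics),
            class = "run_config")
}

#' Run the complete analysis pipeline
#'
#' Orchestrates every stage on one configuration: simulate (or read) the
#' experiment, compute the phenotype table, run the association screen,
#' measure the infection-network structure (NODF and modularity of the
#' lysis matrix), test it against the equiprobable null ensemble, and
#' write the result bundle: `phenotypes_hosts.csv`,
#' `phenotypes_viruses.csv`, `lysis_matrix.csv`, `progeny_matrix.csv`,
#' `screen.csv`, `network.json`, `nulls_<metric>.json` and a
#' human-readable `report.md` stating each of the five classical
#' virus-host hypotheses with its computed statistic. Reruns with the
#' same configuration produce byte-identical files. Any stage failure
#' aborts with the stage name and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return the result bundle (list), invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(stage, e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }

  # inputs
  stage <- "inputs"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- config$seed %||% cfg$seed
      sim <- simulate_experiment(cfg)
      list(counts = sim$counts, metadata = sim$metadata, truth = sim$truth)
    } else {
      counts <- if (is.character(config$counts)) read_counts(config$counts)
                else validate_counts(config$counts)
      metadata <- if (is.character(config$metadata)) read_metadata(config$metadata)
                  else if (!is.null(config$metadata)) validate_metadata(config$metadata)
      list(counts = counts, metadata = metadata, truth = NULL)
    }
  }, error = function(e) on_fail(stage, e))

  stage <- "phenotypes"
  ph <- tryCatch(
    phenotype_table(res$counts, theta = config$theta, rho = config$rho),
    error = function(e) on_fail(stage, e))

  stage <- "screen"
  scr <- tryCatch(
    screen(ph, metadata = res$metadata, cutoff_year = config$cutoff_year,
           k = config$k),
    error = function(e) on_fail(stage, e))

  stage <- "network"
  net <- tryCatch({
    part <- detect_modules(ph$lysis)
    list(nodf = nodf(ph$lysis)$value, qb = part$qb,
         n_modules = part$n_modules,
         row_assignments = as.list(part$rows),
         column_assignments = as.list(part$cols))
  }, error = function(e) on_fail(stage, e))

  stage <- "nulls"
  nulls <- tryCatch({
    out <- list()
    for (i in seq_along(config$metrics)) {
      if (config$n_null > 0) {
        out[[config$metrics[i]]] <- significance(
          ph$lysis, metric = config$metrics[i], n_null = config$n_null,
          seed = config$seed + i)
      }
    }
    out
  }, error = function(e) on_fail(stage, e))

  stage <- "write"
  tryCatch({
    emit("phenotypes_hosts.csv",
         function(p) write.csv(ph$hosts, p, row.names = FALSE, quote = FALSE))
    emit("phenotypes_viruses.csv",
         function(p) write.csv(ph$viruses, p, row.names = FALSE, quote = FALSE))
    emit("lysis_matrix.csv", function(p) write_matrix(ph$lysis, p))
    emit("progeny_matrix.csv", function(p) write_matrix(ph$progeny, p))
    emit("screen.csv",
         function(p) write.csv(scr, p, row.names = FALSE, quote = FALSE))
    emit("network.json",
         function(p) jsonlite::write_json(net, p, auto_unbox = TRUE, digits = NA))
    for (metric in names(nulls)) {
      ens <- nulls[[metric]]
      emit(paste0("nulls_", metric, ".json"), function(p) {
        jsonlite::write_json(
          ens[c("metric", "observed", "null_values", "null_mean", "null_sd",
                "z", "p_empirical", "n_null", "seed")],
          p, auto_unbox = TRUE, digits = NA, na = "null")
      })
    }
    emit("report.md",
         function(p) writeLines(hypothesis_report(scr, net, nulls, ph, config$k), p))
  }, error = function(e) on_fail(stage, e))

  invisible(list(phenotypes = ph, screen = scr, network = net, nulls = nulls,
                 truth = res$truth, out_dir = config$out_dir))
}

# the five classical virus-host interaction hypotheses, each mapped to the
# screen comparison that tests it and the direction that would support it
hypothesis_map <- function() {
  list(
    list(n = 1, text = "Resistance is associated with reduced growth rates (cost of resistance).",
         comparison = "R1_vs_mu", supported = function(s, p) p < 0.05 && s < 0),
    list(n = 2, text = "Host strains with higher growth rate produce more viruses.",
         comparison = "Vp_vs_mu", supported = function(s, p) p < 0.05 && s > 0),
    list(n = 3, text = "Host strains with higher growth rate are infected by more viral strains.",
         comparison = "R2_vs_mu", supported = function(s, p) p < 0.05 && s > 0),
    list(n = 4, text = "Host strains with higher resistance produce fewer viruses.",
         comparison = "Vp_vs_R1", supported = function(s, p) p < 0.05 && s < 0),
    list(n = 5, text = "Specialist viruses have higher viral production than generalists.",
         comparison = "generalist_vs_specialist_Vp",
         supported = function(s, p) p < 0.05 && s < 0))
}

# signed direction for the generalist/specialist contrast: positive when
# generalists out-produce specialists (hypothesis 5 predicts negative)
gen_spec_direction <- function(ph, k) {
  split <- split_generalists_specialists(
    setNames(ph$viruses$host_range, ph$viruses$virus_id), k)
  v <- setNames(ph$viruses$avg_vp, ph$viruses$virus_id)
  mean(v[split$generalists]) - mean(v[split$specialists])
}

hypothesis_report <- function(scr, net, nulls, ph, k) {
  lines <- c("# Cross-infectivity analysis report", "",
             "## Hypotheses", "")
  for (h in hypothesis_map()) {
    row <- scr[scr$comparison == h$comparison, ]
    if (nrow(row) == 0) {
      lines <- c(lines, sprintf("%d. %s — comparison unavailable.", h$n, h$text))
      next
    }
    stat_lab <- if (row$test == "pearson") {
      sprintf("Pearson r = %.4f, p = %.4g", row$statistic, row$p)
    } else {
      sprintf("one-way ANOVA F(%d, %d) = %.4f, p = %.4g",
              row$df1, row$df2, row$statistic, row$p)
    }
    direction <- if (h$comparison == "generalist_vs_specialist_Vp") {
      gen_spec_direction(ph, k)
    } else {
      row$statistic
    }
    verdict <- if (h$supported(direction, row$p)) "supported" else "not supported"
    lines <- c(lines, sprintf("%d. %s — %s (%s).", h$n, h$text, stat_lab, verdict))
  }
  lines <- c(lines, "", "## Network structure", "",
             sprintf("- NODF = %.4f", net$nodf),
             sprintf("- Qb = %.4f over %d module(s)", net$qb, net$n_modules))
  for (metric in names(nulls)) {
    ens <- nulls[[metric]]
    lines <- c(lines, sprintf(
      "- %s vs %d equiprobable nulls: null mean %.4f (sd %.4f), z = %s, empirical p = %.4f",
      metric, ens$n_null, ens$null_mean, ens$null_sd,
      ifelse(is.na(ens$z), "NA", sprintf("%.2f", ens$z)), ens$p_empirical))
  }
  lines
}
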