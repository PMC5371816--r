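#' Read and validate a cross-infectivity count table
#'
#' The count table is the tidy record of the plate experiment: one row per
#' (host strain, challenge, replicate, timepoint) with the flow-cytometry
#' style enumerations. The challenge is either a virus id or the reserved
#' token `"CONTROL"` for the uninfected control series of that host.
#' Expected columns: `host_id`, `challenge_id`, `replicate`, `timepoint_h`,
#' `cell_conc` (cells/mL), `virus_conc` (particles/mL; may be missing for
#' control wells only).
#'
#' Validation enforces the experimental design: every (host, challenge,
#' replicate) series must carry both timepoints, every host must have at
#' least one control series, and concentrations must be finite and
#' non-negative. Row order never matters downstream.
#'
#' @param path path to a counts CSV.
#' @param control token marking control wells (default `"CONTROL"`).
#' @return a validated tibble of counts.
#' @seealso [write_counts()], [phenotype_table()]
#' @export
read_counts <- function(path, control = CONTROL_TOKEN) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_counts(tibble::as_tibble(df), control = control)
}

#' @rdname read_counts
#' @param counts a counts table as returned by [read_counts()] or
#'   [simulate_experiment()].
#' @export
write_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_counts
#' @export
validate_counts <- function(counts, control = CONTROL_TOKEN) {
  required <- c("host_id", "challenge_id", "replicate", "timepoint_h",
                "cell_conc", "virus_conc")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop("counts table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  counts$host_id <- as.character(counts$host_id)
  counts$challenge_id <- as.character(counts$challenge_id)
  for (col in c("replicate", "timepoint_h", "cell_conc", "virus_conc")) {
    v <- counts[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric %s for (host %s, challenge %s, replicate %s)",
                     col, counts$host_id[bad[1]], counts$challenge_id[bad[1]],
                     counts$replicate[bad[1]]), call. = FALSE)
      }
      counts[[col]] <- v2
    }
  }

  bad <- which(!is.finite(counts$cell_conc) | counts$cell_conc < 0)
  if (length(bad) > 0) {
    stop(sprintf("invalid cell_conc for (host %s, challenge %s, replicate %s)",
                 counts$host_id[bad[1]], counts$challenge_id[bad[1]],
                 counts$replicate[bad[1]]), call. = FALSE)
  }
  is_ctrl <- counts$challenge_id == control
  bad <- which(!is_ctrl & (!is.finite(counts$virus_conc) | counts$virus_conc < 0))
  if (length(bad) > 0) {
    stop(sprintf("missing or invalid virus_conc for inoculated well (host %s, challenge %s, replicate %s)",
                 counts$host_id[bad[1]], counts$challenge_id[bad[1]],
                 counts$replicate[bad[1]]), call. = FALSE)
  }
  bad <- which(is_ctrl & !is.na(counts$virus_conc) & counts$virus_conc < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative virus_conc in control well (host %s, replicate %s)",
                 counts$host_id[bad[1]], counts$replicate[bad[1]]), call. = FALSE)
  }

  tps <- sort(unique(counts$timepoint_h))
  if (length(tps) != 2) {
    stop("counts table must contain exactly two timepoints, found: ",
         paste(tps, collapse = ", "), call. = FALSE)
  }
  series <- dplyr::summarise(
    dplyr::group_by(counts, .data$host_id, .data$challenge_id, .data$replicate),
    n_tp = dplyr::n_distinct(.data$timepoint_h), .groups = "drop")
  bad <- series[series$n_tp != 2, ]
  if (nrow(bad) > 0) {
    stop(sprintf("series (host %s, challenge %s, replicate %s) lacks a timepoint",
                 bad$host_id[1], bad$challenge_id[1], bad$replicate[1]), call. = FALSE)
  }
  hosts <- unique(counts$host_id)
  no_ctrl <- setdiff(hosts, counts$host_id[is_ctrl])
  if (length(no_ctrl) > 0) {
    stop("host without CONTROL series: ", no_ctrl[1], call. = FALSE)
  }
  tibble::as_tibble(counts)
}

#' Read a strain metadata table
#'
#' Metadata carries strain identity and provenance: `strain_id`, `role`
#' (`"host"` or `"virus"`), `isolation_year` (may be missing) and `origin`
#' (free-text ocean or region, may be missing). Isolation years feed the
#' before/after-2009 domestication grouping of [split_by_year()].
#'
#' @param path path to a metadata CSV.
#' @return a validated tibble.
#' @export
read_metadata <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata a metadata table.
#' @export
validate_metadata <- function(metadata) {
  required <- c("strain_id", "role", "isolation_year", "origin")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(metadata$role %in% c("host", "virus"))) {
    stop("metadata role must be 'host' or 'virus'", call. = FALSE)
  }
  dup <- metadata[duplicated(metadata[c("strain_id", "role")]), ]
  if (nrow(dup) > 0) {
    stop("duplicated strain_id within role: ", dup$strain_id[1], call. = FALSE)
  }
  yr <- metadata$isolation_year
  bad <- which(!is.na(yr) & (yr < 1900 | yr > 2100))
  if (length(bad) > 0) {
    stop("implausible isolation_year for strain ", metadata$strain_id[bad[1]],
         ": ", yr[bad[1]], call. = FALSE)
  }
  tibble::as_tibble(metadata)
}
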