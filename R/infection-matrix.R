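#' Labelled binary infection matrix
#'
#' An infection matrix records the outcome of a full-factorial
#' cross-infectivity panel: rows are host strains, columns are virus
#' strains, and a cell is 1 when the virus lysed (or produced progeny on)
#' the host and 0 otherwise. It is an ordinary base matrix carrying the
#' class `"infection_matrix"`; all structure statistics ([nodf()], [qb()],
#' [detect_modules()]) and null models ([equiprobable_null()]) accept it
#' or any plain binary matrix.
#'
#' @param x numeric or integer matrix with entries in {0, 1}.
#' @param host_ids,virus_ids optional row / column labels; taken from
#'   `dimnames(x)` when omitted, and generated (`H1..`, `V1..`) when absent.
#' @return an `infection_matrix`: an integer matrix with dimnames.
#' @examples
#' m <- infection_matrix(rbind(c(1, 1), c(1, 0)))
#' sum(m)  # fill = number of interactions
#' @export
infection_matrix <- function(x, host_ids = NULL, virus_ids = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) {
    bad <- which(!(x %in% c(0, 1)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary entry at row %s, column %s: %s",
                 bad[1], bad[2], x[bad[1], bad[2]]), call. = FALSE)
  }
  host_ids <- host_ids %||% rownames(x) %||% paste0("H", seq_len(nrow(x)))
  virus_ids <- virus_ids %||% colnames(x) %||% paste0("V", seq_len(ncol(x)))
  if (length(host_ids) != nrow(x) || length(virus_ids) != ncol(x)) {
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(host_ids)) {
    stop("duplicated host id: ", host_ids[duplicated(host_ids)][1], call. = FALSE)
  }
  if (anyDuplicated(virus_ids)) {
    stop("duplicated virus id: ", virus_ids[duplicated(virus_ids)][1], call. = FALSE)
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- list(host_ids, virus_ids)
  class(x) <- c("infection_matrix", class(x))
  x
}

#' @export
print.infection_matrix <- function(x, ...) {
  cat(sprintf("infection matrix: %d hosts x %d viruses, fill %d (%.2f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Read / write an infection matrix as CSV
#'
#' The CSV layout mirrors the printed host-range tables of cross-infectivity
#' studies: virus ids as header row, host ids in the first column, cells in
#' {0, 1}. `write_matrix()` followed by `read_matrix()` is the identity.
#'
#' @param path file path of a matrix CSV.
#' @return `read_matrix()` returns an [infection_matrix()];
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix CSV needs a host-id column plus virus columns", call. = FALSE)
  hosts <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  viruses <- colnames(vals)
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell for host %s, virus %s", hosts[bad[1]], viruses[bad[2]]),
         call. = FALSE)
  }
  bad <- which(!(vals %in% c(0, 1)))
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dim(vals))
    stop(sprintf("non-binary cell for host %s, virus %s: %s",
                 hosts[idx[1]], viruses[idx[2]], vals[idx[1], idx[2]]),
         call. = FALSE)
  }
  infection_matrix(vals, host_ids = hosts, virus_ids = viruses)
}

#' @rdname read_matrix
#' @param matrix an [infection_matrix()] (or binary matrix with dimnames).
#' @export
write_matrix <- function(matrix, path) {
  matrix <- infection_matrix(unclass(matrix))
  df <- data.frame(host_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
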