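#' NODF nestedness of a binary interaction matrix
#'
#' NODF (nestedness metric based on overlap and decreasing fill) scores
#' how much the interaction sets of specialists are contained within
#' those of generalists. For every ordered pair of rows (i, j) whose
#' marginal sums satisfy k_i > k_j > 0, the paired term is the number of
#' columns shared by both rows divided by k_j; pairs with k_i <= k_j
#' (decreasing-fill rule) or k_j = 0 contribute zero. Column pairs are
#' scored the same way. NODF is the sum of all row-pair and column-pair
#' terms divided by the total pair count n(n-1)/2 + m(m-1)/2, so a
#' strictly nested staircase scores exactly 1 and a matrix whose rows
#' (and columns) all tie on marginal sum scores 0. Empty rows and columns
#' stay in the pair count.
#'
#' The score does not depend on row or column order (pairing is by
#' marginal comparison), so [degree_sort()] never changes it.
#'
#' @param matrix binary matrix (hosts x viruses), at least 2 x 2.
#' @param scale `"unit"` for the 0-1 scale (default) or `"percent"` for
#'   the 0-100 scale of the older nestedness literature.
#' @return a `structure_score` list: `metric`, `value`, `matrix_shape`,
#'   `fill`.
#' @examples
#' stair <- lower.tri(diag(4), diag = TRUE) * 1L
#' nodf(stair)$value  # 1: perfectly nested
#' @export
nodf <- function(matrix, scale = c("unit", "percent")) {
  scale <- match.arg(scale)
  m <- check_binary_matrix(matrix)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("NODF needs at least 2 rows and 2 columns", call. = FALSE)
  }
  value <- nodf_value(m)
  if (scale == "percent") value <- 100 * value
  structure(list(metric = "NODF", value = value,
                 matrix_shape = dim(m), fill = sum(m)),
            class = "structure_score")
}

# fast path: plain numeric NODF on the 0-1 scale
nodf_value <- function(m) {
  (nodf_axis_sum(m) + nodf_axis_sum(t(m))) /
    (choose(nrow(m), 2) + choose(ncol(m), 2))
}

# sum of paired overlap terms over ordered row pairs with k_i > k_j > 0
nodf_axis_sum <- function(m) {
  k <- rowSums(m)
  n <- length(k)
  if (n < 2) return(0)
  overlap <- tcrossprod(m)                  # shared 1-columns per row pair
  denom <- matrix(k, n, n, byrow = TRUE)    # k_j for ordered pair (i, j)
  ok <- outer(k, k, ">") & denom > 0
  sum(overlap[ok] / denom[ok])
}

check_binary_matrix <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (!all(m %in% c(0, 1))) stop("matrix must be binary (0/1)", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' @export
print.structure_score <- function(x, ...) {
  cat(sprintf("%s = %.4f (%d x %d matrix, fill %d)\n",
              x$metric, x$value, x$matrix_shape[1], x$matrix_shape[2], x$fill))
  invisible(x)
}

#' Sort a matrix by decreasing marginal sums
#'
#' Reorders rows and columns by decreasing marginal sums (ties broken by
#' label), the layout used to display nested infection networks with the
#' generalist viruses and most susceptible hosts in the upper left.
#'
#' @param matrix binary matrix with dimnames.
#' @return the reordered matrix (an [infection_matrix()] when labelled).
#' @export
degree_sort <- function(matrix) {
  m <- as.matrix(matrix)
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cn <- colnames(m) %||% as.character(seq_len(ncol(m)))
  ro <- order(-rowSums(m), rn)
  co <- order(-colSums(m), cn)
  out <- m[ro, co, drop = FALSE]
  if (inherits(matrix, "infection_matrix")) out <- infection_matrix(out)
  out
}
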