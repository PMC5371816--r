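#' Pearson correlation test
#'
#' Sample Pearson correlation with the usual two-sided t-transform
#' p-value: t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' Implemented directly from the definition; agreement with
#' `stats::cor.test()` is part of the test suite.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite,
#'   non-constant.
#' @return a `vhinet_test` list: `statistic` (r), `df`, `p`, `n`, `method`.
#' @examples
#' pearson(1:10, (1:10) * 2 + 1)$statistic  # exactly 1
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  df <- n - 2
  p <- if (abs(r) == 1) 0 else 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  structure(list(statistic = r, df = df, p = p, n = n, method = "pearson"),
            class = "vhinet_test")
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA computed from the sums of squares:
#' F = MS_between / MS_within with (k - 1, n - k) degrees of freedom,
#' p from the upper tail of the F distribution. Agreement with
#' `anova(lm(...))` is part of the test suite.
#'
#' @param groups list of numeric vectors, one per group; at least two
#'   groups with at least two values each.
#' @return a `vhinet_test` list: `statistic` (F), `df` (length-2), `p`, `n`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least two values", call. = FALSE)
  n <- sum(sizes)
  all_vals <- unlist(groups, use.names = FALSE)
  grand <- mean(all_vals)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    stop("all observations identical: F undefined", call. = FALSE)
  }
  f <- if (ss_within == 0) Inf else (ss_between / df1) / (ss_within / df2)
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  structure(list(statistic = f, df = c(df1, df2), p = p, n = n, method = "anova"),
            class = "vhinet_test")
}

#' @export
print.vhinet_test <- function(x, ...) {
  if (x$method == "pearson") {
    cat(sprintf("Pearson r = %.4g, df = %d, p = %.4g (n = %d)\n",
                x$statistic, x$df, x$p, x$n))
  } else {
    cat(sprintf("one-way ANOVA F(%d, %d) = %.4g, p = %.4g (n = %d)\n",
                x$df[1], x$df[2], x$statistic, x$p, x$n))
  }
  invisible(x)
}

#' Split host strains by isolation period
#'
#' Partitions strains into those isolated before `cutoff_year` ("older")
#' and those isolated in or after it ("younger"); the cutoff year itself
#' belongs to the younger group. Strains without a recorded year are
#' excluded and reported.
#'
#' @param metadata a strain metadata table ([read_metadata()]).
#' @param cutoff_year boundary year (default 2009).
#' @param role restrict to one role (default `"host"`).
#' @return list with character vectors `older`, `younger`, `unknown`.
#' @export
split_by_year <- function(metadata, cutoff_year = 2009, role = "host") {
  md <- metadata[metadata$role == role, ]
  yr <- md$isolation_year
  out <- list(older = md$strain_id[!is.na(yr) & yr < cutoff_year],
              younger = md$strain_id[!is.na(yr) & yr >= cutoff_year],
              unknown = md$strain_id[is.na(yr)])
  if (length(out$older) == 0 || length(out$younger) == 0) {
    warning("empty isolation-period group at cutoff ", cutoff_year, call. = FALSE)
  }
  out
}

# the declarative screen battery: each entry names a comparison, the test,
# and how to pull its inputs from the phenotype table / metadata
screen_battery <- function(k) {
  list(
    list(name = "R1_vs_mu", test = "pearson",
         pull = function(ph, groups) list(ph$hosts$R1, ph$hosts$mu)),
    list(name = "R2_vs_mu", test = "pearson",
         pull = function(ph, groups) list(ph$hosts$R2, ph$hosts$mu)),
    list(name = "Vp_vs_R1", test = "pearson",
         pull = function(ph, groups) list(ph$hosts$avg_vp_host, ph$hosts$R1)),
    list(name = "maxVp_vs_R2", test = "pearson",
         pull = function(ph, groups) list(ph$hosts$max_vp_host, ph$hosts$R2)),
    list(name = "Vp_vs_mu", test = "pearson",
         pull = function(ph, groups) list(ph$hosts$avg_vp_host, ph$hosts$mu)),
    list(name = "generalist_vs_specialist_Vp", test = "anova",
         pull = function(ph, groups) {
           split <- split_generalists_specialists(
             setNames(ph$viruses$host_range, ph$viruses$virus_id), k)
           v <- setNames(ph$viruses$avg_vp, ph$viruses$virus_id)
           list(list(v[split$generalists], v[split$specialists]))
         }),
    list(name = "maxVp_by_year", test = "anova", var = "max_vp_host"),
    list(name = "mu_by_year", test = "anova", var = "mu"),
    list(name = "R1_by_year", test = "anova", var = "R1"),
    list(name = "R2_by_year", test = "anova", var = "R2")
  )
}

#' Run the full association screen
#'
#' Runs the study's battery of comparisons on a phenotype table: Pearson
#' correlations R1~mu, R2~mu, Vp~R1, maxVp~R2, Vp~mu; a one-way ANOVA of
#' mean viral production between the k most generalist and k most
#' specialist viruses; and, when metadata is supplied, one-way ANOVAs of
#' maxVp, mu, R1 and R2 between strains isolated before and since
#' `cutoff_year`.
#'
#' @param phenotypes a [phenotype_table()].
#' @param metadata optional strain metadata (for the isolation-period ANOVAs).
#' @param cutoff_year isolation-period boundary (default 2009).
#' @param k generalist/specialist group size (default 5).
#' @return tibble with columns `comparison`, `test`, `statistic`, `df1`,
#'   `df2`, `p`, `n`.
#' @export
screen <- function(phenotypes, metadata = NULL, cutoff_year = 2009, k = 5) {
  groups <- if (!is.null(metadata)) split_by_year(metadata, cutoff_year) else NULL
  rows <- list()
  for (item in screen_battery(k)) {
    if (!is.null(item$var)) {  # isolation-period ANOVA
      if (is.null(groups)) next
      v <- setNames(phenotypes$hosts[[item$var]], phenotypes$hosts$host_id)
      res <- tryCatch(one_way_anova(list(v[names(v) %in% groups$older],
                                         v[names(v) %in% groups$younger])),
                      error = function(e) NULL)
    } else {
      inputs <- item$pull(phenotypes, groups)
      res <- tryCatch(
        if (item$test == "pearson") pearson(inputs[[1]], inputs[[2]])
        else one_way_anova(inputs[[1]]),
        error = function(e) NULL)
    }
    if (is.null(res)) next
    rows[[item$name]] <- tibble::tibble(
      comparison = item$name, test = res$method,
      statistic = res$statistic,
      df1 = res$df[1], df2 = if (length(res$df) > 1) res$df[2] else NA_real_,
      p = res$p, n = res$n)
  }
  dplyr::bind_rows(rows)
}
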