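# Rank-based two-group tests, multiplicity correction, normality screening
# and the order-level phylogenetic-signal screen.

#' Mann-Whitney U test
#'
#' U is computed from midranks as U = R1 - n1(n1+1)/2, the number of (a, b)
#' pairs with a > b (ties counted 1/2). Small tie-free samples
#' (n1 + n2 <= `exactness_threshold`) use the exact null distribution of U;
#' otherwise a normal approximation with tie correction and, by default, a
#' 0.5 continuity correction is used. Two-sided p is twice the smaller tail,
#' capped at 1.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative `"two_sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` auto-selects.
#' @param correct apply the continuity correction on the approximate path.
#' @param exactness_threshold maximum n1 + n2 for the exact path.
#' @return A `rank_test` list: `u_statistic`, `n1`, `n2`, `alternative`,
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 2/20
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two_sided", "greater", "less"),
                         exact = NULL, correct = TRUE,
                         exactness_threshold = 20) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- (n <= exactness_threshold) && !ties
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  if (exact) {
    p_greater <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p_less <- stats::pwilcox(u, n1, n2)
    p <- switch(alternative,
      two_sided = min(1, 2 * min(p_greater, p_less)),
      greater = p_greater,
      less = p_less
    )
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      # all observations identical: no evidence either way
      return(structure(list(u_statistic = u, n1 = n1, n2 = n2,
                            alternative = alternative, p_value = 1,
                            method = "normal_approx"),
                       class = "rank_test"))
    }
    cc <- if (correct) {
      switch(alternative,
        two_sided = sign(u - mu) * 0.5,
        greater = 0.5,
        less = -0.5
      )
    } else 0
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- switch(alternative,
      two_sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    p <- min(1, p)
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, n1 = n1, n2 = n2,
                 alternative = alternative, p_value = p, method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, n = (%d, %d), p = %.4g [%s]\n",
              x$alternative, x$u_statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' One-tailed migratory vs non-migratory comparison
#'
#' For metabolic rate and gill area the direction migratory > non-migratory
#' is fixed a priori (routine and maximum metabolic rates correlate, and
#' active species carry larger gills), so the one-tail Mann-Whitney test is
#' applied with `alternative = "greater"` for the migratory sample.
#'
#' @param m_values trait values of migratory species.
#' @param nm_values trait values of non-migratory species.
#' @param ... passed to [mann_whitney()].
#' @return A `rank_test` result.
#' @export
compare_migratory <- function(m_values, nm_values, ...) {
  mann_whitney(m_values, nm_values, alternative = "greater", ...)
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the number of tests `m` and capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param m number of tests; defaults to `length(p_values)` and must be at
#'   least that.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("m must be at least the number of p-values", call. = FALSE)
  }
  pmin(1, p_values * m)
}

#' Shapiro-Wilk normality screen
#'
#' Used to justify the nonparametric/bootstrap path when trait
#' distributions are right-skewed.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `statistic` (W) and `p_value`.
#' @export
normality_screen <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) {
    stop("normality screen needs at least 3 observations", call. = FALSE)
  }
  if (length(values) > 5000) {
    stop("normality screen supports at most 5000 observations", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Order-level phylogenetic-signal screen
#'
#' Groups species at the taxonomic-order level and tests every pair of
#' sufficiently large orders with a two-sided Mann-Whitney test, Bonferroni
#' corrected over the number of pairs. The verdict is `"no signal"` iff no
#' adjusted p-value falls below `alpha`; orders below the minimum size are
#' summarized but not tested; fewer than two testable orders yields
#' `"untestable"`. Per-order summaries (n, median, quartiles, range) are
#' emitted for box-plot rendering.
#'
#' @param dataset a `trait_dataset`.
#' @param min_n minimum order size to enter pairwise testing (default 3).
#' @param alpha significance level applied to adjusted p-values.
#' @return list with `summaries` (data.frame), `pairwise` (data.frame of
#'   order1, order2, u, p, p_adjusted or NULL), `verdict`.
#' @export
phylo_signal_screen <- function(dataset, min_n = 3, alpha = 0.05) {
  stopifnot(inherits(dataset, "trait_dataset"))
  rec <- dataset$records
  by_order <- split(rec$value, rec$order)
  summaries <- do.call(rbind, lapply(names(by_order), function(o) {
    v <- by_order[[o]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(order = o, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               min = min(v), max = max(v), tested = length(v) >= min_n,
               stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL
  testable <- names(by_order)[lengths(by_order) >= min_n]
  if (length(testable) < 2) {
    return(list(summaries = summaries, pairwise = NULL,
                verdict = "untestable"))
  }
  pairs <- utils::combn(testable, 2)
  pw <- data.frame(
    order1 = pairs[1, ], order2 = pairs[2, ],
    u = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs))) {
    tst <- mann_whitney(by_order[[pairs[1, i]]], by_order[[pairs[2, i]]],
                        alternative = "two_sided")
    pw$u[i] <- tst$u_statistic
    pw$p[i] <- tst$p_value
  }
  pw$p_adjusted <- bonferroni_adjust(pw$p, m = nrow(pw))
  verdict <- if (any(pw$p_adjusted < alpha)) "signal" else "no signal"
  list(summaries = summaries, pairwise = pw, verdict = verdict)
}
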