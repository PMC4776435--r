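# Two-way factorial ANOVA (salinity x migration) with a nonparametric
# bootstrap assessment of the main and interaction effects.

#' Construct a two-way factorial design
#'
#' @param response numeric trait values.
#' @param factor_a salinity labels (`"FW"` / `"SW"`).
#' @param factor_b migration labels (`"NM"` / `"M"`).
#' @return A `factorial_design` list; empty cells are allowed and flagged
#'   downstream.
#' @export
factorial_design <- function(response, factor_a, factor_b) {
  response <- as.numeric(response)
  stopifnot(length(response) == length(factor_a),
            length(response) == length(factor_b))
  if (any(!is.finite(response))) {
    stop("response contains non-finite values", call. = FALSE)
  }
  if (length(response) < 2) {
    stop("need at least 2 observations", call. = FALSE)
  }
  structure(list(response = response,
                 factor_a = as.character(factor_a),
                 factor_b = as.character(factor_b)),
            class = "factorial_design")
}

# Orthonormal bases and ranks for the nested model matrices of ~ A * B,
# built with sum-to-zero contrasts so that Type III comparisons are valid.
.design_bases <- function(design) {
  d <- data.frame(A = factor(design$factor_a), B = factor(design$factor_b))
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  X_full <- stats::model.matrix(~ A * B, d)
  asgn <- attr(X_full, "assign") # 0 = intercept, 1 = A, 2 = B, 3 = A:B
  pick <- function(keep) X_full[, asgn %in% keep, drop = FALSE]
  qbase <- function(X) {
    qx <- qr(X)
    list(Q = qr.Q(qx)[, seq_len(qx$rank), drop = FALSE], rank = qx$rank)
  }
  list(
    m1    = qbase(pick(0)),
    mA    = qbase(pick(c(0, 1))),
    mB    = qbase(pick(c(0, 2))),
    mAB   = qbase(pick(c(0, 1, 2))),
    mfull = qbase(X_full),
    mnoA  = qbase(pick(c(0, 2, 3))),
    mnoB  = qbase(pick(c(0, 1, 3))),
    n     = nrow(X_full),
    cells = table(d$A, d$B)
  )
}

# Residual sums of squares of each observation-column of Y under the model
# spanned by the orthonormal basis Q.
.rss_cols <- function(Q, Y) {
  pmax(0, colSums(Y^2) - colSums(crossprod(Q, Y)^2))
}

# F statistics for every column of Y under a fixed design. Returns a list
# of numeric vectors f_a, f_b, f_ab (NA where a term is not estimable,
# NaN where the error variance vanishes) plus the df bookkeeping.
.f_stats_cols <- function(bases, Y, ss_type) {
  rss <- lapply(bases[c("m1", "mA", "mB", "mAB", "mfull", "mnoA", "mnoB")],
                function(m) .rss_cols(m$Q, Y))
  rk <- vapply(bases[c("m1", "mA", "mB", "mAB", "mfull", "mnoA", "mnoB")],
               function(m) m$rank, numeric(1))
  ss_err <- rss[["mfull"]]
  df_err <- bases$n - rk[["mfull"]]
  comp <- switch(ss_type,
    I = list(
      a  = list(ss = rss[["m1"]] - rss[["mA"]],  df = rk[["mA"]] - rk[["m1"]]),
      b  = list(ss = rss[["mA"]] - rss[["mAB"]], df = rk[["mAB"]] - rk[["mA"]]),
      ab = list(ss = rss[["mAB"]] - rss[["mfull"]],
                df = rk[["mfull"]] - rk[["mAB"]])
    ),
    II = list(
      a  = list(ss = rss[["mB"]] - rss[["mAB"]], df = rk[["mAB"]] - rk[["mB"]]),
      b  = list(ss = rss[["mA"]] - rss[["mAB"]], df = rk[["mAB"]] - rk[["mA"]]),
      ab = list(ss = rss[["mAB"]] - rss[["mfull"]],
                df = rk[["mfull"]] - rk[["mAB"]])
    ),
    III = list(
      a  = list(ss = rss[["mnoA"]] - rss[["mfull"]],
                df = rk[["mfull"]] - rk[["mnoA"]]),
      b  = list(ss = rss[["mnoB"]] - rss[["mfull"]],
                df = rk[["mfull"]] - rk[["mnoB"]]),
      ab = list(ss = rss[["mAB"]] - rss[["mfull"]],
                df = rk[["mfull"]] - rk[["mAB"]])
    )
  )
  fstat <- function(eff) {
    if (eff$df < 1 || df_err < 1) return(rep(NA_real_, ncol(Y)))
    out <- (pmax(0, eff$ss) / eff$df) / (ss_err / df_err)
    out[ss_err == 0] <- NaN
    out
  }
  list(
    f_a = fstat(comp$a), f_b = fstat(comp$b), f_ab = fstat(comp$ab),
    ss = list(a = comp$a$ss, b = comp$b$ss, ab = comp$ab$ss, error = ss_err),
    df = list(a = comp$a$df, b = comp$b$df, ab = comp$ab$df, error = df_err)
  )
}

#' Two-way ANOVA F statistics
#'
#' Computes the F statistics of the two main effects and their interaction
#' for a (possibly unbalanced) 2x2 design, by residual-sum-of-squares
#' comparisons of nested least-squares fits built with sum-to-zero
#' contrasts. Type II (order-invariant for main effects, the default for
#' unbalanced data), Type I (sequential A, B, A:B) and Type III (drop each
#' term from the full model) sums of squares are available; all three
#' coincide on balanced designs.
#'
#' @param design a [factorial_design()].
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @return list with `f_a`, `f_b`, `f_ab` (NA where not estimable, NaN when
#'   the error variance is zero), `ss`, `df`, `ss_type`, `empty_cells`.
#' @export
anova_f <- function(design, ss_type = c("II", "I", "III")) {
  ss_type <- match.arg(ss_type)
  stopifnot(inherits(design, "factorial_design"))
  bases <- .design_bases(design)
  empty <- sum(bases$cells == 0L)
  if (empty > 0L && ss_type == "III") {
    stop("Type III sums of squares are undefined with empty cells",
         call. = FALSE)
  }
  if (bases$n - bases$mfull$rank < 1) {
    stop("error degrees of freedom < 1: the full model is saturated",
         call. = FALSE)
  }
  res <- .f_stats_cols(bases, matrix(design$response, ncol = 1), ss_type)
  out <- list(
    f_a = res$f_a[1], f_b = res$f_b[1], f_ab = res$f_ab[1],
    ss = lapply(res$ss, `[`, 1), df = res$df,
    ss_type = ss_type, empty_cells = empty
  )
  if (any(vapply(out[c("f_a", "f_b", "f_ab")],
                 function(f) is.nan(f), logical(1)))) {
    warning("zero error variance: F statistic undefined (NaN)",
            call. = FALSE)
  }
  if (empty > 0L && (is.na(out$f_ab) || res$df$ab < 1)) {
    warning("empty cell(s): interaction not estimable, skipped",
            call. = FALSE)
  }
  out
}

#' Bootstrap null distributions of the ANOVA F statistics
#'
#' The default scheme draws each resample with replacement from the pooled
#' observed responses while the factor labels stay fixed (a global
#' exchangeability null), recomputing all three F statistics per resample.
#' An alternative residual scheme (`scheme = "residual"`) resamples
#' full-model residuals onto the per-effect null-model fits. Degenerate
#' resamples with zero error variance yield NaN and are excluded (and
#' counted) by [bootstrap_pvalue()].
#'
#' @param design a [factorial_design()].
#' @param b number of resamples (default 1000).
#' @param seed integer seed; recorded for reproducibility.
#' @param ss_type sums-of-squares type, as in [anova_f()].
#' @param scheme `"pooled"` (default) or `"residual"`.
#' @return list with `null_f_a`, `null_f_b`, `null_f_ab` (length `b`),
#'   `b`, `seed`, `scheme`.
#' @export
bootstrap_null <- function(design, b = 1000, seed = NULL,
                           ss_type = c("II", "I", "III"),
                           scheme = c("pooled", "residual")) {
  ss_type <- match.arg(ss_type)
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "factorial_design"), b >= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- .design_bases(design)
  y <- design$response
  n <- length(y)
  if (scheme == "pooled") {
    Y <- matrix(sample(y, n * b, replace = TRUE), nrow = n, ncol = b)
    res <- .f_stats_cols(bases, Y, ss_type)
    nulls <- list(a = res$f_a, b = res$f_b, ab = res$f_ab)
  } else {
    # residual scheme: per effect, resample full-model residuals onto the
    # fit of the model lacking that effect
    resid_full <- y - bases$mfull$Q %*% crossprod(bases$mfull$Q, y)
    null_fit <- list(
      a  = bases$mnoA$Q %*% crossprod(bases$mnoA$Q, y),
      b  = bases$mnoB$Q %*% crossprod(bases$mnoB$Q, y),
      ab = bases$mAB$Q %*% crossprod(bases$mAB$Q, y)
    )
    resample_on <- function(fit) {
      matrix(sample(resid_full, n * b, replace = TRUE),
             nrow = n, ncol = b) + as.numeric(fit)
    }
    nulls <- list(
      a  = .f_stats_cols(bases, resample_on(null_fit$a), ss_type)$f_a,
      b  = .f_stats_cols(bases, resample_on(null_fit$b), ss_type)$f_b,
      ab = .f_stats_cols(bases, resample_on(null_fit$ab), ss_type)$f_ab
    )
  }
  list(null_f_a = nulls$a, null_f_b = nulls$b, null_f_ab = nulls$ab,
       b = b, seed = seed, scheme = scheme)
}

#' Bootstrap p-value by the indicator count
#'
#' p = (number of resampled F values strictly greater than the observed F)
#' divided by the number of valid resamples, following the indicator-count
#' definition. NaN resamples (zero error variance) are excluded from both
#' numerator and denominator and counted in the `n_excluded` attribute.
#' When p = 0 the attainable bound is attached as attribute
#' `bound = "< 1/B"`. An optional add-one correction (r+1)/(B+1) is
#' available but off by default.
#'
#' @param observed_f observed F statistic.
#' @param null_f numeric vector of bootstrap F statistics.
#' @param add_one use the (r+1)/(B+1) correction.
#' @return The p-value, with attributes `n_valid`, `n_excluded` and
#'   (when p = 0) `bound`.
#' @export
bootstrap_pvalue <- function(observed_f, null_f, add_one = FALSE) {
  valid <- null_f[is.finite(null_f)]
  n_excluded <- length(null_f) - length(valid)
  if (n_excluded > 0) {
    message(n_excluded, " degenerate resample(s) excluded from the p-value")
  }
  if (!length(valid)) {
    stop("no valid bootstrap resamples", call. = FALSE)
  }
  if (!is.finite(observed_f)) {
    p <- NA_real_
  } else {
    r <- sum(valid > observed_f)
    p <- if (add_one) (r + 1) / (length(valid) + 1) else r / length(valid)
  }
  attr(p, "n_valid") <- length(valid)
  attr(p, "n_excluded") <- n_excluded
  if (isTRUE(as.numeric(p) == 0)) {
    attr(p, "bound") <- paste0("< 1/", length(valid))
  }
  p
}

#' Run the full bootstrap two-way ANOVA on a trait dataset
#'
#' Classifies the dataset (if needed), assembles the salinity x migration
#' factorial design, computes the observed F statistics and assesses them
#' against `b` bootstrap resamples. With an empty cell the interaction is
#' not estimable and is skipped with a warning.
#'
#' @param dataset a `trait_dataset` (classified or not).
#' @param b number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param ss_type sums-of-squares type (default `"II"`).
#' @param scheme bootstrap scheme, see [bootstrap_null()].
#' @return An `anova_result` list: observed F and df per effect, null
#'   distributions, p-values (`p_a`, `p_b`, `p_ab`), `b`, `seed`,
#'   `ss_type`, `n_excluded` per effect.
#' @export
run_two_way <- function(dataset, b = 1000, seed = 1,
                        ss_type = c("II", "I", "III"),
                        scheme = c("pooled", "residual")) {
  ss_type <- match.arg(ss_type)
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "trait_dataset"))
  if (is.null(dataset$records$group4)) dataset <- classify_dataset(dataset)
  rec <- dataset$records
  design <- factorial_design(rec$value, rec$salinity_class,
                             rec$migration_class)
  observed <- anova_f(design, ss_type)
  nulls <- bootstrap_null(design, b = b, seed = seed, ss_type = ss_type,
                          scheme = scheme)
  pv <- function(obs, nl) {
    if (is.na(obs)) return(NA_real_)
    bootstrap_pvalue(obs, nl)
  }
  structure(list(
    f_a = observed$f_a, f_b = observed$f_b, f_ab = observed$f_ab,
    df = observed$df, ss_type = ss_type, b_resamples = b, seed = seed,
    null_f_a = nulls$null_f_a, null_f_b = nulls$null_f_b,
    null_f_ab = nulls$null_f_ab,
    p_a = pv(observed$f_a, nulls$null_f_a),
    p_b = pv(observed$f_b, nulls$null_f_b),
    p_ab = pv(observed$f_ab, nulls$null_f_ab),
    empty_cells = observed$empty_cells
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Bootstrap two-way ANOVA (Type %s SS, B = %d, seed = %s)\n",
              x$ss_type, x$b_resamples, format(x$seed)))
  eff <- data.frame(
    effect = c("salinity", "migration", "interaction"),
    F = c(x$f_a, x$f_b, x$f_ab),
    df = c(x$df$a, x$df$b, x$df$ab),
    p_bootstrap = c(as.numeric(x$p_a), as.numeric(x$p_b), as.numeric(x$p_ab))
  )
  print(eff, row.names = FALSE)
  invisible(x)
}
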