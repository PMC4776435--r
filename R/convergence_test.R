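# Cross-variable convergence: does the same ecological group attain the
# highest median across several independent trait datasets?

#' Group with the highest median
#'
#' Ties at the maximum median are reported as a tie with no winner
#' (conservative: a tie never counts as a match downstream).
#'
#' @param groups named list of numeric vectors (one per group, all
#'   non-empty).
#' @return list with `group` (name, or `NA` on tie), `tie` (logical) and
#'   `medians` (named numeric).
#' @export
top_group <- function(groups) {
  if (!length(groups) || is.null(names(groups))) {
    stop("groups must be a non-empty named list", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) {
    stop("empty group(s): ",
         paste(names(groups)[lengths(groups) == 0L], collapse = ", "),
         call. = FALSE)
  }
  meds <- vapply(groups, stats::median, numeric(1))
  at_max <- which(meds == max(meds))
  if (length(at_max) > 1L) {
    list(group = NA_character_, tie = TRUE, medians = meds)
  } else {
    list(group = names(meds)[at_max], tie = FALSE, medians = meds)
  }
}

#' Exact convergence probability under exchangeability
#'
#' With g exchangeable groups and k independent variables, the chance that
#' a prespecified group tops every variable is (1/g)^k; the chance that
#' some single group does is g * (1/g)^k.
#'
#' @param g number of groups (>= 2).
#' @param k number of independent variables (>= 1).
#' @param focal `"prespecified"` or `"any"`.
#' @return The exact probability.
#' @examples
#' exact_convergence_p(4, 3)            # (1/4)^3 = 0.015625
#' exact_convergence_p(4, 3, "any")     # 4 * (1/4)^3 = 0.0625
#' @export
exact_convergence_p <- function(g, k, focal = c("prespecified", "any")) {
  focal <- match.arg(focal)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (k < 1) stop("need at least 1 variable", call. = FALSE)
  p <- (1 / g)^k
  if (focal == "any") p <- g * p
  p
}

#' Permutation estimate of the convergence probability
#'
#' For each permutation, group labels are shuffled independently within
#' each variable (preserving the observed group sizes) and the top-median
#' group recomputed. The p-value is the fraction of permutations in which
#' the focal group (or, for `focal_group = "any"`, one and the same group)
#' tops every variable; ties at the top count as non-matches. With equal
#' group sizes this estimate converges to [exact_convergence_p()].
#'
#' @param datasets list of named lists of numeric vectors: one
#'   group-to-values mapping per variable, all sharing the same group
#'   names.
#' @param focal_group a group name, or `"any"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return The permutation p-value, with attribute `n_perm`.
#' @export
permutation_convergence_p <- function(datasets, focal_group = "any",
                                      n_perm = 10000, seed = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1, n_perm >= 1)
  group_names <- names(datasets[[1]])
  for (d in datasets) {
    if (!identical(names(d), group_names)) {
      stop("all datasets must share the same group labels, in order",
           call. = FALSE)
    }
  }
  if (!identical(focal_group, "any") && !focal_group %in% group_names) {
    stop("unknown focal group: ", focal_group, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pooled <- lapply(datasets, function(d) unlist(d, use.names = FALSE))
  sizes <- lapply(datasets, lengths)
  idx <- lapply(sizes, function(sz) rep(seq_along(sz), sz))
  g <- length(group_names)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    tops <- integer(length(datasets))
    for (v in seq_along(datasets)) {
      shuffled <- pooled[[v]][sample.int(length(pooled[[v]]))]
      meds <- vapply(seq_len(g), function(j) {
        stats::median(shuffled[idx[[v]] == j])
      }, numeric(1))
      at_max <- which(meds == max(meds))
      tops[v] <- if (length(at_max) == 1L) at_max else 0L # 0 marks a tie
    }
    ok <- if (identical(focal_group, "any")) {
      tops[1] != 0L && all(tops == tops[1])
    } else {
      all(tops == match(focal_group, group_names))
    }
    if (ok) hits <- hits + 1L
  }
  out <- hits / n_perm
  attr(out, "n_perm") <- n_perm
  out
}

#' Convergence test across independent trait datasets
#'
#' Identifies the top-median group of each variable, checks whether all
#' variables crown the same group (the focal one if prespecified), and
#' reports the exact exchangeability probabilities for both the
#' prespecified-group and any-group variants together with an optional
#' permutation estimate. All three numbers are printed side by side; none
#' is privileged.
#'
#' @param datasets list of named lists of numeric vectors, one per
#'   variable (e.g. MR, Gill, GC group partitions); may be named.
#' @param focal_group a group name (e.g. `"SWM"`), or `"any"`.
#' @param n_perm permutations for the empirical check; 0 disables it.
#' @param seed integer seed for the permutation step.
#' @return A `convergence_result` list: `observed_top` (per variable),
#'   `all_match`, `p_exact_prespecified`, `p_exact_any`, `p_permutation`,
#'   `n_permutations`, `focal_group`.
#' @export
convergence_test <- function(datasets, focal_group = "SWM", n_perm = 10000,
                             seed = 1) {
  tops <- lapply(datasets, top_group)
  observed <- vapply(tops, function(t) {
    if (t$tie) NA_character_ else t$group
  }, character(1))
  if (is.null(names(observed))) {
    names(observed) <- paste0("variable_", seq_along(observed))
  }
  g <- length(datasets[[1]])
  k <- length(datasets)
  all_match <- if (identical(focal_group, "any")) {
    !anyNA(observed) && length(unique(observed)) == 1L
  } else {
    !anyNA(observed) && all(observed == focal_group)
  }
  p_perm <- NULL
  if (n_perm > 0) {
    p_perm <- permutation_convergence_p(datasets, focal_group, n_perm, seed)
  }
  structure(list(
    observed_top = observed,
    all_match = all_match,
    focal_group = focal_group,
    p_exact_prespecified = exact_convergence_p(g, k, "prespecified"),
    p_exact_any = exact_convergence_p(g, k, "any"),
    p_permutation = if (is.null(p_perm)) NA_real_ else as.numeric(p_perm),
    n_permutations = n_perm,
    medians = lapply(tops, `[[`, "medians")
  ), class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("Cross-variable convergence test\n")
  cat("  top group per variable: ",
      paste(names(x$observed_top), x$observed_top, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  all match (focal = %s): %s\n", x$focal_group,
              x$all_match))
  cat(sprintf("  exact p (prespecified group): %.6g\n",
              x$p_exact_prespecified))
  cat(sprintf("  exact p (any single group):   %.6g\n", x$p_exact_any))
  if (x$n_permutations > 0) {
    cat(sprintf("  permutation p (%d perms):     %.6g\n",
                x$n_permutations, x$p_permutation))
  }
  invisible(x)
}
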