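# Orchestration: classify -> normalize -> compare -> ANOVA -> convergence
# -> expression, with logging and a single reproducible report.

#' Build and validate a run configuration
#'
#' @param traits named list (any subset of `MR`, `Gill`, `GC`) of input
#'   TSV paths or in-memory `trait_dataset`s.
#' @param exclusions species names to discard; [default_exclusions()] by
#'   default; `character(0)` disables exclusion.
#' @param boltzmann a [boltzmann_params()].
#' @param anova list of settings: `b` resamples, `seed`, `ss_type`.
#' @param convergence list of settings: `focal`, `n_perm`, `seed`.
#' @param expression `NULL`, or a list with `fasta` and `expr` paths (or
#'   in-memory tables), `cutpoints` (3 ascending GC-percent limits,
#'   required: no genome-specific defaults are assumed) and `main_bins`.
#' @param out_dir optional output directory for [write_report()].
#' @return A `run_config` list.
#' @export
run_config <- function(traits,
                       exclusions = default_exclusions(),
                       boltzmann = boltzmann_params(),
                       anova = list(b = 1000, seed = 1, ss_type = "II"),
                       convergence = list(focal = "SWM", n_perm = 10000,
                                          seed = 1),
                       expression = NULL,
                       out_dir = NULL) {
  stopifnot(is.list(traits), length(traits) >= 1,
            all(names(traits) %in% c("MR", "Gill", "GC")))
  for (v in names(traits)) {
    x <- traits[[v]]
    if (is.character(x) && !file.exists(x)) {
      stop("input path for ", v, " does not exist: ", x, call. = FALSE)
    }
    if (!is.character(x) && !inherits(x, "trait_dataset")) {
      stop("traits$", v, " must be a file path or a trait_dataset",
           call. = FALSE)
    }
  }
  anova <- utils::modifyList(list(b = 1000, seed = 1, ss_type = "II"), anova)
  convergence <- utils::modifyList(
    list(focal = "SWM", n_perm = 10000, seed = 1), convergence)
  if (!is.null(expression)) {
    if (is.null(expression$cutpoints)) {
      stop("expression analysis requires explicit isochore GC cutpoints",
           call. = FALSE)
    }
    expression <- utils::modifyList(list(main_bins = c("H1", "H2")),
                                    expression)
  }
  structure(list(traits = traits, exclusions = exclusions,
                 boltzmann = boltzmann, anova = anova,
                 convergence = convergence, expression = expression,
                 out_dir = out_dir),
            class = "run_config")
}

.config_hash <- function(config) {
  describable <- list(
    traits = lapply(config$traits, function(x) {
      if (is.character(x)) x else paste0("in-memory:", x$provenance)
    }),
    exclusions = config$exclusions,
    boltzmann = unclass(config$boltzmann),
    anova = config$anova,
    convergence = config$convergence,
    expression = if (is.null(config$expression)) NULL else
      config$expression[c("cutpoints", "main_bins")]
  )
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(describable, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full comparative analysis
#'
#' Executes, per available trait variable: reading, exclusion of
#' conflicting species, ecological classification, Boltzmann
#' ln-normalization (MR only), group medians, FW-vs-SW and M-vs-NM
#' Mann-Whitney comparisons (one-tailed migratory > non-migratory for MR
#' and Gill, the directional hypotheses fixed a priori; two-sided
#' elsewhere), and the bootstrap two-way ANOVA. Across variables it runs
#' the cross-variable convergence test, and, when configured, the
#' CDS-by-isochore expression analysis. Record counts in and out of every
#' filter are logged so dataset sizes are auditable.
#'
#' @param config a [run_config()].
#' @return A `report_bundle` list: `medians`, `two_group`, `anova`,
#'   `convergence`, `expression`, `log`, `meta`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  vars <- names(config$traits)
  datasets <- list()
  log <- list()
  for (v in vars) {
    x <- config$traits[[v]]
    ds <- if (is.character(x)) {
      read_trait_table(x, variable = v)
    } else x
    n_read <- nrow(ds$records)
    ds <- suppressWarnings(apply_exclusions(ds, config$exclusions))
    n_excluded <- if (is.null(attr(ds, "n_excluded"))) 0L else
      attr(ds, "n_excluded")
    ds <- classify_dataset(ds)
    if (v == "MR" && !isTRUE(attr(ds, "normalized"))) {
      ds <- normalize_mr(ds, config$boltzmann)
    }
    datasets[[v]] <- ds
    log[[v]] <- list(n_read = n_read, n_excluded = n_excluded,
                     n_final = nrow(ds$records))
  }

  groups4 <- lapply(datasets, partition_groups, mode = "four_way")

  medians <- do.call(rbind, lapply(c("FWNM", "FWM", "SWNM", "SWM"),
    function(g) {
      row <- data.frame(group = g, stringsAsFactors = FALSE)
      for (v in vars) row[[v]] <- stats::median(groups4[[v]][[g]])
      row
    }))

  two_group <- lapply(stats::setNames(vars, vars), function(v) {
    sal <- partition_groups(datasets[[v]], "salinity")
    mig <- partition_groups(datasets[[v]], "migration")
    mig_test <- if (v %in% c("MR", "Gill")) {
      compare_migratory(mig$M, mig$NM)
    } else {
      mann_whitney(mig$M, mig$NM, alternative = "two_sided")
    }
    list(
      fw_vs_sw = mann_whitney(sal$SW, sal$FW, alternative = "two_sided"),
      m_vs_nm = mig_test,
      n = list(FW = length(sal$FW), SW = length(sal$SW),
               NM = length(mig$NM), M = length(mig$M))
    )
  })

  anova <- lapply(stats::setNames(seq_along(vars), vars), function(i) {
    run_two_way(datasets[[vars[i]]], b = config$anova$b,
                seed = config$anova$seed + i - 1,
                ss_type = config$anova$ss_type)
  })

  convergence <- convergence_test(groups4,
                                  focal_group = config$convergence$focal,
                                  n_perm = config$convergence$n_perm,
                                  seed = config$convergence$seed)

  expression <- NULL
  if (!is.null(config$expression)) {
    ex <- config$expression
    cds <- if (is.character(ex$fasta)) read_cds_fasta(ex$fasta) else ex$fasta
    n_cds_read <- nrow(cds)
    flt <- filter_cds(cds)
    expr_tab <- if (is.character(ex$expr)) {
      utils::read.delim(ex$expr, stringsAsFactors = FALSE)
    } else ex$expr
    kept <- merge(flt$kept, expr_tab, by = "cds_id")
    kept <- assign_bins(kept, isochore_binning(ex$cutpoints))
    expression <- list(
      tests = expression_by_bin(kept, main_bins = ex$main_bins),
      n_read = n_cds_read, n_kept = nrow(flt$kept),
      n_with_expression = nrow(kept),
      rejections = table(flt$rejected$reason)
    )
    log$expression <- list(n_read = n_cds_read, n_kept = nrow(flt$kept),
                           n_with_expression = nrow(kept))
  }

  report <- structure(list(
    medians = medians,
    two_group = two_group,
    anova = anova,
    convergence = convergence,
    expression = expression,
    log = log,
    meta = list(
      package_version = as.character(utils::packageVersion("ecogc")),
      config_hash = .config_hash(config),
      anova_seed = config$anova$seed,
      convergence_seed = config$convergence$seed
    )
  ), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Render the four-group medians table
#'
#' Four groups (FWNM, FWM, SWNM, SWM) by the three variables in the fixed
#' column order Gill (cm^2 g^-1), MR (ln), GC (%), rounded to 2 decimals
#' for display; a missing variable leaves an explicit NA column. Full
#' precision is retained in the report itself.
#'
#' @param report a `report_bundle`.
#' @param digits rounding for display (default 2).
#' @return data.frame with columns `group`, `Gill`, `MR`, `GC`.
#' @export
render_table1 <- function(report, digits = 2) {
  stopifnot(inherits(report, "report_bundle"))
  out <- data.frame(group = report$medians$group, stringsAsFactors = FALSE)
  for (v in c("Gill", "MR", "GC")) {
    out[[v]] <- if (v %in% names(report$medians)) {
      round(report$medians[[v]], digits)
    } else NA_real_
  }
  out
}

# report serialization without the bulky bootstrap null distributions
.report_as_list <- function(report) {
  slim_anova <- lapply(report$anova, function(a) {
    list(f_a = a$f_a, f_b = a$f_b, f_ab = a$f_ab, df = a$df,
         ss_type = a$ss_type, b_resamples = a$b_resamples, seed = a$seed,
         p_a = as.numeric(a$p_a), p_b = as.numeric(a$p_b),
         p_ab = as.numeric(a$p_ab), empty_cells = a$empty_cells)
  })
  slim_two_group <- lapply(report$two_group, function(t) {
    list(
      fw_vs_sw = t$fw_vs_sw[c("u_statistic", "n1", "n2", "alternative",
                              "p_value", "method")],
      m_vs_nm = t$m_vs_nm[c("u_statistic", "n1", "n2", "alternative",
                            "p_value", "method")],
      n = t$n
    )
  })
  conv <- unclass(report$convergence)
  expr <- report$expression
  if (!is.null(expr)) {
    expr$tests$pairwise <- expr$tests$pairwise[
      c("u_statistic", "n1", "n2", "alternative", "p_value", "method")]
    expr$rejections <- as.list(expr$rejections)
  }
  list(medians = report$medians, two_group = slim_two_group,
       anova = slim_anova, convergence = conv, expression = expr,
       log = report$log, meta = report$meta)
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (machine-readable, full precision), `report.md`
#' (human-readable summary) and per-table TSVs under `tables/`.
#'
#' @param report a `report_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "report_bundle"))
  dir.create(file.path(dir, "tables"), showWarnings = FALSE,
             recursive = TRUE)
  jsonlite::write_json(.report_as_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.table(report$medians,
                     file.path(dir, "tables", "group_medians.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  t1 <- render_table1(report)
  md <- c(
    "# ecogc analysis report", "",
    sprintf("Package version %s, config hash %s.",
            report$meta$package_version, report$meta$config_hash), "",
    "## Group medians (display rounding, 2 decimals)", "",
    paste(c("group", "Gill", "MR", "GC"), collapse = " | "),
    "--- | --- | --- | ---",
    apply(t1, 1, paste, collapse = " | "), "",
    "## Two-group comparisons", ""
  )
  for (v in names(report$two_group)) {
    t <- report$two_group[[v]]
    md <- c(md, sprintf(
      "- %s: FW vs SW p = %.4g (%s); NM vs M p = %.4g (%s)",
      v, t$fw_vs_sw$p_value, t$fw_vs_sw$alternative,
      t$m_vs_nm$p_value, t$m_vs_nm$alternative))
  }
  md <- c(md, "", "## Bootstrap two-way ANOVA", "")
  for (v in names(report$anova)) {
    a <- report$anova[[v]]
    md <- c(md, sprintf(
      "- %s: F(salinity) = %.3f p = %.4g; F(migration) = %.3f p = %.4g; F(interaction) = %.3f p = %.4g",
      v, a$f_a, as.numeric(a$p_a), a$f_b, as.numeric(a$p_b),
      a$f_ab, as.numeric(a$p_ab)))
  }
  cv <- report$convergence
  md <- c(md, "", "## Convergence", "",
          sprintf("- top groups: %s",
                  paste(names(cv$observed_top), cv$observed_top, sep = "=",
                        collapse = ", ")),
          sprintf("- all match (focal %s): %s", cv$focal_group,
                  cv$all_match),
          sprintf("- exact p prespecified = %.6g; exact p any = %.6g; permutation p = %.6g",
                  cv$p_exact_prespecified, cv$p_exact_any,
                  cv$p_permutation))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
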