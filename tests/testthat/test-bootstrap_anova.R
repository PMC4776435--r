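# Two-way factorial ANOVA and its bootstrap assessment.

balanced_toy <- function() {
  factorial_design(c(1, 2, 3, 4, 5, 6, 7, 8),
                   rep(c("FW", "SW"), each = 4),
                   rep(c("NM", "NM", "M", "M"), 2))
}

test_that("balanced 2x2 toy gives the hand-computed F statistics", {
  # SS_A = 32, SS_B = 8, SS_AB = 0, SS_err = 2 on 4 df -> F = 64, 16, 0
  for (type in c("I", "II", "III")) {
    a <- anova_f(balanced_toy(), type)
    expect_equal(a$f_a, 64)
    expect_equal(a$f_b, 16)
    expect_equal(a$f_ab, 0)
    expect_equal(a$df$error, 4)
  }
})

test_that("constant responses give zero SS and NaN F with a warning", {
  d <- factorial_design(rep(3.3, 8), rep(c("FW", "SW"), each = 4),
                        rep(c("NM", "NM", "M", "M"), 2))
  expect_warning(a <- anova_f(d), "zero error variance")
  expect_equal(a$ss$a, 0)
  expect_equal(a$ss$b, 0)
  expect_true(is.nan(a$f_a))
})

test_that("all SS types match the nested-least-squares oracle", {
  set.seed(31)
  for (i in 1:20) {
    n_per <- sample(2:7, 4, replace = TRUE)
    A <- rep(c("FW", "FW", "SW", "SW"), n_per)
    B <- rep(c("NM", "M", "NM", "M"), n_per)
    y <- rnorm(sum(n_per), mean = as.integer(factor(A)) +
                 0.5 * as.integer(factor(B)))
    d <- factorial_design(y, A, B)
    for (type in c("I", "II", "III")) {
      got <- anova_f(d, type)
      want <- anova_oracle(y, A, B, type)
      expect_equal(c(got$f_a, got$f_b, got$f_ab), unname(want),
                   tolerance = 1e-8)
    }
  }
})

test_that("SS types coincide on balanced designs", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    A <- rep(c("FW", "SW"), each = 2 * n)
    B <- rep(rep(c("NM", "M"), each = n), 2)
    d <- factorial_design(rnorm(4 * n), A, B)
    f1 <- anova_f(d, "I"); f2 <- anova_f(d, "II"); f3 <- anova_f(d, "III")
    expect_equal(c(f1$f_a, f1$f_b, f1$f_ab), c(f2$f_a, f2$f_b, f2$f_ab),
                 tolerance = 1e-8)
    expect_equal(c(f2$f_a, f2$f_b, f2$f_ab), c(f3$f_a, f3$f_b, f3$f_ab),
                 tolerance = 1e-8)
  }
})

test_that("empty cells: interaction skipped, Type III refuses", {
  d <- factorial_design(c(1, 2, 3, 4, 5, 6),
                        c("FW", "FW", "FW", "FW", "SW", "SW"),
                        c("NM", "NM", "M", "M", "NM", "NM"))
  expect_warning(a <- anova_f(d, "II"), "interaction not estimable")
  expect_true(is.na(a$f_ab))
  expect_false(is.na(a$f_a))
  expect_error(anova_f(d, "III"), "empty cells")
})

test_that("bootstrap_null honors count, seed determinism and structure", {
  d <- balanced_toy()
  one <- bootstrap_null(d, b = 1, seed = 5)
  expect_length(one$null_f_a, 1)
  n1 <- bootstrap_null(d, b = 50, seed = 9)
  n2 <- bootstrap_null(d, b = 50, seed = 9)
  expect_identical(n1, n2)
  n3 <- bootstrap_null(d, b = 50, seed = 10)
  expect_false(identical(n1$null_f_a, n3$null_f_a))
  # residual scheme runs and differs from the pooled scheme
  r1 <- bootstrap_null(d, b = 50, seed = 9, scheme = "residual")
  expect_length(r1$null_f_b, 50)
})

test_that("bootstrap_pvalue counts strict exceedances over valid resamples", {
  expect_equal(as.numeric(bootstrap_pvalue(5, c(1:4, 6:11))), 6 / 10)
  # strict inequality: equals do not count
  expect_equal(as.numeric(bootstrap_pvalue(3, c(3, 3, 4))), 1 / 3)
  # observed above all nulls: p = 0 with the attainable bound annotated
  p0 <- bootstrap_pvalue(99, c(1, 2, 3))
  expect_equal(as.numeric(p0), 0)
  expect_equal(attr(p0, "bound"), "< 1/3")
  # NaN resamples are excluded from numerator and denominator
  pex <- suppressMessages(bootstrap_pvalue(5, c(1, NaN, 6, 7)))
  expect_equal(as.numeric(pex), 2 / 3)
  expect_equal(attr(pex, "n_excluded"), 1L)
  expect_error(bootstrap_pvalue(1, c(NaN, NaN)), "no valid")
  # optional add-one correction
  expect_equal(as.numeric(bootstrap_pvalue(5, c(1:4, 6:11), add_one = TRUE)),
               7 / 11)
})

test_that("run_two_way detects strong constructed effects", {
  spec <- default_trait_spec("GC", seed = 33,
                             n_per_cell = c(FWNM = 40, FWM = 40,
                                            SWNM = 40, SWM = 40),
                             effect_salinity = 3, effect_migration = 3,
                             effect_interaction = 3)
  ds <- generate_trait_dataset(spec, "GC")
  res <- run_two_way(ds, b = 500, seed = 11)
  expect_lt(as.numeric(res$p_a), 0.05)
  expect_lt(as.numeric(res$p_b), 0.05)
  expect_lt(as.numeric(res$p_ab), 0.05)
  # observed F dominates the bulk of the null distribution
  expect_gt(res$f_a, quantile(res$null_f_a, 0.99))
})

test_that("run_two_way has power for a 2-SD salinity shift across seeds", {
  # normal noise, effect = 2 SD, n = 40/cell; expect near-certain detection
  hits <- vapply(1:10, function(s) {
    spec <- synthetic_trait_spec(
      n_per_cell = c(FWNM = 40, FWM = 40, SWNM = 40, SWM = 40),
      trait_base = 40, effect_salinity = 2, effect_migration = 0,
      effect_interaction = 0, noise = "normal", noise_scale = 1,
      seed = 4000 + s)
    ds <- generate_trait_dataset(spec, "GC")
    as.numeric(run_two_way(ds, b = 200, seed = s)$p_a) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("run_two_way is deterministic under (data, b, seed)", {
  ds <- generate_trait_dataset(default_trait_spec("Gill", seed = 2), "Gill")
  r1 <- run_two_way(ds, b = 100, seed = 7)
  r2 <- run_two_way(ds, b = 100, seed = 7)
  expect_identical(r1, r2)
})

test_that("run_two_way skips the interaction when a cell is empty", {
  rec <- data.frame(
    species = sprintf("Fishus sp%02d", 1:12),
    family = "Fam", order = "Ord",
    salinity_raw = rep(c("freshwater", "marine"), each = 6),
    migration_raw = c(rep("", 3), rep("potamodromous", 3), rep("", 6)),
    value = c(41:52), stringsAsFactors = FALSE
  )
  ds <- trait_dataset(rec, "GC")
  expect_warning(res <- run_two_way(ds, b = 50, seed = 1),
                 "interaction not estimable")
  expect_true(is.na(res$f_ab))
  expect_true(is.na(res$p_ab))
  expect_false(is.na(as.numeric(res$p_a)))
})
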