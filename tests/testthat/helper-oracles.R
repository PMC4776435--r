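# Independent oracles used against the package implementations.

# Mann-Whitney p by exhaustive enumeration of all C(n1+n2, n1) labelings.
# Two-sided convention: twice the smaller tail, capped at 1.
mw_enum_p <- function(a, b, alternative = "two_sided") {
  n1 <- length(a)
  vals <- c(a, b)
  n <- length(vals)
  r <- rank(vals)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  p_ge <- mean(us >= obs)
  p_le <- mean(us <= obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
}

# Nested least-squares ANOVA oracle via stats::lm model comparisons
# (sum-to-zero contrasts), independent of the package's QR machinery.
anova_oracle <- function(y, A, B, ss_type = "II") {
  d <- data.frame(y = y, A = factor(A), B = factor(B))
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  rss <- function(fm) deviance(lm(fm, data = d))
  dfm <- function(fm) {
    f <- lm(fm, data = d)
    length(y) - df.residual(f)
  }
  r_full <- rss(y ~ A * B); k_full <- dfm(y ~ A * B)
  df_err <- length(y) - k_full
  mse <- r_full / df_err
  if (ss_type == "III") {
    # drop each term (respecting the sum-to-zero coding) from the full fit
    d1 <- drop1(lm(y ~ A * B, data = d), ~ A + B + A:B, test = "F")
    return(c(a = d1["A", "F value"], b = d1["B", "F value"],
             ab = d1["A:B", "F value"]))
  }
  comp <- switch(ss_type,
    I = list(
      a  = c(rss(y ~ 1) - rss(y ~ A), dfm(y ~ A) - dfm(y ~ 1)),
      b  = c(rss(y ~ A) - rss(y ~ A + B), dfm(y ~ A + B) - dfm(y ~ A)),
      ab = c(rss(y ~ A + B) - r_full, k_full - dfm(y ~ A + B))
    ),
    II = list(
      a  = c(rss(y ~ B) - rss(y ~ A + B), dfm(y ~ A + B) - dfm(y ~ B)),
      b  = c(rss(y ~ A) - rss(y ~ A + B), dfm(y ~ A + B) - dfm(y ~ A)),
      ab = c(rss(y ~ A + B) - r_full, k_full - dfm(y ~ A + B))
    )
  )
  vapply(comp, function(x) (x[1] / x[2]) / mse, numeric(1))
}

# Small well-formed trait table for IO tests.
toy_trait_records <- function() {
  data.frame(
    species = c("Danio rerio", "Salmo salar", "Thunnus thynnus"),
    family = c("Cyprinidae", "Salmonidae", "Scombridae"),
    order = c("Cypriniformes", "Salmoniformes", "Perciformes"),
    salinity_raw = c("freshwater", "freshwater", "marine"),
    migration_raw = c("", "anadromous", "oceanodromous"),
    value = c(37.7, 43.5, 41.0),
    stringsAsFactors = FALSE
  )
}

write_toy_tsv <- function(records = toy_trait_records(),
                          path = tempfile(fileext = ".tsv")) {
  out <- records
  names(out)[names(out) == "salinity_raw"] <- "salinity"
  names(out)[names(out) == "migration_raw"] <- "migration"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# reverse complement for the GC strand-symmetry property
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}
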