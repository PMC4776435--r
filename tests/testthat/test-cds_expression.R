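# CDS reading, filtering, GC, isochore binning and expression tests.

test_that("FASTA round-trips through write/read; contract errors surface", {
  cds <- data.frame(cds_id = c("g1", "g2"),
                    sequence = c("ATGAAACCCGGGTTTTAA", "ATGGGCCATTGA"),
                    stringsAsFactors = FALSE)
  fa <- tempfile(fileext = ".fa")
  write_cds_fasta(cds, fa)
  back <- read_cds_fasta(fa)
  expect_equal(back$cds_id, cds$cds_id)
  expect_equal(back$sequence, cds$sequence)
  expect_equal(back$length, nchar(cds$sequence))

  # header token before whitespace is the id; sequences are upper-cased
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">geneA some description", "atgaaa", ">geneB", "CCGG"), fa2)
  b2 <- read_cds_fasta(fa2)
  expect_equal(b2$cds_id, c("geneA", "geneB"))
  expect_equal(b2$sequence[1], "ATGAAA")

  # duplicate ids error
  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">dup", "ATG", ">dup", "CCC"), fa3)
  expect_error(read_cds_fasta(fa3), "duplicate")

  # empty file: empty table with a warning
  fa4 <- tempfile(fileext = ".fa")
  writeLines(character(0), fa4)
  expect_warning(b4 <- read_cds_fasta(fa4), "empty FASTA")
  expect_equal(nrow(b4), 0)

  # malformed: sequence before any header, reported with line number
  fa5 <- tempfile(fileext = ".fa")
  writeLines(c("ATGATG", ">late", "CCC"), fa5)
  expect_error(read_cds_fasta(fa5), "line 1")
})

test_that("gc_fraction counts G+C over length and is strand-symmetric", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_error(gc_fraction(""), "empty")
  set.seed(51)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  expect_equal(gc_fraction(seqs), gc_fraction(revcomp(seqs)))
})

test_that("filter_cds applies the integrity rules in order", {
  good102 <- paste0("ATG", strrep("ACG", 32), "TAA") # 102 nt, clean
  short99 <- paste0("ATG", strrep("ACG", 31), "TGA") # 99 nt
  withN <- paste0("ATG", strrep("ACG", 12), "N", strrep("ACG", 26), "TAA")
  nostart <- paste0("CTG", strrep("ACG", 32), "TAA")
  nostop <- paste0("ATG", strrep("ACG", 32), "AAA")
  offframe <- paste0("ATG", strrep("ACG", 32), "A", "TAA") # 103 nt
  rec <- data.frame(
    cds_id = c("ok", "short", "ambig", "nostart", "nostop", "frame"),
    sequence = c(good102, short99, withN, nostart, nostop, offframe),
    stringsAsFactors = FALSE
  )
  out <- filter_cds(rec)
  expect_equal(out$kept$cds_id, "ok")
  expect_equal(out$rejected$reason[match(
    c("short", "ambig", "nostart", "nostop", "frame"),
    out$rejected$cds_id)],
    c("length", "ambiguous", "start", "stop", "frame"))
  # first failing rule wins: short sequence with an N reports "length"
  rec2 <- data.frame(cds_id = "x", sequence = "ATGNNNTAA",
                     stringsAsFactors = FALSE)
  expect_equal(filter_cds(rec2)$rejected$reason, "length")
  # kept u rejected partitions the input; filtering is idempotent
  expect_setequal(c(out$kept$cds_id, out$rejected$cds_id), rec$cds_id)
  again <- filter_cds(out$kept)
  expect_equal(nrow(again$rejected), 0)
  expect_equal(again$kept$cds_id, out$kept$cds_id)
  # frame rule is toggleable
  expect_true("frame" %in% filter_cds(rec, enforce_frame = FALSE)$kept$cds_id)
})

test_that("isochore binning places GC percent in half-open intervals", {
  b <- isochore_binning(c(42, 47, 52))
  rec <- data.frame(cds_id = c("a", "b", "c", "d"),
                    gc_fraction = c(0.41, 0.45, 0.47, 0.60),
                    stringsAsFactors = FALSE)
  out <- assign_bins(rec, b)
  expect_equal(as.character(out$bin), c("L", "H1", "H2", "H3"))
  # exactly at a cutpoint -> upper bin (c above: 47 -> H2)
  expect_error(isochore_binning(c(50, 40, 60)), "ascending")
  expect_error(isochore_binning(c(40, 50)), "cutpoints")
})

test_that("expression_by_bin reproduces the hand-computed Kruskal-Wallis H", {
  # N = 6, mean ranks 1.5 / 3.5 / 5.5 -> H = 32/7
  rec <- data.frame(
    bin = factor(rep(c("L", "H1", "H2"), each = 2),
                 levels = c("L", "H1", "H2")),
    expression = c(1, 2, 3, 4, 5, 6)
  )
  out <- expression_by_bin(rec, main_bins = c("L", "H1"))
  expect_equal(out$kw_h, 32 / 7, tolerance = 1e-12)
  expect_equal(out$kw_df, 2)
  expect_s3_class(out$pairwise, "rank_test")

  # two bins with identical values: H = 0, p = 1
  rec2 <- data.frame(bin = factor(rep(c("H1", "H2"), each = 3)),
                     expression = rep(c(1, 2, 3), 2))
  out2 <- expression_by_bin(rec2)
  expect_equal(out2$kw_h, 0, tolerance = 1e-12)
  expect_equal(out2$kw_p, 1)

  expect_error(expression_by_bin(
    data.frame(bin = factor(rep("H1", 4)), expression = 1:4)),
    "at least 2")
})

test_that("two-group Kruskal-Wallis chi-square equals the squared MW z", {
  set.seed(52)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(12, 0.5)
    rec <- data.frame(bin = factor(rep(c("H1", "H2"), c(15, 12))),
                      expression = c(a, b))
    out <- expression_by_bin(rec, correct = FALSE)
    # recover |z| from the two-sided normal-approximation p-value
    z <- qnorm(1 - out$pairwise$p_value / 2)
    expect_equal(out$kw_h, z^2, tolerance = 1e-6)
  }
})

test_that("expression increases across bins when generated with positive slope", {
  spec <- synthetic_cds_spec(n_cds = 600, expression_slope_on_gc = 0.3,
                             expression_noise_sd = 0.5, seed = 53)
  cs <- generate_cds_set(spec)
  rec <- merge(data.frame(cds_id = cs$cds$cds_id,
                          gc_fraction = gc_fraction(cs$cds$sequence),
                          stringsAsFactors = FALSE),
               cs$expression, by = "cds_id")
  rec <- assign_bins(rec, isochore_binning(c(42, 47, 52)))
  out <- expression_by_bin(rec)
  expect_true(all(diff(out$bin_summary$median) > 0))
  expect_lt(out$kw_p, 1e-6)
})
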