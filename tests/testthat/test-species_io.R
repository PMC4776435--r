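# Reading, validation, classification and partitioning of trait tables.

test_that("read_trait_table reads back a well-formed table and rejects bad ones", {
  path <- write_toy_tsv()
  ds <- read_trait_table(path, "GC")
  expect_s3_class(ds, "trait_dataset")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$species, toy_trait_records()$species)
  expect_equal(ds$records$value, toy_trait_records()$value)

  # missing 'order' column -> schema error
  rec <- toy_trait_records()
  rec$order <- NULL
  path2 <- write_toy_tsv(rec)
  expect_error(read_trait_table(path2, "GC"), "schema error.*order")

  # non-numeric value in row 2 -> parse error citing the row
  rec <- toy_trait_records()
  rec$value <- c("41.0", "n/a", "39.9")
  path3 <- write_toy_tsv(rec)
  expect_error(read_trait_table(path3, "GC"), "row\\(s\\) 2")

  # MR requires a temperature column
  expect_error(read_trait_table(path, "MR"), "schema error.*temperature")
})

test_that("trait table round-trips through write/read bit-identically", {
  rec <- toy_trait_records()
  rec$temperature <- c(25, 10.5, 18)
  ds <- trait_dataset(rec, "MR")
  path <- tempfile(fileext = ".tsv")
  write_trait_table(ds, path)
  back <- read_trait_table(path, "MR")
  expect_identical(back$records[names(rec)], rec)
})

test_that("salinity classification follows habitat with diadromous override", {
  expect_equal(classify_salinity("freshwater", ""), "FW")
  expect_equal(classify_salinity("freshwater-brackish", ""), "FW")
  expect_equal(classify_salinity("marine", ""), "SW")
  expect_equal(classify_salinity("marine-brackish", ""), "SW")
  # catadromous species group with FW even from a marine habitat
  expect_equal(classify_salinity("marine", "catadromous"), "FW")
  # anadromous species group with SW even from a freshwater habitat
  expect_equal(classify_salinity("freshwater", "anadromous"), "SW")
  # normalization: case and whitespace
  expect_equal(classify_salinity(" Freshwater ", ""), "FW")

  # unrecognized descriptor with no override -> error naming the species
  expect_error(classify_salinity("brackish", "", species = "Mugil cephalus"),
               "unclassifiable.*Mugil cephalus")
  # but an overriding migration class rescues it
  expect_equal(classify_salinity("brackish", "anadromous"), "SW")
  # and a user-supplied vocabulary extension rescues it too
  expect_equal(classify_salinity("brackish", "", extra_map = c(brackish = "FW")),
               "FW")
})

test_that("migration classification: five migratory classes, empty means NM", {
  expect_equal(
    classify_migration(c("catadromous", "potamodromous", "amphidromous",
                         "oceanodromous", "anadromous")),
    rep("M", 5)
  )
  expect_equal(classify_migration(""), "NM")
  expect_equal(classify_migration("non-migratory"), "NM")
  expect_equal(classify_migration("Oceanodromous"), "M")
})

test_that("classification is deterministic and idempotent", {
  ds <- classify_dataset(trait_dataset(toy_trait_records(), "GC"))
  again <- classify_dataset(ds)
  expect_identical(ds, again)
  expect_equal(ds$records$group4, c("FWNM", "SWM", "SWM"))
})

test_that("apply_exclusions removes listed species and logs no-ops", {
  rec <- toy_trait_records()
  rec$species[1] <- "Perca fluviatilis" # on the default exclusion list
  ds <- trait_dataset(rec, "GC")
  out <- suppressWarnings(apply_exclusions(ds))
  expect_equal(nrow(out$records), 2)
  expect_false("Perca fluviatilis" %in% out$records$species)
  expect_equal(attr(out, "n_excluded"), 1L)

  # empty exclusion list is the identity
  expect_identical(apply_exclusions(ds, character(0))$records, ds$records)

  # matching is case-insensitive and whitespace-collapsed, exact
  out2 <- suppressWarnings(
    apply_exclusions(ds, c("  perca   FLUVIATILIS ")))
  expect_equal(nrow(out2$records), 2)

  # absent name: no-op with a warning
  expect_warning(out3 <- apply_exclusions(ds, "Gadus morhua"),
                 "not present")
  expect_equal(nrow(out3$records), 3)

  # the printed list has nine entries, including one trinomial
  expect_length(default_exclusions(), 9)
  expect_true("Aphanius dispar dispar" %in% default_exclusions())
})

test_that("collapse_replicates takes the median", {
  expect_equal(collapse_replicates(2.0), 2.0)
  expect_equal(collapse_replicates(c(1.0, 3.0)), 2.0)
  expect_equal(collapse_replicates(c(5.0, 1.0, 3.0)), 3.0)
  expect_error(collapse_replicates(numeric(0)), "empty")
})

test_that("partition is complete, exclusive, and coarsening-consistent", {
  set.seed(42)
  for (seed in 1:5) {
    ds <- generate_trait_dataset(default_trait_spec("GC", seed = seed), "GC")
    ds <- classify_dataset(ds)
    g4 <- partition_groups(ds, "four_way")
    g2s <- partition_groups(ds, "salinity")
    g2m <- partition_groups(ds, "migration")
    expect_equal(sum(lengths(g4)), nrow(ds$records))
    expect_equal(sum(lengths(g2s)), nrow(ds$records))
    # coarsening: FW = FWNM u FWM exactly (values and counts)
    expect_equal(sort(g2s$FW), sort(c(g4$FWNM, g4$FWM)))
    expect_equal(sort(g2s$SW), sort(c(g4$SWNM, g4$SWM)))
    expect_equal(sort(g2m$M), sort(c(g4$FWM, g4$SWM)))
  }
})

test_that("four records, one per combination, give 4 singleton cells", {
  rec <- data.frame(
    species = paste("Fishus", c("a", "b", "c", "d")),
    family = "Fam", order = "Ord",
    salinity_raw = c("freshwater", "freshwater", "marine", "marine"),
    migration_raw = c("", "potamodromous", "", "oceanodromous"),
    value = c(1, 2, 3, 4), stringsAsFactors = FALSE
  )
  g <- partition_groups(trait_dataset(rec, "GC"))
  expect_equal(lengths(g), c(FWNM = 1L, FWM = 1L, SWNM = 1L, SWM = 1L))
  # empty cell warns
  g3 <- suppressWarnings(
    partition_groups(trait_dataset(rec[1:3, ], "GC")))
  expect_warning(partition_groups(trait_dataset(rec[1:3, ], "GC")),
                 "empty cell")
  expect_equal(lengths(g3)[["SWM"]], 0L)
})

test_that("dataset validation enforces the record invariants", {
  rec <- toy_trait_records()
  rec$species[2] <- "Danio rerio"
  expect_error(trait_dataset(rec, "GC"), "duplicate")
  rec <- toy_trait_records()
  rec$value[1] <- -1
  expect_error(trait_dataset(rec, "GC"), "strictly in")
  expect_error(trait_dataset(rec, "Gill"), "> 0")
  rec <- toy_trait_records()
  rec$value[3] <- 101
  expect_error(trait_dataset(rec, "GC"), "strictly in")
})
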