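# Species-trait tables: reading, validation, ecological classification and
# partitioning into salinity x migration groups.

#' Recognized habitat and migration vocabularies
#'
#' Habitat descriptors mapping to the freshwater (FW) and seawater (SW)
#' classes, and the migration classes counted as migratory (M). A habitat
#' descriptor outside these vocabularies (e.g. bare \code{"brackish"}) is
#' unclassifiable unless a diadromous migration class overrides it, or the
#' user extends the vocabulary via \code{extra_map}.
#'
#' @format Named character vectors.
#' @name vocabularies
#' @keywords internal
NULL

.salinity_vocab <- c(
  "freshwater"          = "FW",
  "freshwater-brackish" = "FW",
  "marine"              = "SW",
  "marine-brackish"     = "SW"
)

.migratory_vocab <- c(
  "catadromous", "potamodromous", "amphidromous", "oceanodromous", "anadromous"
)

.norm_text <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Default species exclusion list
#'
#' The nine species discarded for conflicting salinity and/or migration
#' information. Matching is case-insensitive and whitespace-collapsed.
#'
#' @return Character vector of binomial (one trinomial) species names.
#' @export
default_exclusions <- function() {
  c(
    "Aphanius dispar dispar",
    "Aphanius fasciatus",
    "Ciprinodon variegatus",
    "Fundulus heteroclitus",
    "Lagodon rhomboides",
    "Leptococcus armatus",
    "Takifugu rubripes",
    "Bathygobius soporator",
    "Perca fluviatilis"
  )
}

#' Construct a species-trait dataset
#'
#' A `trait_dataset` bundles one trait variable (`"MR"`, `"Gill"` or `"GC"`)
#' with one row per species: taxonomy (`species`, `family`, `order`), raw
#' habitat and migration descriptors, the trait value in its native units
#' (mg O2 kg^-1 h^-1 for raw MR, cm^2 g^-1 for Gill, percent for GC) and,
#' for MR, the assay temperature in degrees Celsius.
#'
#' @param records data.frame with columns `species`, `family`, `order`,
#'   `salinity_raw`, `migration_raw`, `value` and, for MR, `temperature`.
#' @param variable one of `"MR"`, `"Gill"`, `"GC"`.
#' @param provenance free-text origin of the table.
#' @return An object of class `trait_dataset`.
#' @export
trait_dataset <- function(records, variable = c("MR", "Gill", "GC"),
                          provenance = "unspecified") {
  variable <- match.arg(variable)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  obj <- structure(
    list(variable = variable, records = records, provenance = provenance),
    class = "trait_dataset"
  )
  validate_trait_dataset(obj)
  obj
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat(sprintf("<trait_dataset> variable=%s, %d species (%s)\n",
              x$variable, nrow(x$records), x$provenance))
  invisible(x)
}

#' Validate a trait dataset
#'
#' Checks the per-record invariants: non-empty unique species names,
#' positive trait values (strictly inside (0, 100) for GC percent), and an
#' assay temperature for every metabolic-rate record.
#'
#' @param x a `trait_dataset`.
#' @return `x`, invisibly; stops with an informative error on violation.
#' @export
validate_trait_dataset <- function(x) {
  stopifnot(inherits(x, "trait_dataset"))
  rec <- x$records
  required <- c("species", "family", "order", "salinity_raw", "migration_raw",
                "value")
  if (x$variable == "MR") required <- c(required, "temperature")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sp <- .norm_text(rec$species)
  if (any(!nzchar(sp))) {
    stop("empty species name in row(s) ",
         paste(which(!nzchar(sp)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sp)) {
    stop("duplicate species name(s): ",
         paste(unique(rec$species[duplicated(sp)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(rec$value) || any(!is.finite(rec$value))) {
    stop("non-numeric or non-finite trait value in row(s) ",
         paste(which(!is.finite(suppressWarnings(as.numeric(rec$value)))),
               collapse = ", "), call. = FALSE)
  }
  if (x$variable %in% c("MR", "Gill") && any(rec$value <= 0)) {
    stop(x$variable, " values must be > 0; offending row(s): ",
         paste(which(rec$value <= 0), collapse = ", "), call. = FALSE)
  }
  if (x$variable == "GC" && any(rec$value <= 0 | rec$value >= 100)) {
    stop("GC percent must lie strictly in (0, 100); offending row(s): ",
         paste(which(rec$value <= 0 | rec$value >= 100), collapse = ", "),
         call. = FALSE)
  }
  if (x$variable == "MR" && any(!is.finite(rec$temperature))) {
    stop("missing assay temperature for species: ",
         paste(rec$species[!is.finite(rec$temperature)], collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a species-trait table from delimited text
#'
#' Reads a TSV (default) or CSV table with a header naming at least
#' `species`, `family`, `order`, `salinity`, `migration` and `value`
#' (plus `temperature` for MR). Column names can be remapped through
#' `col_map` when the file uses different headers.
#'
#' @param path file path.
#' @param variable one of `"MR"`, `"Gill"`, `"GC"`.
#' @param sep field separator; `"\t"` by default, `","` accepted.
#' @param col_map named character vector mapping canonical names
#'   (`species`, `family`, `order`, `salinity`, `migration`, `value`,
#'   `temperature`) to the file's column headers.
#' @return A validated [trait_dataset()].
#' @export
read_trait_table <- function(path, variable = c("MR", "Gill", "GC"),
                             sep = "\t", col_map = NULL) {
  variable <- match.arg(variable)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  canonical <- c(species = "species", family = "family", order = "order",
                 salinity = "salinity", migration = "migration",
                 value = "value", temperature = "temperature")
  if (!is.null(col_map)) canonical[names(col_map)] <- col_map
  need <- c("species", "family", "order", "salinity", "migration", "value")
  if (variable == "MR") need <- c(need, "temperature")
  missing_cols <- need[!canonical[need] %in% names(raw)]
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing required column(s): ",
         paste(canonical[missing_cols], collapse = ", "), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(raw[[canonical["value"]]]))
  bad <- which(is.na(val))
  if (length(bad)) {
    stop("parse error in ", path, ": non-numeric trait value in data row(s) ",
         paste(bad, collapse = ", "), " (value = ",
         paste(raw[[canonical["value"]]][bad], collapse = ", "), ")",
         call. = FALSE)
  }
  rec <- data.frame(
    species = raw[[canonical["species"]]],
    family = raw[[canonical["family"]]],
    order = raw[[canonical["order"]]],
    salinity_raw = .norm_text(raw[[canonical["salinity"]]]),
    migration_raw = .norm_text(raw[[canonical["migration"]]]),
    value = val,
    stringsAsFactors = FALSE
  )
  if (variable == "MR") {
    tmp <- suppressWarnings(as.numeric(raw[[canonical["temperature"]]]))
    badt <- which(is.na(tmp))
    if (length(badt)) {
      stop("parse error in ", path,
           ": non-numeric assay temperature in data row(s) ",
           paste(badt, collapse = ", "), call. = FALSE)
    }
    rec$temperature <- tmp
  }
  trait_dataset(rec, variable, provenance = path)
}

#' Write a trait dataset as TSV
#'
#' Writes the record table (including any classification columns appended by
#' [classify_dataset()]) as UTF-8 tab-separated text. A written table read
#' back with [read_trait_table()] reproduces all canonical fields.
#'
#' @param dataset a `trait_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "trait_dataset"))
  out <- dataset$records
  names(out)[names(out) == "salinity_raw"] <- "salinity"
  names(out)[names(out) == "migration_raw"] <- "migration"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify habitat salinity as freshwater or seawater
#'
#' FW groups species whose habitat descriptor is freshwater or
#' freshwater-brackish plus the catadromous species; SW groups marine and
#' marine-brackish habitats plus the anadromous species. The diadromous
#' migration classes (catadromous, anadromous) override the habitat
#' descriptor. Any other descriptor is unclassifiable by default: ambiguous
#' species are meant to be discarded, not guessed.
#'
#' @param salinity character vector of habitat descriptors.
#' @param migration character vector of migration descriptors (same length,
#'   recycled if length 1); empty string for none.
#' @param species optional species names used in error messages.
#' @param extra_map optional named character vector extending the habitat
#'   vocabulary, e.g. `c(brackish = "FW")`.
#' @return Character vector of `"FW"` / `"SW"`.
#' @export
classify_salinity <- function(salinity, migration = "", species = NULL,
                              extra_map = NULL) {
  salinity <- .norm_text(salinity)
  migration <- .norm_text(migration)
  if (length(migration) == 1L) migration <- rep(migration, length(salinity))
  stopifnot(length(salinity) == length(migration))
  vocab <- .salinity_vocab
  if (!is.null(extra_map)) {
    stopifnot(all(extra_map %in% c("FW", "SW")))
    vocab[.norm_text(names(extra_map))] <- unname(extra_map)
  }
  out <- unname(vocab[salinity])
  # diadromous migration overrides the habitat descriptor
  out[migration == "catadromous"] <- "FW"
  out[migration == "anadromous"] <- "SW"
  if (anyNA(out)) {
    idx <- which(is.na(out))
    who <- if (is.null(species)) paste0("row ", idx) else species[idx]
    stop("unclassifiable salinity descriptor(s) [",
         paste(unique(salinity[idx]), collapse = ", "), "] for: ",
         paste(who, collapse = ", "),
         " (extend the vocabulary with extra_map or discard the species)",
         call. = FALSE)
  }
  out
}

#' Classify migratory lifestyle
#'
#' Migratory (M) iff the descriptor is one of catadromous, potamodromous,
#' amphidromous, oceanodromous or anadromous; everything else, including an
#' empty descriptor, is non-migratory (NM) — species with no indication
#' about migration are considered non-migratory.
#'
#' @param migration character vector of migration descriptors.
#' @return Character vector of `"M"` / `"NM"`.
#' @export
classify_migration <- function(migration) {
  migration <- .norm_text(migration)
  ifelse(migration %in% .migratory_vocab, "M", "NM")
}

#' Append classification columns to a trait dataset
#'
#' Adds `salinity_class` (FW/SW), `migration_class` (M/NM) and their
#' concatenation `group4` (FWNM/FWM/SWNM/SWM) to the record table.
#' Classification is deterministic and idempotent.
#'
#' @inheritParams classify_salinity
#' @param dataset a `trait_dataset`.
#' @return The dataset with classification columns appended.
#' @export
classify_dataset <- function(dataset, extra_map = NULL) {
  stopifnot(inherits(dataset, "trait_dataset"))
  rec <- dataset$records
  rec$salinity_class <- classify_salinity(rec$salinity_raw, rec$migration_raw,
                                          species = rec$species,
                                          extra_map = extra_map)
  rec$migration_class <- classify_migration(rec$migration_raw)
  rec$group4 <- paste0(rec$salinity_class, rec$migration_class)
  dataset$records <- rec
  dataset
}

#' Remove excluded species from a dataset
#'
#' Species with conflicting ecological information are discarded by exact,
#' case-insensitive, whitespace-collapsed name match. Excluded names absent
#' from the dataset are a no-op (with a warning naming them). The number of
#' removed records is recorded in the `n_excluded` attribute.
#'
#' @param dataset a `trait_dataset`.
#' @param exclusions character vector of species names;
#'   [default_exclusions()] by default.
#' @return The dataset without the excluded species.
#' @export
apply_exclusions <- function(dataset, exclusions = default_exclusions()) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (!length(exclusions)) return(dataset)
  key <- .norm_text(dataset$records$species)
  ex <- .norm_text(exclusions)
  absent <- exclusions[!ex %in% key]
  if (length(absent)) {
    warning("exclusion name(s) not present in dataset: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  drop <- key %in% ex
  dataset$records <- dataset$records[!drop, , drop = FALSE]
  rownames(dataset$records) <- NULL
  attr(dataset, "n_excluded") <- sum(drop)
  dataset
}

#' Collapse replicate measurements into one species value
#'
#' When more than one value is available for a species the median is used
#' (even counts: mean of the two central order statistics).
#'
#' @param values numeric vector of replicate measurements.
#' @param rule collapsing rule; only `"median"` is defined.
#' @return A single numeric value.
#' @export
collapse_replicates <- function(values, rule = c("median")) {
  rule <- match.arg(rule)
  values <- as.numeric(values)
  if (!length(values)) stop("cannot collapse an empty replicate list",
                            call. = FALSE)
  stats::median(values)
}

#' Partition trait values into ecological groups
#'
#' Splits a classified dataset into FW/SW (`mode = "salinity"`), NM/M
#' (`"migration"`) or the four combined cells FWNM/FWM/SWNM/SWM
#' (`"four_way"`). Every record lands in exactly one cell; cell sizes sum
#' to the dataset size. An empty cell in four-way mode triggers a warning.
#'
#' @param dataset a classified `trait_dataset` (see [classify_dataset()]);
#'   an unclassified dataset is classified on the fly.
#' @param mode partition mode.
#' @return Named list of numeric vectors of trait values, one per group,
#'   in the fixed order FWNM, FWM, SWNM, SWM (or FW, SW / NM, M).
#' @export
partition_groups <- function(dataset,
                             mode = c("four_way", "salinity", "migration")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "trait_dataset"))
  if (is.null(dataset$records$group4)) dataset <- classify_dataset(dataset)
  rec <- dataset$records
  levels_by_mode <- list(
    four_way = c("FWNM", "FWM", "SWNM", "SWM"),
    salinity = c("FW", "SW"),
    migration = c("NM", "M")
  )
  key <- switch(mode,
    four_way = rec$group4,
    salinity = rec$salinity_class,
    migration = rec$migration_class
  )
  lv <- levels_by_mode[[mode]]
  out <- split(rec$value, factor(key, levels = lv))
  if (mode == "four_way" && any(lengths(out) == 0L)) {
    warning("empty cell(s) in four-way partition: ",
            paste(lv[lengths(out) == 0L], collapse = ", "), call. = FALSE)
  }
  out
}
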