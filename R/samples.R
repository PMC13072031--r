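# Data model: elemental samples (needle or soil) and the paired study dataset.
#
# Concentrations are mass-based (mg per g dry mass) throughout; no molar
# conversion happens anywhere in the package. Soil depth is a closed
# categorical variable: the five fixed 20-cm intervals of a 1-m core.

#' Canonical factor levels of the sampling design
#'
#' The design distinguishes two tree conditions (healthy vs chlorotic crowns),
#' two within-branch needle positions (apical green tip vs basal, potentially
#' chlorotic, section) and five fixed soil depth layers of a 1-m core.
#'
#' @name design-levels
#' @keywords internal
NULL

#' Validate a table of elemental samples
#'
#' Checks a needle or soil sample table against the design contract: required
#' columns present, condition/position/layer drawn from the closed level sets,
#' all three concentrations strictly positive and below 1000 mg/g, and the
#' (tree, position-or-layer) key unique — one composite sample per position
#' (or depth layer) per tree. Every violation is reported with the offending
#' `sample_id` and field; nothing is silently coerced or imputed.
#'
#' @param samples A data frame with the canonical columns (see
#'   [read_samples()] for the exact schema).
#' @param schema `"needle"` or `"soil"`.
#' @return The validated samples as a tibble (invisibly usable in pipes), with
#'   `condition` and the design column as factors in canonical level order.
#' @export
validate_samples <- function(samples, schema = c("needle", "soil")) {
  schema <- match.arg(schema)
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("%s table is missing required column(s): %s",
                  schema, paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(samples)[cols]
  x$sample_id <- as.character(x$sample_id)
  x$tree_id <- as.character(x$tree_id)

  problems <- character()
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  if (anyNA(x)) {
    bad <- which(!complete.cases(x))
    for (i in bad) {
      fields <- cols[is.na(x[i, ])]
      note("row %d (sample_id %s): missing value in %s",
           i, x$sample_id[i] %||% "?", paste(fields, collapse = ", "))
    }
  }

  bad_cond <- which(!is.na(x$condition) & !(as.character(x$condition) %in% condition_levels))
  for (i in bad_cond) {
    note("row %d (sample_id %s): condition '%s' not one of %s",
         i, x$sample_id[i], x$condition[i], paste(condition_levels, collapse = "/"))
  }
  dcol <- design_column(schema)
  dlev <- design_levels(schema)
  bad_design <- which(!is.na(x[[dcol]]) & !(as.character(x[[dcol]]) %in% dlev))
  for (i in bad_design) {
    note("row %d (sample_id %s): %s '%s' not one of %s",
         i, x$sample_id[i], dcol, x[[dcol]][i], paste(dlev, collapse = ", "))
  }

  for (cc in conc_columns) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    not_num <- which(!is.na(x[[cc]]) & is.na(v))
    for (i in not_num) {
      note("row %d (sample_id %s): %s '%s' is not numeric", i, x$sample_id[i], cc, x[[cc]][i])
    }
    bad <- which(!is.na(v) & (v <= 0 | v >= 1000))
    for (i in bad) {
      note("row %d (sample_id %s): %s = %g outside (0, 1000) mg/g",
           i, x$sample_id[i], cc, v[i])
    }
    x[[cc]] <- v
  }

  if (!anyNA(x$sample_id) && anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    note("duplicate sample_id: %s", paste(dup, collapse = ", "))
  }
  key <- paste(x$tree_id, x[[dcol]], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    dup_keys <- unique(paste0("tree ", x$tree_id[dup], " / ", dcol, " ", x[[dcol]][dup]))
    note("duplicate (tree, %s) key — one composite sample allowed per %s per tree: %s",
         dcol, dcol, paste(dup_keys, collapse = "; "))
  }

  if (length(problems)) {
    abort(paste0("invalid ", schema, " samples:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  x$condition <- factor(as.character(x$condition), levels = condition_levels)
  x[[dcol]] <- factor(as.character(x[[dcol]]), levels = dlev)
  x
}

#' Read a table of elemental samples from CSV
#'
#' Reads a needle or soil concentration table. Needle files carry the columns
#' `sample_id, tree_id, condition, position, c_mg_g, n_mg_g, p_mg_g`; soil
#' files replace `position` with `soil_layer` (values `"0-20"`, `"20-40"`,
#' `"40-60"`, `"60-80"`, `"80-100"`). Files with other headers (e.g. a raw
#' data deposit) can be read through a column mapping.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal, comma separator).
#' @param schema `"needle"` or `"soil"`.
#' @param mapping Optional column mapping: either a named character vector
#'   `c(canonical = "source_name", ...)` or the path to a two-column CSV with
#'   headers `canonical,source`.
#' @return A validated tibble of samples in file row order.
#' @export
read_samples <- function(path, schema = c("needle", "soil"), mapping = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!is.null(mapping)) {
    map <- read_column_mapping(mapping)
    missing_src <- setdiff(unname(map), names(x))
    if (length(missing_src)) {
      abort(sprintf("mapping names source column(s) absent from %s: %s",
                    path, paste(missing_src, collapse = ", ")))
    }
    x <- dplyr::rename(x, !!!rlang::syms(map))
  }
  validate_samples(x, schema)
}

read_column_mapping <- function(mapping) {
  if (is.character(mapping) && is.null(names(mapping)) && length(mapping) == 1) {
    m <- readr::read_csv(mapping, col_types = "cc", progress = FALSE)
    if (!all(c("canonical", "source") %in% names(m))) {
      abort("mapping file must have columns 'canonical' and 'source'")
    }
    setNames(m$source, m$canonical)
  } else if (is.character(mapping) && !is.null(names(mapping))) {
    mapping
  } else {
    abort("mapping must be a named character vector or a path to a mapping CSV")
  }
}

#' Write a table of elemental samples to CSV
#'
#' Emits the canonical column order so that [read_samples()] inverts the write
#' exactly (round-trip identity, field for field).
#'
#' @param samples A validated (or validatable) sample table.
#' @param path Output file path.
#' @param schema `"needle"` or `"soil"`.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, schema = c("needle", "soil")) {
  schema <- match.arg(schema)
  if (is.null(samples) || nrow(samples) == 0) {
    abort("refusing to write an empty sample table")
  }
  out <- validate_samples(samples, schema)
  out$condition <- as.character(out$condition)
  dcol <- design_column(schema)
  out[[dcol]] <- as.character(out[[dcol]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Bundle needle and soil tables into a study dataset
#'
#' Validates both tables and the cross-table design invariants: every tree
#' with a basal needle sample must also have an apical sample (required for
#' resorption pairing), and each tree has at most one soil sample per depth
#' layer (enforced by per-table validation).
#'
#' @param needles Needle sample table (see [read_samples()]).
#' @param soils Soil sample table.
#' @param provenance Free-text note on where the data came from (source file
#'   or generator seed); carried into reports.
#' @return An object of class `study_dataset`: a list with elements `needles`,
#'   `soils` (tibbles) and `provenance`.
#' @export
study_dataset <- function(needles, soils, provenance = "") {
  needles <- validate_samples(needles, "needle")
  soils <- validate_samples(soils, "soil")
  basal_trees <- unique(needles$tree_id[needles$position == "basal"])
  apical_trees <- unique(needles$tree_id[needles$position == "apical"])
  orphans <- setdiff(basal_trees, apical_trees)
  if (length(orphans)) {
    abort(sprintf("tree(s) with a basal needle sample but no apical partner: %s",
                  paste(orphans, collapse = ", ")))
  }
  structure(list(needles = needles, soils = soils,
                 provenance = as.character(provenance)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat(sprintf("  needles: %d samples, %d trees\n",
              nrow(x$needles), length(unique(x$needles$tree_id))))
  cat(sprintf("  soils:   %d samples, %d trees, %d layers\n",
              nrow(x$soils), length(unique(x$soils$tree_id)),
              length(unique(as.character(x$soils$soil_layer)))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
#' @rdname study_dataset
#' @param x Object to test.
is_study_dataset <- function(x) inherits(x, "study_dataset")

#' Write both tables of a study dataset
#'
#' @param dataset A [study_dataset()].
#' @param dir Output directory (created if needed); writes `needles.csv` and
#'   `soils.csv`.
#' @return `dir`, invisibly.
#' @export
write_study_dataset <- function(dataset, dir) {
  stopifnot(is_study_dataset(dataset))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_samples(dataset$needles, file.path(dir, "needles.csv"), "needle")
  write_samples(dataset$soils, file.path(dir, "soils.csv"), "soil")
  invisible(dir)
}

#' Read a study dataset from a directory
#'
#' @param dir Directory containing `needles.csv` and `soils.csv`.
#' @param mapping Optional column mapping passed to [read_samples()].
#' @return A [study_dataset()].
#' @export
read_study_dataset <- function(dir, mapping = NULL) {
  study_dataset(read_samples(file.path(dir, "needles.csv"), "needle", mapping),
                read_samples(file.path(dir, "soils.csv"), "soil", mapping),
                provenance = dir)
}
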