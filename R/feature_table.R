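#' Validate a morphological feature table
#'
#' Checks the structural invariants of a site- or well-level feature table:
#' metadata columns present, at least one feature column, no duplicate
#' `(plate, well, site)` keys, at least one control row per plate, and strictly
#' positive concentrations for test rows.
#'
#' @param x A data frame with metadata columns `plate_id`, `well`,
#'   `compound_id`, `concentration_um`, `role`, `dmso_percent` (and optionally
#'   `site`), plus numeric feature columns.
#' @param level `"site"` requires a `site` column; `"well"` forbids duplicate
#'   `(plate, well)` keys; `"any"` checks whatever is present.
#' @return `x` invisibly, as a tibble; errors describe the first violation.
#' @export
validate_feature_table <- function(x, level = c("any", "site", "well")) {
  level <- match.arg(level)
  required <- c("plate_id", "well", "compound_id", "concentration_um", "role", "dmso_percent")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("Feature table is missing metadata columns: ", toString(missing)))
  }
  feats <- feature_columns(x)
  if (length(feats) == 0) {
    abort("Feature table has no feature columns.")
  }
  bad_role <- setdiff(unique(x$role), c("control", "test"))
  if (length(bad_role) > 0) {
    abort(paste0("Unknown role values: ", toString(bad_role)))
  }
  if (level == "site" && !"site" %in% names(x)) {
    abort("Site-level table requires a `site` column.")
  }
  keys <- if ("site" %in% names(x)) c("plate_id", "well", "site") else c("plate_id", "well")
  if (level == "well") keys <- c("plate_id", "well")
  dup <- duplicated(x[keys])
  if (any(dup)) {
    abort(paste0(
      "Duplicate (", toString(keys), ") keys, e.g. ",
      paste(unlist(x[which(dup)[1], keys]), collapse = "/")
    ))
  }
  plates_without_controls <- setdiff(
    unique(x$plate_id),
    unique(x$plate_id[x$role == "control"])
  )
  if (length(plates_without_controls) > 0) {
    abort(paste0("Plates without control wells: ", toString(plates_without_controls)))
  }
  bad_conc <- x$role == "test" & (!is.finite(x$concentration_um) | x$concentration_um <= 0)
  if (any(bad_conc)) {
    abort("Test rows must have a finite concentration_um > 0.")
  }
  invisible(as_tibble(x))
}

#' Read / write feature tables
#'
#' Feature tables are stored as flat files with long metadata columns
#' (`plate_id`, `well`, `site`, `compound_id`, `concentration_um`, `role`,
#' `dmso_percent`) followed by wide numeric feature columns. CSV is always
#' supported; Parquet requires the `arrow` package.
#'
#' @param path File path; format inferred from the extension
#'   (`.csv`/`.csv.gz` or `.parquet`).
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Reading Parquet requires the `arrow` package.")
    }
    return(as_tibble(arrow::read_parquet(path)))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_feature_table
#' @param x Feature table to write.
#' @export
write_feature_table <- function(x, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Writing Parquet requires the `arrow` package.")
    }
    arrow::write_parquet(x, path)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Aggregate site-level measurements to well medians
#'
#' Collapses the (typically 9) microscope sites of each well to a single row
#' per `(plate, well)` by taking the per-feature median. Missing site values
#' are excluded from the median; a well whose sites are all missing for a
#' feature yields a missing well value and is reported via the
#' `"dropped_values"` attribute.
#'
#' @param sites Site-level feature table (see [validate_feature_table()]).
#' @return Well-level tibble, one row per `(plate, well)`, metadata carried
#'   through; attribute `"dropped_values"` counts all-missing (well, feature)
#'   cells.
#' @export
aggregate_wells <- function(sites) {
  validate_feature_table(sites, level = "site")
  feats <- feature_columns(sites)
  out <- sites %>%
    group_by(.data$plate_id, .data$well) %>%
    summarise(
      compound_id = first(.data$compound_id),
      concentration_um = first(.data$concentration_um),
      role = first(.data$role),
      dmso_percent = first(.data$dmso_percent),
      across(all_of(feats), ~ median(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  # a well whose sites are all missing for a feature aggregates to NA
  m <- as.matrix(out[feats])
  n_all_missing <- sum(is.na(m) | is.nan(m))
  if (n_all_missing > 0) {
    m[is.nan(m)] <- NA_real_
    out[feats] <- as_tibble(m)
    inform(paste0(n_all_missing, " (well, feature) cells had all sites missing; set to NA."))
  }
  attr(out, "dropped_values") <- n_all_missing
  out
}

#' Collapse replicate plates by median
#'
#' After well aggregation, replicate plates (e.g. triplicates with shifted
#' layouts) are collapsed by per-feature median: test rows per
#' `(compound, concentration)`, control rows per well position, so that
#' plate-matched control lookup still finds one control row per original
#' control well.
#'
#' @param wells Well-level feature table covering the replicate plates.
#' @param group_id Plate id assigned to the collapsed pseudo-plate.
#' @return Well-level tibble with a single `plate_id` equal to `group_id`.
#' @export
aggregate_replicates <- function(wells, group_id = "replicate_median") {
  validate_feature_table(wells)
  feats <- feature_columns(wells)
  tests <- wells %>%
    filter(.data$role == "test") %>%
    group_by(.data$compound_id, .data$concentration_um, .data$dmso_percent) %>%
    summarise(
      well = first(.data$well),
      across(all_of(feats), ~ median(.x, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    mutate(role = "test")
  controls <- wells %>%
    filter(.data$role == "control") %>%
    group_by(.data$well, .data$dmso_percent) %>%
    summarise(
      compound_id = first(.data$compound_id),
      concentration_um = first(.data$concentration_um),
      across(all_of(feats), ~ median(.x, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    mutate(role = "control")
  bind_rows(tests, controls) %>%
    mutate(plate_id = group_id) %>%
    select(
      "plate_id", "well", "compound_id", "concentration_um",
      "role", "dmso_percent", all_of(feats)
    )
}
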