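#' Raw median absolute deviation
#'
#' Median of absolute deviations from the median, without the 1.4826 Gaussian
#' consistency factor (set `constant = 1.4826` to restore it). The raw MAD is
#' the unit of the robust Z-score used throughout the package.
#'
#' @param x Numeric vector; missing values dropped.
#' @param constant Scale factor applied to the median absolute deviation.
#' @return Scalar MAD.
#' @export
mad_raw <- function(x, constant = 1) {
  x <- x[!is.na(x)]
  constant * median(abs(x - median(x)))
}

#' Induction: percentage of significantly changed features
#'
#' The activity measure of a morphological profile: the percentage of features
#' whose robust Z-score passes the significance cutoff in absolute value.
#'
#' @param z Numeric Z-score vector (missing values excluded from both counts).
#' @param cutoff Significance cutoff on `|z|`; the comparison is inclusive.
#' @return Induction in percent, in `[0, 100]`.
#' @export
induction <- function(z, cutoff = 3) {
  z <- z[!is.na(z)]
  if (length(z) == 0) {
    abort("Cannot compute induction of an empty Z-score vector.")
  }
  100 * sum(abs(z) >= cutoff) / length(z)
}

#' Robust Z-score profiles against plate-matched DMSO controls
#'
#' For every test well, each robust feature is converted to a Z-score
#' `(value - median(controls)) / MAD(controls)` using the control wells of the
#' same plate and the same DMSO load (`dmso_percent`). The MAD is the raw
#' median absolute deviation ([mad_raw()]). Features whose control MAD is zero
#' are floored at `max(eps_abs, eps_rel * |control median|)` and reported in
#' the `"diagnostics"` attribute, so no Z-score is ever infinite.
#'
#' @param wells Well-level feature table ([aggregate_wells()] output).
#' @param features Robust feature set: character vector of feature names or a
#'   [select_robust_features()] result.
#' @param cutoff Significance cutoff passed to [induction()].
#' @param mad_constant MAD scale factor (1 = raw MAD).
#' @param eps_abs,eps_rel Floor for degenerate (zero) control MADs.
#' @param min_controls Minimum number of matching control wells per
#'   (plate, dmso_percent) stratum.
#' @param include_controls Also emit Z-profiles for the control wells
#'   themselves (each control is scored against the full control set).
#' @param max_missing Profiles with a larger fraction of missing feature
#'   values are dropped with a message.
#' @return Tibble with one row per profiled well: `plate_id`, `well`,
#'   `compound_id`, `concentration_um`, `role`, the Z-scored features, and
#'   `induction`. Attributes: `"features"` (the feature order) and
#'   `"diagnostics"` (tibble of MAD-floored features per stratum).
#' @export
zscore_profiles <- function(wells, features, cutoff = 3, mad_constant = 1,
                            eps_abs = 1e-6, eps_rel = 1e-6, min_controls = 3,
                            include_controls = FALSE, max_missing = 0.05) {
  validate_feature_table(wells)
  feats <- as_feature_names(features)
  if (length(feats) == 0) {
    abort("The robust feature set is empty.")
  }
  missing_feats <- setdiff(feats, names(wells))
  if (length(missing_feats) > 0) {
    abort(paste0("Features absent from the table: ", toString(head(missing_feats, 5))))
  }

  strata <- wells %>% distinct(.data$plate_id, .data$dmso_percent)
  diags <- list()
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    pl <- strata$plate_id[i]
    dp <- strata$dmso_percent[i]
    in_stratum <- wells$plate_id == pl & wells$dmso_percent == dp
    ctrl <- wells[in_stratum & wells$role == "control", , drop = FALSE]
    test <- wells[in_stratum & wells$role == "test", , drop = FALSE]
    if (nrow(test) == 0 && !include_controls) next
    if (nrow(ctrl) < min_controls) {
      abort(paste0(
        "Plate ", pl, " has ", nrow(ctrl), " control wells at dmso_percent = ",
        dp, " (need >= ", min_controls, ")."
      ))
    }
    cm <- as.matrix(ctrl[feats])
    ctr_median <- apply(cm, 2, median, na.rm = TRUE)
    ctr_mad <- apply(cm, 2, function(v) mad_raw(v, constant = mad_constant))
    floored <- which(ctr_mad == 0 | !is.finite(ctr_mad))
    if (length(floored) > 0) {
      diags[[length(diags) + 1]] <- tibble(
        plate_id = pl, dmso_percent = dp, feature = feats[floored],
        control_median = ctr_median[floored]
      )
      ctr_mad[floored] <- pmax(eps_abs, eps_rel * abs(ctr_median[floored]))
    }
    target <- if (include_controls) rbind(as.matrix(test[feats]), cm) else as.matrix(test[feats])
    meta <- if (include_controls) bind_rows(test, ctrl) else test
    if (nrow(target) == 0) next
    z <- sweep(sweep(target, 2, ctr_median, "-"), 2, ctr_mad, "/")
    rows[[length(rows) + 1]] <- bind_cols(
      meta %>% select("plate_id", "well", "compound_id", "concentration_um", "role"),
      as_tibble(z)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    zmat <- as.matrix(out[feats])
    frac_missing <- rowMeans(is.na(zmat))
    if (any(frac_missing > max_missing)) {
      n_drop <- sum(frac_missing > max_missing)
      inform(paste0(
        n_drop, " profile(s) dropped: > ", 100 * max_missing,
        "% of robust features missing."
      ))
      out <- out[frac_missing <= max_missing, , drop = FALSE]
      zmat <- zmat[frac_missing <= max_missing, , drop = FALSE]
    }
    out$induction <- apply(zmat, 1, induction, cutoff = cutoff)
  }
  attr(out, "features") <- feats
  attr(out, "diagnostics") <- if (length(diags) > 0) bind_rows(diags) else
    tibble(plate_id = character(), dmso_percent = numeric(),
           feature = character(), control_median = numeric())
  out
}

#' Extract the Z-score matrix of a profile table
#'
#' @param profiles Profile tibble from [zscore_profiles()] (or any table with
#'   feature columns); row names are compound ids where available.
#' @param features Optional explicit feature subset.
#' @return Numeric matrix, rows = profiles, columns = features.
#' @export
profile_matrix <- function(profiles, features = NULL) {
  feats <- as_feature_names(features %||% attr(profiles, "features") %||% feature_columns(profiles))
  m <- as.matrix(profiles[feats])
  if ("compound_id" %in% names(profiles)) {
    rownames(m) <- profiles$compound_id
  }
  m
}

#' Call compound activity from induction
#'
#' A profile is active when its induction reaches the activity threshold
#' (inclusive), by default 5%.
#'
#' @param profiles Profile tibble with an `induction` column.
#' @param threshold Activity threshold in percent.
#' @return `profiles` with an added logical `active` column.
#' @export
call_activity <- function(profiles, threshold = 5) {
  if (!"induction" %in% names(profiles)) {
    abort("`profiles` must carry an `induction` column (see zscore_profiles()).")
  }
  mutate(profiles, active = .data$induction >= threshold)
}

#' Read / write Z-score profile tables
#'
#' Profile tables are flat CSV/Parquet files with one row per
#' (compound, concentration): identifier columns, wide Z-scored feature
#' columns, and `induction` — the schema used for deposited profile data.
#' Reading restores the `"features"` attribute used downstream.
#'
#' @param path File path (`.csv`/`.csv.gz` or `.parquet`).
#' @return A profile tibble.
#' @export
read_profile_table <- function(path) {
  out <- read_feature_table(path)
  attr(out, "features") <- feature_columns(out)
  out
}

#' @rdname read_profile_table
#' @param profiles Profile tibble to write.
#' @export
write_profile_table <- function(profiles, path) {
  write_feature_table(profiles, path)
}
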