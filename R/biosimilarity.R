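#' Biosimilarity of two morphological profiles
#'
#' Profile similarity derived from the correlation distance
#' `CD = 1 - ((x - mean(x)) . (y - mean(y))) / (||x - mean(x)|| ||y - mean(y)||)`:
#' biosimilarity is `(1 - CD) * 100 = Pearson(x, y) * 100`, negative values
#' clipped to 0, so the result lies in `[0, 100]` percent.
#'
#' @param x,y Numeric vectors of equal length >= 2 (paired missing values are
#'   dropped). Constant vectors have undefined correlation and raise an error;
#'   callers that tolerate this (e.g. feature selection) catch it.
#' @return Biosimilarity in percent.
#' @export
biosimilarity <- function(x, y) {
  if (length(x) != length(y)) {
    abort("Profiles must have equal length.")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2) {
    abort("Need at least 2 paired finite values.")
  }
  sx <- x - mean(x)
  sy <- y - mean(y)
  nx <- sqrt(sum(sx^2))
  ny <- sqrt(sum(sy^2))
  if (nx == 0 || ny == 0) {
    abort("Correlation is undefined for a constant profile.")
  }
  r <- sum(sx * sy) / (nx * ny)
  max(0, r) * 100
}

# Well sort key: row letter(s) then column number, i.e. row-major A01..P24.
.well_order <- function(well) {
  row <- gsub("[0-9]+$", "", well)
  col <- suppressWarnings(as.integer(gsub("^[A-Za-z]+", "", well)))
  order(row, col)
}

#' Select robust features from two repeats of a reference plate
#'
#' For every feature, its whole-plate profile (value vector across wells in
#' fixed row-major well order) is computed in each repeat; the feature is
#' retained when the cross-repeat biosimilarity of the two per-feature well
#' vectors reaches `min_similarity`. Features with a constant (zero-variance)
#' vector in either repeat have undefined similarity and are excluded with a
#' message.
#'
#' @param repeat_a,repeat_b Well-level feature tables of the same reference
#'   plate layout (same wells, same features).
#' @param min_similarity Retention cutoff in percent (80 corresponds to the
#'   similarity >= 0.8 rule).
#' @return Tibble of class `robust_features` with columns `feature`,
#'   `similarity` (percent, `NA` for zero-variance features) and `retained`;
#'   attribute `"min_similarity"`.
#' @export
select_robust_features <- function(repeat_a, repeat_b, min_similarity = 80) {
  feats <- feature_columns(repeat_a)
  if (!setequal(feats, feature_columns(repeat_b))) {
    abort("The two repeats must share the same feature set.")
  }
  if (!setequal(repeat_a$well, repeat_b$well)) {
    only_a <- setdiff(repeat_a$well, repeat_b$well)
    only_b <- setdiff(repeat_b$well, repeat_a$well)
    abort(paste0(
      "Well sets differ between repeats. Only in A: ",
      toString(head(only_a, 5)), "; only in B: ", toString(head(only_b, 5))
    ))
  }
  a <- repeat_a[.well_order(repeat_a$well), , drop = FALSE]
  b <- repeat_b[.well_order(repeat_b$well), , drop = FALSE]
  sim <- vapply(feats, function(f) {
    tryCatch(biosimilarity(a[[f]], b[[f]]), error = function(e) NA_real_)
  }, numeric(1))
  n_const <- sum(is.na(sim))
  if (n_const > 0) {
    inform(paste0(n_const, " feature(s) excluded: zero variance in at least one repeat."))
  }
  out <- tibble(
    feature = feats,
    similarity = unname(sim),
    retained = !is.na(sim) & sim >= min_similarity
  )
  class(out) <- c("robust_features", class(out))
  attr(out, "min_similarity") <- min_similarity
  out
}

#' Replicate concordance of two profiling runs
#'
#' Compares two runs of Z-score profiles compound by compound: cross-run
#' profile biosimilarity, induction in each run, and summary reproducibility
#' statistics (Pearson r and r-squared of induction values, median
#' biosimilarity, fraction of compounds with biosimilarity at or above
#' `biosim_threshold`, and the confirmed-active fraction: among compounds
#' active in run 1, the fraction also active in run 2).
#'
#' @param run1,run2 Profile tibbles from [zscore_profiles()]. Compounds are
#'   matched on `compound_id` (and `concentration_um` when present in both);
#'   the intersection is used and mismatches are reported.
#' @param biosim_threshold Reproducibility threshold on biosimilarity, percent.
#' @param activity_threshold Induction threshold defining "active" in run 1.
#' @param confirm_threshold Induction threshold for confirmation in run 2
#'   (defaults to `activity_threshold`).
#' @return Object of class `replicate_concordance` with elements `compounds`
#'   (per-compound tibble) and `summary` (one-row tibble). Use [tidy()] /
#'   [glance()] / [autoplot()].
#' @export
replicate_concordance <- function(run1, run2, biosim_threshold = 80,
                                  activity_threshold = 5,
                                  confirm_threshold = activity_threshold) {
  keys <- intersect(
    intersect(c("compound_id", "concentration_um"), names(run1)),
    names(run2)
  )
  if (!"compound_id" %in% keys) {
    abort("Both runs must carry a compound_id column.")
  }
  feats <- intersect(
    as_feature_names(attr(run1, "features") %||% feature_columns(run1)),
    as_feature_names(attr(run2, "features") %||% feature_columns(run2))
  )
  r1 <- if ("role" %in% names(run1)) filter(run1, .data$role == "test") else run1
  r2 <- if ("role" %in% names(run2)) filter(run2, .data$role == "test") else run2
  shared <- inner_join(
    r1 %>% select(all_of(keys), all_of(feats), induction_run1 = "induction"),
    r2 %>% select(all_of(keys), all_of(feats), induction_run2 = "induction"),
    by = keys, suffix = c("_run1", "_run2")
  )
  if (nrow(shared) == 0) {
    abort("The two runs share no compounds.")
  }
  n_only1 <- nrow(r1) - nrow(shared)
  n_only2 <- nrow(r2) - nrow(shared)
  if (n_only1 > 0 || n_only2 > 0) {
    inform(paste0(
      "Unmatched profiles ignored: ", n_only1, " in run 1, ", n_only2, " in run 2."
    ))
  }
  f1 <- paste0(feats, "_run1")
  f2 <- paste0(feats, "_run2")
  m1 <- as.matrix(shared[f1])
  m2 <- as.matrix(shared[f2])
  biosim <- vapply(seq_len(nrow(shared)), function(i) {
    tryCatch(biosimilarity(m1[i, ], m2[i, ]), error = function(e) NA_real_)
  }, numeric(1))
  compounds <- shared %>%
    select(all_of(keys), "induction_run1", "induction_run2") %>%
    mutate(
      biosimilarity = biosim,
      active_run1 = .data$induction_run1 >= activity_threshold,
      confirmed = .data$active_run1 & .data$induction_run2 >= confirm_threshold
    )
  r <- suppressWarnings(cor(compounds$induction_run1, compounds$induction_run2))
  n_active1 <- sum(compounds$active_run1)
  summary <- tibble(
    n_compounds = nrow(compounds),
    induction_pearson_r = r,
    induction_r_squared = r^2,
    median_biosimilarity = median(compounds$biosimilarity, na.rm = TRUE),
    frac_biosim_ge_threshold = mean(compounds$biosimilarity >= biosim_threshold, na.rm = TRUE),
    n_active_run1 = n_active1,
    frac_confirmed = if (n_active1 > 0) sum(compounds$confirmed) / n_active1 else NA_real_
  )
  structure(
    list(
      compounds = compounds, summary = summary,
      thresholds = list(
        biosim = biosim_threshold, activity = activity_threshold,
        confirm = confirm_threshold
      )
    ),
    class = "replicate_concordance"
  )
}

#' @export
print.replicate_concordance <- function(x, ...) {
  s <- x$summary
  cat("Replicate concordance over", s$n_compounds, "compounds\n")
  cat(sprintf(
    "  induction: r = %.3f (r^2 = %.3f)\n",
    s$induction_pearson_r, s$induction_r_squared
  ))
  cat(sprintf("  median biosimilarity: %.1f%%\n", s$median_biosimilarity))
  cat(sprintf(
    "  biosimilarity >= %g%%: %.1f%% of compounds\n",
    x$thresholds$biosim, 100 * s$frac_biosim_ge_threshold
  ))
  cat(sprintf(
    "  confirmed active: %d/%d (%.1f%%)\n",
    round(s$frac_confirmed * s$n_active_run1), s$n_active_run1,
    100 * s$frac_confirmed
  ))
  invisible(x)
}
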