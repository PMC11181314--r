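#' Plot replicate induction concordance
#'
#' Scatter of induction in run 1 vs run 2 with the identity line, colouring
#' confirmed actives — the standard replicate-reproducibility view.
#'
#' @param object A [replicate_concordance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replicate_concordance <- function(object, ...) {
  ggplot(object$compounds, aes(
    x = .data$induction_run1, y = .data$induction_run2,
    colour = .data$confirmed
  )) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point(alpha = 0.7) +
    labs(
      x = "Induction, run 1 (%)", y = "Induction, run 2 (%)",
      colour = "Confirmed",
      title = sprintf(
        "Replicate concordance (r = %.2f, median biosimilarity = %.0f%%)",
        object$summary$induction_pearson_r, object$summary$median_biosimilarity
      )
    )
}

#' Plot per-cluster compound counts
#'
#' Bar chart of the number of compounds assigned to each bioactivity cluster
#' (plus the unassigned "no cluster" bar).
#'
#' @param object A [assign_clusters()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  counts <- cluster_counts(object)
  counts$cluster <- factor(counts$cluster, levels = rev(counts$cluster))
  ggplot(counts, aes(x = .data$cluster, y = .data$n_compounds)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(
      x = NULL, y = "Compounds",
      title = sprintf("Cluster assignments (biosimilarity >= %g%%)", attr(object, "threshold"))
    )
}

#' Plot the robust-feature similarity distribution
#'
#' Histogram of cross-repeat feature similarities with the retention cutoff.
#'
#' @param object A [select_robust_features()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.robust_features <- function(object, ...) {
  ggplot(object, aes(x = .data$similarity)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey30", na.rm = TRUE) +
    geom_vline(xintercept = attr(object, "min_similarity"),
               colour = "firebrick", linetype = "dashed") +
    labs(
      x = "Cross-repeat biosimilarity (%)", y = "Features",
      title = sprintf(
        "Robust feature selection: %d / %d retained",
        sum(object$retained), nrow(object)
      )
    )
}

#' Plot funnel stage counts
#'
#' @param object A [apply_funnel()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.funnel_report <- function(object, ...) {
  s <- object$stages
  s$stage <- factor(s$stage, levels = rev(s$stage))
  ggplot(s, aes(x = .data$stage, y = .data$n_kept)) +
    geom_col(fill = "darkorange") +
    coord_flip() +
    labs(x = NULL, y = "Compounds remaining", title = "Curation funnel")
}
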