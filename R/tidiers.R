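#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_histogram geom_vline labs coord_flip
#' @export
ggplot2::autoplot

#' @rdname replicate_concordance
#' @param x A `replicate_concordance` object.
#' @param ... Unused.
#' @export
tidy.replicate_concordance <- function(x, ...) x$compounds

#' @rdname replicate_concordance
#' @export
glance.replicate_concordance <- function(x, ...) x$summary

#' @rdname assign_clusters
#' @param x A `cluster_assignment` table.
#' @param ... Unused.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  cl <- attr(x, "clusters")
  ids <- intersect(c("compound_id", "concentration_um"), names(x))
  x %>%
    as_tibble() %>%
    select(all_of(ids), all_of(cl)) %>%
    tidyr::pivot_longer(all_of(cl), names_to = "cluster", values_to = "biosimilarity") %>%
    mutate(assigned = !is.na(.data$biosimilarity) &
             .data$biosimilarity >= attr(x, "threshold"))
}

#' @rdname assign_clusters
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(
    n_compounds = nrow(x),
    n_clusters = length(attr(x, "clusters")),
    threshold = attr(x, "threshold"),
    n_assigned = sum(x$n_assigned > 0),
    n_unassigned = sum(x$n_assigned == 0)
  )
}

#' @rdname apply_funnel
#' @param x A `funnel_report`.
#' @param ... Unused.
#' @export
tidy.funnel_report <- function(x, ...) as_tibble(x$records)

#' @rdname apply_funnel
#' @export
glance.funnel_report <- function(x, ...) {
  s <- x$stages
  tibble(
    n_input = s$n_kept[s$stage == "input"],
    n_after_availability = s$n_kept[s$stage == "availability"],
    n_after_size = s$n_kept[s$stage == "size"],
    n_after_overlap = s$n_kept[s$stage == "overlap"]
  )
}

#' @rdname select_robust_features
#' @param x A `robust_features` table.
#' @param ... Unused.
#' @export
glance.robust_features <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_retained = sum(x$retained),
    n_undefined = sum(is.na(x$similarity)),
    min_similarity = attr(x, "min_similarity")
  )
}

#' @rdname build_subprofile
#' @param x A `cluster_subprofile`.
#' @param ... Unused.
#' @export
tidy.cluster_subprofile <- function(x, ...) {
  tibble(feature = x$feature_names, median_z = x$median_z)
}

#' @rdname build_subprofile
#' @export
glance.cluster_subprofile <- function(x, ...) {
  tibble(
    name = x$name, n_features = length(x$feature_names),
    n_defining = x$n_defining, consistency = x$consistency
  )
}
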