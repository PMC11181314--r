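#' Build a bioactivity cluster subprofile
#'
#' A cluster subprofile is the reduced median profile of a set of
#' cluster-defining Z-score profiles. For each feature the numbers of strictly
#' positive and strictly negative values across the defining profiles are
#' counted; the feature enters the subprofile when
#' `max(n_pos, n_neg) / n_defining >= consistency` (inclusive; zero values
#' count toward neither sign but stay in the denominator). The subprofile
#' value of a retained feature is the median of that feature over all defining
#' profiles.
#'
#' @param defining Profile tibble ([zscore_profiles()] rows) of the
#'   cluster-defining compounds.
#' @param name Cluster name (e.g. `"tubulin"`, `"DNA synthesis"`).
#' @param consistency Sign-consistency fraction in `(0, 1]`.
#' @param features Optional feature subset; defaults to the profile table's
#'   feature columns.
#' @return Object of class `cluster_subprofile`: list with `name`,
#'   `feature_names`, `median_z`, `n_defining`, `consistency`.
#' @export
build_subprofile <- function(defining, name, consistency = 0.85, features = NULL) {
  feats <- as_feature_names(features %||% attr(defining, "features") %||% feature_columns(defining))
  if (nrow(defining) < 1) {
    abort("A cluster needs at least one defining profile.")
  }
  z <- as.matrix(defining[feats])
  n_def <- nrow(z)
  n_pos <- colSums(z > 0, na.rm = TRUE)
  n_neg <- colSums(z < 0, na.rm = TRUE)
  keep <- pmax(n_pos, n_neg) / n_def >= consistency
  if (!any(keep)) {
    abort(paste0("Cluster '", name, "': no feature passes the sign-consistency rule."))
  }
  median_z <- apply(z[, keep, drop = FALSE], 2, median, na.rm = TRUE)
  structure(
    list(
      name = name,
      feature_names = feats[keep],
      median_z = unname(median_z),
      n_defining = n_def,
      consistency = consistency
    ),
    class = "cluster_subprofile"
  )
}

#' @export
print.cluster_subprofile <- function(x, ...) {
  cat(
    "Cluster subprofile '", x$name, "': ", length(x$feature_names),
    " features from ", x$n_defining, " defining profile(s) (consistency >= ",
    x$consistency, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Biosimilarity of profiles to a cluster subprofile
#'
#' Restricts each profile to the subprofile's feature subset and computes the
#' biosimilarity against the cluster's median Z-values.
#'
#' @param profiles Profile tibble covering all subprofile features.
#' @param subprofile A [build_subprofile()] result.
#' @return Tibble with the profile identifiers and a `biosimilarity` column
#'   (`NA` where the restricted profile is constant).
#' @export
cluster_biosimilarity <- function(profiles, subprofile) {
  stopifnot(inherits(subprofile, "cluster_subprofile"))
  missing_feats <- setdiff(subprofile$feature_names, names(profiles))
  if (length(missing_feats) > 0) {
    abort(paste0(
      "Profiles lack subprofile features: ", toString(head(missing_feats, 5))
    ))
  }
  m <- as.matrix(profiles[subprofile$feature_names])
  biosim <- vapply(seq_len(nrow(m)), function(i) {
    tryCatch(biosimilarity(m[i, ], subprofile$median_z), error = function(e) NA_real_)
  }, numeric(1))
  ids <- intersect(c("compound_id", "concentration_um"), names(profiles))
  bind_cols(profiles[ids], tibble(biosimilarity = biosim))
}

#' Assign compounds to bioactivity clusters
#'
#' Computes each profile's biosimilarity to every cluster subprofile and
#' assigns the profile to all clusters reaching `threshold` (inclusive).
#' Profiles matching no cluster are labelled `"no cluster"`.
#'
#' @param profiles Profile tibble.
#' @param subprofiles List of [build_subprofile()] results (names taken from
#'   the subprofiles themselves).
#' @param threshold Cluster biosimilarity threshold in percent.
#' @return Tibble of class `cluster_assignment`: identifiers, one
#'   biosimilarity column per cluster, `assigned` (list column of cluster
#'   names), `n_assigned`, and `top_cluster` (`"no cluster"` when unassigned).
#' @export
assign_clusters <- function(profiles, subprofiles, threshold = 80) {
  stopifnot(length(subprofiles) >= 1)
  cl_names <- unname(vapply(subprofiles, function(s) s$name, character(1)))
  if (anyDuplicated(cl_names)) {
    abort("Cluster names must be unique.")
  }
  sims <- lapply(subprofiles, function(s) cluster_biosimilarity(profiles, s)$biosimilarity)
  sim_tbl <- as_tibble(setNames(sims, cl_names))
  sim_mat <- as.matrix(sim_tbl)
  assigned <- lapply(seq_len(nrow(sim_mat)), function(i) {
    cl_names[!is.na(sim_mat[i, ]) & sim_mat[i, ] >= threshold]
  })
  top <- vapply(seq_len(nrow(sim_mat)), function(i) {
    v <- sim_mat[i, ]
    if (all(is.na(v)) || length(assigned[[i]]) == 0) "no cluster" else cl_names[which.max(v)]
  }, character(1))
  ids <- intersect(c("compound_id", "concentration_um"), names(profiles))
  out <- bind_cols(
    profiles[ids], sim_tbl,
    tibble(
      assigned = assigned,
      n_assigned = lengths(assigned),
      top_cluster = top
    )
  )
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "clusters") <- cl_names
  attr(out, "threshold") <- threshold
  out
}

#' Per-cluster compound counts from an assignment table
#'
#' Summary in the style of a per-cluster activity bar chart: for each cluster,
#' the number of compounds whose biosimilarity reached the assignment
#' threshold, plus the count of compounds assigned to no cluster.
#'
#' @param assignment A [assign_clusters()] result.
#' @return Tibble with `cluster` and `n_compounds`.
#' @export
cluster_counts <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cl <- attr(assignment, "clusters")
  counts <- vapply(cl, function(k) {
    sum(vapply(assignment$assigned, function(a) k %in% a, logical(1)))
  }, numeric(1))
  bind_rows(
    tibble(cluster = cl, n_compounds = unname(counts)),
    tibble(cluster = "no cluster", n_compounds = sum(assignment$n_assigned == 0))
  )
}

#' Hierarchical clustering on the non-cluster feature space
#'
#' Restricts profiles to the complement of a cluster subprofile's features
#' (the "non-cluster" features) and performs hierarchical clustering with
#' correlation distance (`1 - Pearson`) and, by default, average linkage.
#' Deterministic given the input order.
#'
#' @param profiles Profile tibble with >= 2 rows.
#' @param exclude A [build_subprofile()] result (its features are removed) or
#'   a character vector of feature names.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param features Full feature universe; defaults to the profile table's.
#' @return An [stats::hclust] object, leaves labelled by `compound_id`;
#'   attribute `"n_features_used"` records the complement size.
#' @export
cluster_residual <- function(profiles, exclude, linkage = "average", features = NULL) {
  feats <- as_feature_names(features %||% attr(profiles, "features") %||% feature_columns(profiles))
  excl <- as_feature_names(exclude)
  used <- setdiff(feats, excl)
  if (length(used) == 0) {
    abort("No features remain after excluding the cluster features.")
  }
  if (nrow(profiles) < 2) {
    abort("Need at least 2 profiles to cluster.")
  }
  m <- profile_matrix(profiles, used)
  d <- as.dist(1 - suppressWarnings(cor(t(m))))
  hc <- hclust(d, method = linkage)
  if ("compound_id" %in% names(profiles)) {
    hc$labels <- profiles$compound_id
  }
  attr(hc, "n_features_used") <- length(used)
  hc
}

#' Read / write cluster subprofiles
#'
#' Serializes a subprofile as CSV (columns `feature`, `median_z`) with the
#' name, defining-profile count and consistency in `#`-comment header lines.
#'
#' @param x A `cluster_subprofile`.
#' @param path Output/input file path.
#' @return `write_subprofile()`: the path, invisibly. `read_subprofile()`: a
#'   `cluster_subprofile`.
#' @export
write_subprofile <- function(x, path) {
  stopifnot(inherits(x, "cluster_subprofile"))
  header <- c(
    paste0("# name: ", x$name),
    paste0("# n_defining: ", x$n_defining),
    paste0("# consistency: ", x$consistency)
  )
  writeLines(
    c(header, "feature,median_z",
      paste(x$feature_names, format(x$median_z, digits = 17, scientific = TRUE), sep = ",")),
    path
  )
  invisible(path)
}

#' @rdname write_subprofile
#' @export
read_subprofile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  body <- readr::read_csv(I(lines[!grepl("^#", lines)]), show_col_types = FALSE, progress = FALSE)
  structure(
    list(
      name = get("name"),
      feature_names = body$feature,
      median_z = body$median_z,
      n_defining = as.integer(get("n_defining")),
      consistency = as.numeric(get("consistency"))
    ),
    class = "cluster_subprofile"
  )
}
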