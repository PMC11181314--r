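#' Default pipeline configuration
#'
#' All screen thresholds as named keys, defaulting to the values used
#' throughout the package: activity at induction >= 5%, retest selection at
#' >= 10%, confirmation at >= 10% in the second run, replicate biosimilarity threshold 80%,
#' robust-feature similarity >= 80 (i.e. 0.8), cluster sign consistency 0.85,
#' cluster biosimilarity threshold 80%, |z| significance cutoff 3,
#' availability >= 2 mg and NumHA >= 25 for the curation funnel.
#'
#' @param seed Integer seed driving every random draw.
#' @param ... Overrides for any default key.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(seed, ...) {
  if (missing(seed)) abort("A seed is required.")
  defaults <- list(
    seed = as.integer(seed),
    # synthetic study
    n_compounds = 60,
    active_fraction = 0.3,
    n_features = 579,
    n_wells_per_plate = 384,
    n_sites = 9,
    control_fraction = 1 / 6,
    effect_size = 4,
    noise_sd = 1,
    precipitation_rate = 0.096,
    reference_effect_size = 10,
    # analysis thresholds
    z_cutoff = 3,
    activity_threshold = 5,
    retest_threshold = 10,
    confirm_threshold = 10,
    biosim_threshold = 80,
    robust_min_similarity = 80,
    consistency = 0.85,
    cluster_threshold = 80,
    # curation
    min_mg = 2,
    min_heavy = 25,
    n_pick = 3
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", toString(unknown)))
  }
  modifyList(defaults, overrides)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()`: a config list; `write_pipeline_config()`:
#'   the path, invisibly. The round trip is lossless.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = cfg$seed), cfg[setdiff(names(cfg), "seed")]))
}

#' @rdname read_pipeline_config
#' @param config A config list from [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Run the full profiling pipeline on a synthetic study
#'
#' Orchestrates every stage end to end on generated data with known ground
#' truth: replicate-pair generation (with precipitation failures), site-to-
#' well aggregation, robust-feature selection from a reference-plate repeat
#' pair, MAD Z-score profiling, induction and activity calls, replicate
#' concordance, cluster subprofile construction from the confirmed actives,
#' cluster assignment and per-cluster counts, and the toy curation funnel
#' with a seeded diversity pick. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()] list (or a path to its YAML form).
#' @param out_dir Optional directory; when given, all tables plus a JSON run
#'   manifest are written there.
#' @return List with elements `manifest`, `truth`, `robust_features`,
#'   `profiles_run1`, `profiles_run2`, `activity`, `concordance`,
#'   `subprofiles`, `assignment`, `cluster_counts`, `funnel`, `selected`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  spec <- synth_spec(
    n_features = cfg$n_features, n_wells_per_plate = cfg$n_wells_per_plate,
    n_sites = cfg$n_sites, control_fraction = cfg$control_fraction,
    effect_size = cfg$effect_size, noise_sd = cfg$noise_sd,
    precipitation_rate = cfg$precipitation_rate, seed = cfg$seed
  )
  clusters <- names(spec$cluster_templates)
  assignments <- .with_seed(cfg$seed + 3L, {
    n_active <- round(cfg$active_fraction * cfg$n_compounds)
    cl <- c(
      sample(clusters, n_active, replace = TRUE),
      rep(NA_character_, cfg$n_compounds - n_active)
    )
    setNames(cl, sprintf("SYN-%04d", seq_len(cfg$n_compounds)))
  })

  pair <- synth_replicate_pair(spec, assignments)
  wells1 <- aggregate_wells(pair$run1)
  wells2 <- aggregate_wells(pair$run2)

  # Robust-feature selection from a dedicated reference-plate repeat pair:
  # the reference plate carries strong-phenotype reference compounds (every
  # well perturbed, larger effect), as in a real reference layout.
  ref_spec <- synth_spec(
    n_features = cfg$n_features, n_wells_per_plate = cfg$n_wells_per_plate,
    n_sites = cfg$n_sites, control_fraction = cfg$control_fraction,
    effect_size = cfg$reference_effect_size, noise_sd = cfg$noise_sd,
    seed = cfg$seed
  )
  ref_assign <- setNames(
    rep(clusters, length.out = cfg$n_compounds),
    sprintf("REF-%04d", seq_len(cfg$n_compounds))
  )
  ref1 <- aggregate_wells(synth_run(ref_spec, ref_assign, run = 11))
  ref2 <- aggregate_wells(synth_run(ref_spec, ref_assign, run = 12))
  ref_plate <- ref1$plate_id[1]
  robust <- select_robust_features(
    filter(ref1, .data$plate_id == ref_plate),
    filter(ref2, .data$plate_id == sub("run11", "run12", ref_plate)),
    min_similarity = cfg$robust_min_similarity
  )

  prof1 <- zscore_profiles(wells1, robust, cutoff = cfg$z_cutoff)
  prof2 <- zscore_profiles(wells2, robust, cutoff = cfg$z_cutoff)
  activity <- call_activity(prof1, threshold = cfg$activity_threshold) %>%
    select("plate_id", "well", "compound_id", "concentration_um", "induction", "active")

  # only initially active compounds are retested
  retest <- filter(prof1, .data$induction >= cfg$retest_threshold)
  conc <- replicate_concordance(
    retest, prof2,
    biosim_threshold = cfg$biosim_threshold,
    activity_threshold = cfg$retest_threshold,
    confirm_threshold = cfg$confirm_threshold
  )
  confirmed_ids <- conc$compounds$compound_id[conc$compounds$confirmed]

  truth <- pair$truth
  subprofiles <- list()
  for (cl in clusters) {
    defining_ids <- intersect(
      truth$compound_id[!is.na(truth$cluster) & truth$cluster == cl],
      confirmed_ids
    )
    defining <- filter(prof1, .data$compound_id %in% defining_ids)
    if (nrow(defining) >= 1) {
      subprofiles[[cl]] <- build_subprofile(
        defining, name = cl, consistency = cfg$consistency,
        features = attr(prof1, "features")
      )
    }
  }

  confirmed_prof <- filter(prof1, .data$compound_id %in% confirmed_ids)
  assignment <- NULL
  counts <- NULL
  if (length(subprofiles) > 0 && nrow(confirmed_prof) > 0) {
    assignment <- assign_clusters(confirmed_prof, subprofiles, threshold = cfg$cluster_threshold)
    counts <- cluster_counts(assignment)
  }

  toy <- synth_toy_sdf()
  std <- standardize_compounds(toy)
  ref_keys <- std$inchikey[std$overlaps_reference]
  funnel <- apply_funnel(std, reference_keys = ref_keys,
                         min_mg = cfg$min_mg, min_heavy = cfg$min_heavy)
  kept <- filter(funnel$records, .data$kept)
  selected <- select_diverse(kept, n_pick = min(cfg$n_pick, nrow(kept)), seed = cfg$seed)

  manifest <- list(
    package = "cellpaintr",
    version = as.character(packageVersion("cellpaintr")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = cfg,
    inputs = list(kind = "synthetic", n_compounds = cfg$n_compounds)
  )

  out <- list(
    manifest = manifest, truth = truth, robust_features = robust,
    profiles_run1 = prof1, profiles_run2 = prof2, activity = activity,
    concordance = conc, subprofiles = subprofiles, assignment = assignment,
    cluster_counts = counts, funnel = funnel, selected = selected
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    readr::write_csv(activity, file.path(out_dir, "activity.csv"), progress = FALSE)
    readr::write_csv(glance(conc), file.path(out_dir, "concordance_summary.csv"), progress = FALSE)
    readr::write_csv(tidy(conc), file.path(out_dir, "concordance_compounds.csv"), progress = FALSE)
    readr::write_csv(as_tibble(robust), file.path(out_dir, "robust_features.csv"), progress = FALSE)
    if (!is.null(counts)) {
      readr::write_csv(counts, file.path(out_dir, "cluster_counts.csv"), progress = FALSE)
    }
    readr::write_csv(funnel$stages, file.path(out_dir, "funnel_stages.csv"), progress = FALSE)
  }
  out
}
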