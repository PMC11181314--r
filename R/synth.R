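# Evaluate expr under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic Cell Painting run
#'
#' Bundles the generator parameters of a synthetic morphological-profiling
#' study. The defaults emulate the study conditions the analysis pipeline
#' targets: 579 robust features, 384-well plates with 9 microscope sites per
#' well and one-sixth DMSO control wells (64 per plate), compound effects of 4 control-MADs
#' on the features an effect template touches, unit well noise (in MAD
#' units), and a 9.6% precipitation failure rate in the second replicate.
#'
#' @param n_features Number of image features.
#' @param n_wells_per_plate Wells per plate.
#' @param n_sites Microscope sites per well (aggregated by median).
#' @param control_fraction Fraction of wells per plate that are DMSO controls.
#' @param cluster_templates Named list of effect templates (one per
#'   bioactivity cluster): numeric vectors of length `n_features` with
#'   entries in `{-1, 0, +1}` marking decreased / untouched / increased
#'   features (see [synth_templates()]).
#' @param effect_size Per-affected-feature shift of an active compound, in
#'   control-MAD units.
#' @param noise_sd Well-to-well noise level in control-MAD units (the raw MAD
#'   of the well noise equals `noise_sd`).
#' @param site_noise_sd Site-to-site jitter within a well, same units.
#' @param precipitation_rate Fraction of active compounds whose effect is
#'   zeroed in replicate 2 (freeze–thaw precipitation failure mode).
#' @param replicate_correlation Multiplier on effect sizes in replicate 2
#'   (1 = fully shared effects; lower values attenuate run-2 effects).
#' @param noise `"gaussian"` or `"t"` (Student t, df = 3, heavy-tailed).
#' @param concentration_um Nominal test concentration.
#' @param seed Mandatory integer seed; every draw derives from it.
#' @return Object of class `synth_spec` (a named list).
#' @export
synth_spec <- function(n_features = 579, n_wells_per_plate = 384, n_sites = 9,
                       control_fraction = 1 / 6, cluster_templates = NULL,
                       effect_size = 4, noise_sd = 1, site_noise_sd = 0.5,
                       precipitation_rate = 0.096, replicate_correlation = 1,
                       noise = c("gaussian", "t"), concentration_um = 10,
                       seed) {
  if (missing(seed)) abort("A seed is required.")
  noise <- match.arg(noise)
  if (is.null(cluster_templates)) {
    cluster_templates <- synth_templates(n_features, seed = seed)
  }
  bad <- vapply(cluster_templates, function(t) length(t) != n_features, logical(1))
  if (any(bad)) {
    abort("Every cluster template must have length n_features.")
  }
  stopifnot(
    control_fraction > 0, control_fraction < 1,
    precipitation_rate >= 0, precipitation_rate <= 1
  )
  structure(
    list(
      n_features = n_features, n_wells_per_plate = n_wells_per_plate,
      n_sites = n_sites, control_fraction = control_fraction,
      cluster_templates = cluster_templates, effect_size = effect_size,
      noise_sd = noise_sd, site_noise_sd = site_noise_sd,
      precipitation_rate = precipitation_rate,
      replicate_correlation = replicate_correlation, noise = noise,
      concentration_um = concentration_um, seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Random sign-pattern effect templates for bioactivity clusters
#'
#' Each template marks a random `frac_active` subset of features with a
#' random sign; an active compound of that cluster shifts those features by
#' `effect_size` control-MADs in the template's direction.
#'
#' @param n_features Feature count.
#' @param clusters Cluster names.
#' @param frac_active Fraction of features each template touches.
#' @param seed Integer seed.
#' @return Named list of numeric vectors with entries in `{-1, 0, +1}`.
#' @export
synth_templates <- function(n_features,
                            clusters = c("tubulin", "DNA synthesis", "lysosomotropism"),
                            frac_active = 0.15, seed) {
  if (missing(seed)) abort("A seed is required.")
  n_active <- max(1, round(frac_active * n_features))
  .with_seed(seed + 7L, {
    setNames(lapply(seq_along(clusters), function(i) {
      t <- numeric(n_features)
      idx <- sample.int(n_features, n_active)
      t[idx] <- sample(c(-1, 1), n_active, replace = TRUE)
      t
    }), clusters)
  })
}

# Noise draw whose raw MAD equals `sd` in expectation.
.synth_noise <- function(n, sd, kind) {
  if (kind == "t") {
    sd * rt(n, df = 3) / stats::qt(0.75, df = 3)
  } else {
    sd * rnorm(n) / stats::qnorm(0.75)
  }
}

# Per-feature baseline medians and MADs, log-uniform to avoid scale
# homogeneity across features; deterministic in the spec seed so replicate
# runs share the same baseline.
.synth_baseline <- function(spec) {
  .with_seed(spec$seed + 13L, {
    med <- 10^runif(spec$n_features, 0, 2)
    mad <- med * 10^runif(spec$n_features, -1.3, -0.7)
    list(median = med, mad = mad)
  })
}

#' Generate a synthetic site-level profiling run
#'
#' Produces a site-level feature table with known ground truth. Control wells
#' fluctuate around per-feature baselines (log-uniform medians and MADs);
#' each test well adds `effect_size x template(assigned cluster)` (in
#' control-MAD units) plus independent well noise; site values jitter around
#' the well value. Compounds are distributed over as many plates as needed,
#' each plate carrying its own control wells. Fully reproducible from the
#' spec seed; different `run` indices reuse the same baseline and ground
#' truth but draw independent noise.
#'
#' @param spec A [synth_spec()].
#' @param assignments Named character vector: compound id -> cluster name, or
#'   `NA` for an inactive compound.
#' @param run Replicate index (changes the noise stream only).
#' @param zero_effect Compound ids whose effect is zeroed in this run
#'   (precipitation failure mode).
#' @param effect_multiplier Scales all effects in this run.
#' @return Site-level feature-table tibble; attribute `"truth"` holds the
#'   ground-truth tibble (`compound_id`, `cluster`, `effect_size`, `active`).
#' @export
synth_run <- function(spec, assignments, run = 1, zero_effect = character(),
                      effect_multiplier = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  compounds <- names(assignments)
  if (is.null(compounds) || any(compounds == "")) {
    abort("`assignments` must be a named vector (names = compound ids).")
  }
  unknown <- setdiff(stats::na.omit(unname(assignments)), names(spec$cluster_templates))
  if (length(unknown) > 0) {
    abort(paste0("Unknown cluster(s) in assignments: ", toString(unknown)))
  }
  base <- .synth_baseline(spec)
  n_ctrl <- max(3, round(spec$control_fraction * spec$n_wells_per_plate))
  n_test_per_plate <- spec$n_wells_per_plate - n_ctrl
  n_plates <- ceiling(length(compounds) / n_test_per_plate)
  feats <- sprintf("feat_%04d", seq_len(spec$n_features))
  well_names <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24), rep(1:24, 16))
  if (spec$n_wells_per_plate > length(well_names)) {
    abort("n_wells_per_plate cannot exceed 384.")
  }

  truth <- tibble(
    compound_id = compounds,
    cluster = unname(assignments),
    effect_size = ifelse(is.na(assignments), 0, spec$effect_size),
    active = !is.na(assignments)
  )
  eff <- spec$effect_size * effect_multiplier

  .with_seed(spec$seed + 104729L * as.integer(run), {
    plates <- lapply(seq_len(n_plates), function(p) {
      idx <- ((p - 1) * n_test_per_plate + 1):min(p * n_test_per_plate, length(compounds))
      cpds <- compounds[idx]
      n_wells <- n_ctrl + length(cpds)
      wells <- well_names[seq_len(n_wells)]
      roles <- c(rep("control", n_ctrl), rep("test", length(cpds)))
      well_cpd <- c(rep("DMSO", n_ctrl), cpds)
      # well-level effect matrix (MAD units)
      effect <- matrix(0, n_wells, spec$n_features)
      for (j in seq_along(cpds)) {
        cl <- assignments[[cpds[j]]]
        if (!is.na(cl) && !(cpds[j] %in% zero_effect)) {
          effect[n_ctrl + j, ] <- eff * spec$cluster_templates[[cl]]
        }
      }
      well_noise <- matrix(
        .synth_noise(n_wells * spec$n_features, spec$noise_sd, spec$noise),
        n_wells, spec$n_features
      )
      well_val_mad <- effect + well_noise
      rows <- lapply(seq_len(spec$n_sites), function(s) {
        site_noise <- matrix(
          .synth_noise(n_wells * spec$n_features, spec$site_noise_sd, spec$noise),
          n_wells, spec$n_features
        )
        v <- sweep(
          sweep(well_val_mad + site_noise, 2, base$mad, "*"),
          2, base$median, "+"
        )
        colnames(v) <- feats
        bind_cols(
          tibble(
            plate_id = sprintf("plate_%02d_run%d", p, run),
            well = wells, site = s, compound_id = well_cpd,
            concentration_um = ifelse(roles == "test", spec$concentration_um, 0),
            role = roles,
            dmso_percent = 0.1
          ),
          as_tibble(v)
        )
      })
      bind_rows(rows)
    })
    out <- bind_rows(plates) %>% arrange(.data$plate_id, .data$well, .data$site)
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a replicate pair with a precipitation failure mode
#'
#' Two runs sharing compounds, baseline and ground truth, with independent
#' noise. A `precipitation_rate` fraction of the active compounds (chosen
#' reproducibly from the spec seed) precipitates after the freeze–thaw cycle:
#' their effect is zeroed in run 2. Run-2 effects are additionally scaled by
#' `replicate_correlation`.
#'
#' @inheritParams synth_run
#' @return List with `run1`, `run2` (site-level tables) and `truth`
#'   (ground-truth tibble with a `precipitated` column).
#' @export
synth_replicate_pair <- function(spec, assignments) {
  active <- names(assignments)[!is.na(assignments)]
  precipitated <- .with_seed(spec$seed + 31L, {
    n_prec <- round(spec$precipitation_rate * length(active))
    if (n_prec > 0) sample(active, n_prec) else character()
  })
  run1 <- synth_run(spec, assignments, run = 1)
  run2 <- synth_run(
    spec, assignments, run = 2, zero_effect = precipitated,
    effect_multiplier = spec$replicate_correlation
  )
  truth <- attr(run1, "truth") %>%
    mutate(precipitated = .data$compound_id %in% precipitated)
  list(run1 = run1, run2 = run2, truth = truth)
}

#' Toy compound library with ground truth
#'
#' A small fixed compound set exercising every curation step: large clean
#' molecules, a free base and its hydrochloride salt (identical after
#' largest-fragment standardization), low-availability records, sub-25-heavy-
#' atom structures, and a record intended to overlap a reference collection.
#' All structures are ordinary synthetic toys, not real library compounds.
#'
#' @param path Optional file path; when given, the set is written as a V2000
#'   SDF with `ID` and `available` data fields.
#' @param n_corrupt Number of structurally corrupt records appended to the
#'   SDF (for parser robustness tests; only affects the file).
#' @return Tibble with `identifier`, `smiles`, `available_mg` and ground
#'   truth columns `is_small` (NumHA < 25), `low_availability`,
#'   `overlaps_reference`, `salt_of` (identifier of the free base, or `NA`).
#' @export
synth_toy_sdf <- function(path = NULL, n_corrupt = 0) {
  base_amine <- "CN(C)CCCCCCCCCCCCCCCCCCCCCCCN(C)C"
  records <- tibble(
    identifier = sprintf("CPD-%03d", 1:8),
    smiles = c(
      "CCCCCCCCCCCCCCCCCCCCCCCCCC",                   # 26 heavy atoms, clean
      "c1ccc(cc1)CCCCCCCCCCCCCCCCCCCCc1ccccc1",       # 32, marked as reference overlap
      base_amine,                                     # 29, free base
      paste0(base_amine, ".Cl"),                      # HCl salt of CPD-003
      "c1ccc2ccccc2c1CCCCCCCCCCCCCCCCCC",             # 28, low availability
      "OCCCCCCCCCCCCCCCCCCCCCCCCO",                   # 26, low availability
      "CC(=O)Oc1ccccc1C(=O)O",                        # 13, small
      "CCO"                                           # 3, small
    ),
    available_mg = c(10, 8, 5, 5, 0.5, 1, 10, 10),
    is_small = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    low_availability = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    overlaps_reference = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    salt_of = c(NA, NA, NA, "CPD-003", NA, NA, NA, NA)
  )
  if (!is.null(path)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      setNames(records$smiles, records$identifier)
    ))
    ChemmineR::datablock(sdf) <- lapply(seq_len(nrow(records)), function(i) {
      c(ID = records$identifier[i], available = as.character(records$available_mg[i]))
    })
    ChemmineR::write.SDF(sdf, file = path, cid = TRUE)
    # scrub the timestamp OpenBabel embeds in molblock header lines so a
    # seeded run is byte-for-byte reproducible
    lines <- readLines(path)
    lines <- sub("OpenBabel[0-9]+([23]D)", "OpenBabel\\1", lines)
    writeLines(lines, path)
    if (n_corrupt > 0) {
      bad <- c("corrupt_record", "", "",
               " not a counts line", "M  END", "> <ID>", "BAD", "$$$$")
      con <- file(path, open = "a")
      for (k in seq_len(n_corrupt)) writeLines(bad, con)
      close(con)
    }
  }
  records
}
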