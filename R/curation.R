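#' Read a compound library from an SDF file
#'
#' Parses a V2000 SDF, keeping a per-record identifier and the available
#' amount in milligram from the `available` data field (a differently named
#' field can be given). Structurally invalid records are skipped with a
#' position-stamped message and reported in the `"skipped"` attribute.
#'
#' @param path SDF file path.
#' @param id_field Data field holding the identifier; falls back to the
#'   molecule title line when absent.
#' @param available_field Data field holding the available amount (mg).
#' @return Tibble with `identifier`, `smiles` (as stored), `available_mg`.
#' @export
read_compound_sdf <- function(path, id_field = "ID", available_field = "available") {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdfs)
  if (any(!ok)) {
    inform(paste0(
      "Skipped ", sum(!ok), " unreadable SDF record(s) at position(s): ",
      toString(which(!ok))
    ))
  }
  skipped <- unname(which(!ok))
  sdfs <- sdfs[ok]
  blocks <- ChemmineR::datablock(sdfs)
  get_field <- function(block, field) {
    if (field %in% names(block)) block[[field]] else NA_character_
  }
  ids <- unname(vapply(blocks, get_field, character(1), field = id_field))
  titles <- unname(ChemmineR::sdfid(sdfs))
  ids <- ifelse(is.na(ids) | ids == "", titles, ids)
  avail <- suppressWarnings(as.numeric(unname(
    vapply(blocks, get_field, character(1), field = available_field)
  )))
  smis <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdfs)))
  out <- tibble(identifier = ids, smiles = smis, available_mg = avail)
  attr(out, "skipped") <- skipped
  out
}

# OpenBabel molecule references for a SMILES batch (one call, order-preserving).
.ob_mols <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

# Heavy (non-hydrogen) atom count from a molecular formula such as "C8H11N".
.formula_heavy_atoms <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || f == "") return(NA_integer_)
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    el <- sub("[0-9]*$", "", toks)
    cnt <- as.integer(sub("^[A-Za-z]+", "", toks))
    cnt[is.na(cnt)] <- 1L
    sum(cnt[el != "H"])
  }, integer(1), USE.NAMES = FALSE)
}

# Canonical SMILES via OpenBabel; NA when unparseable.
.ob_canonical <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || s == "") return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- strsplit(trimws(out), "[ \t]")[[1]][1]
    if (is.na(out) || out == "") NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

.ob_inchikey <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHIKEY", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- trimws(out)
    if (nchar(out) == 27) out else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Standardize compound records to their largest fragment
#'
#' Splits multi-fragment structures (salts, mixtures) and retains the largest
#' fragment — by heavy-atom count, ties broken by molecular weight, then by
#' canonical SMILES order — then attaches the standard InChIKey and a
#' physicochemical descriptor block (MW, NumHA, logP, TPSA, FrCsp3, NumHAcc,
#' NumHDon). Unparseable structures and failed InChIKeys are kept with missing
#' values and reported, never dropped silently. The operation is idempotent.
#'
#' @param records Tibble with at least `identifier` and `smiles` columns
#'   (e.g. from [read_compound_sdf()]).
#' @return Input tibble plus `smiles_std`, `inchikey`, `mw`, `num_heavy`,
#'   `logp`, `tpsa`, `fr_csp3`, `num_hacc`, `num_hdon`.
#' @export
standardize_compounds <- function(records) {
  stopifnot(all(c("identifier", "smiles") %in% names(records)))
  largest <- vapply(records$smiles, function(s) {
    if (is.na(s) || s == "") return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags <- frags[frags != ""]
    if (length(frags) == 0) return(NA_character_)
    can <- .ob_canonical(frags)
    frags <- can[!is.na(can)]
    if (length(frags) == 0) return(NA_character_)
    if (length(frags) == 1) return(frags)
    props <- ChemmineOB::prop_OB(.ob_mols(frags))
    heavy <- .formula_heavy_atoms(props$formula)
    ord <- order(-heavy, -props$MW, props$cansmi)
    frags[ord[1]]
  }, character(1), USE.NAMES = FALSE)
  n_unparseable <- sum(is.na(largest) & !is.na(records$smiles))
  if (n_unparseable > 0) {
    inform(paste0(n_unparseable, " structure(s) could not be parsed; left missing."))
  }
  keys <- .ob_inchikey(largest)
  n_keyfail <- sum(is.na(keys) & !is.na(largest))
  if (n_keyfail > 0) {
    inform(paste0(n_keyfail, " InChIKey(s) could not be generated."))
  }
  out <- records
  out$smiles_std <- largest
  out$inchikey <- keys
  desc <- tibble(
    mw = NA_real_, num_heavy = NA_integer_, logp = NA_real_, tpsa = NA_real_,
    fr_csp3 = NA_real_, num_hacc = NA_real_, num_hdon = NA_real_
  )[rep(1, nrow(out)), ]
  ok <- !is.na(largest)
  if (any(ok)) {
    mols <- .ob_mols(largest[ok])
    props <- ChemmineOB::prop_OB(mols)
    n_carbon <- ChemmineOB::smartsSearch_OB(mols, "[#6]", uniqueMatches = FALSE)
    n_sp3 <- ChemmineOB::smartsSearch_OB(mols, "[CX4]", uniqueMatches = FALSE)
    desc$mw[ok] <- props$MW
    desc$num_heavy[ok] <- .formula_heavy_atoms(props$formula)
    desc$logp[ok] <- props$logP
    desc$tpsa[ok] <- props$TPSA
    desc$fr_csp3[ok] <- ifelse(n_carbon > 0, n_sp3 / n_carbon, NA_real_)
    desc$num_hacc[ok] <- props$HBA2
    desc$num_hdon[ok] <- props$HBD
  }
  bind_cols(out[setdiff(names(out), names(desc))], desc)
}

#' Library curation funnel
#'
#' Applies the ordered selection stages of the library-curation funnel to
#' standardized records: (1) input; (2) availability (`available_mg >=
#' min_mg`; records with missing amounts fail and are counted separately);
#' (3) size (`num_heavy >= min_heavy`, so a compound with exactly `min_heavy`
#' heavy atoms is kept); (4) overlap removal (drop records whose InChIKey is
#' in `reference_keys`; full-string, case-exact comparison — records without a
#' key cannot match and are kept).
#'
#' @param records Output of [standardize_compounds()].
#' @param reference_keys Character vector of InChIKeys of a reference
#'   collection whose overlap must be removed.
#' @param min_mg Availability threshold, mg (inclusive).
#' @param min_heavy Heavy-atom threshold (inclusive).
#' @return Object of class `funnel_report`: list with `stages` (per-stage
#'   kept/dropped counts), `records` (input plus `exit_stage`: `NA` =
#'   survived), and `params`.
#' @export
apply_funnel <- function(records, reference_keys = character(),
                         min_mg = 2, min_heavy = 25) {
  req <- c("available_mg", "num_heavy", "inchikey")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Records must be standardized first; missing: ", toString(missing_cols)
    ))
  }
  alive <- rep(TRUE, nrow(records))
  exit_stage <- rep(NA_character_, nrow(records))
  stages <- list(c(stage = "input", n_kept = nrow(records), n_dropped = 0))

  fail_avail <- alive & (is.na(records$available_mg) | records$available_mg < min_mg)
  exit_stage[fail_avail] <- "availability"
  alive <- alive & !fail_avail
  stages[[2]] <- c(stage = "availability", n_kept = sum(alive), n_dropped = sum(fail_avail))

  fail_size <- alive & (is.na(records$num_heavy) | records$num_heavy < min_heavy)
  exit_stage[fail_size] <- "size"
  alive <- alive & !fail_size
  stages[[3]] <- c(stage = "size", n_kept = sum(alive), n_dropped = sum(fail_size))

  fail_overlap <- alive & !is.na(records$inchikey) & records$inchikey %in% reference_keys
  exit_stage[fail_overlap] <- "overlap"
  alive <- alive & !fail_overlap
  stages[[4]] <- c(stage = "overlap", n_kept = sum(alive), n_dropped = sum(fail_overlap))

  stage_tbl <- tibble(
    stage = vapply(stages, `[[`, character(1), "stage"),
    n_kept = as.integer(vapply(stages, `[[`, character(1), "n_kept")),
    n_dropped = as.integer(vapply(stages, `[[`, character(1), "n_dropped"))
  )
  structure(
    list(
      stages = stage_tbl,
      records = mutate(records, exit_stage = exit_stage, kept = alive),
      params = list(min_mg = min_mg, min_heavy = min_heavy,
                    n_reference_keys = length(reference_keys)),
      n_missing_available = sum(is.na(records$available_mg))
    ),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Curation funnel (available >=", x$params$min_mg, "mg; NumHA >=",
      x$params$min_heavy, "):\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' Extended-connectivity fingerprints for a SMILES set
#'
#' Circular (Morgan-family) fingerprints via OpenBabel's ECFP implementation;
#' `"ECFP4"` corresponds to radius 2.
#'
#' @param smiles Character vector of valid SMILES.
#' @param type OpenBabel fingerprint name.
#' @return Binary matrix, one row per molecule.
#' @export
compound_fingerprints <- function(smiles, type = "ECFP4") {
  if (any(is.na(smiles))) {
    abort("All structures must be valid (no missing SMILES).")
  }
  fp <- ChemmineOB::fingerprint_OB(.ob_mols(smiles), type)
  rownames(fp) <- NULL
  fp
}

# Pairwise Tanimoto similarity of binary fingerprint rows.
.tanimoto_matrix <- function(fp) {
  inter <- tcrossprod(fp)
  counts <- rowSums(fp)
  denom <- outer(counts, counts, "+") - inter
  sim <- ifelse(denom > 0, inter / denom, 1) # two empty fingerprints: identical
  sim
}

#' MaxMin diversity selection on fingerprint Tanimoto distance
#'
#' Greedy farthest-point (MaxMin) picking: a seeded random record starts the
#' selection; each subsequent pick maximizes the minimum Tanimoto distance to
#' the already-selected set (ties broken by record order). Deterministic given
#' the seed.
#'
#' @param records Standardized records with valid `smiles_std`.
#' @param n_pick Number of compounds to select (>= 1); if `n_pick` is at least
#'   the pool size, all records are returned.
#' @param fp_type Fingerprint type (see [compound_fingerprints()]).
#' @param seed Mandatory integer seed choosing the starting record.
#' @return The selected rows of `records`, in pick order; attribute
#'   `"min_pairwise_distance"` holds the selection's minimum pairwise
#'   Tanimoto distance.
#' @export
select_diverse <- function(records, n_pick, fp_type = "ECFP4", seed) {
  if (missing(seed)) abort("A seed is required for reproducible selection.")
  if (n_pick <= 0) abort("n_pick must be >= 1.")
  smiles <- records$smiles_std %||% records$smiles
  n <- nrow(records)
  if (n_pick >= n) {
    return(records)
  }
  fp <- compound_fingerprints(smiles, fp_type)
  dist <- 1 - .tanimoto_matrix(fp)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  picked <- sample.int(n, 1)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  min_dist <- dist[, picked[1]]
  while (length(picked) < n_pick) {
    min_dist[picked] <- -1
    nxt <- which.max(min_dist) # ties: lowest index
    picked <- c(picked, nxt)
    min_dist <- pmin(min_dist, dist[, nxt])
  }
  out <- records[picked, , drop = FALSE]
  sel_d <- dist[picked, picked]
  attr(out, "picked_order") <- picked
  attr(out, "min_pairwise_distance") <- min(sel_d[upper.tri(sel_d)])
  out
}

#' Curated PAINS substructure catalog
#'
#' A hand-curated catalog of canonical pan-assay-interference (PAINS)
#' substructure families — rhodanines, hydroxyphenyl hydrazones, catechols,
#' quinones, alkylidene barbiturates, isothiazolones, azo dyes — expressed as
#' SMARTS. This is a representative subset of the published alert families,
#' not the full catalog.
#'
#' @return Tibble with `name` and `smarts`.
#' @export
pains_catalog <- function() {
  path <- system.file("extdata", "pains_smarts.tsv", package = "cellpaintr")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Flag PAINS substructures
#'
#' Matches each standardized structure against a PAINS SMARTS catalog and
#' returns the names of all matched patterns (empty = clean).
#'
#' @param smiles Character vector of valid SMILES (use `smiles_std`).
#' @param catalog Pattern table with `name` and `smarts` columns; defaults to
#'   the packaged catalog ([pains_catalog()]).
#' @return List (one element per molecule) of matched pattern names.
#' @export
flag_pains <- function(smiles, catalog = pains_catalog()) {
  if (any(is.na(smiles) | smiles == "")) {
    abort("All structures must be valid SMILES.")
  }
  mols <- .ob_mols(smiles)
  hits <- vapply(catalog$smarts, function(p) {
    ChemmineOB::smartsSearch_OB(mols, p, uniqueMatches = TRUE) > 0
  }, logical(length(smiles)))
  hits <- matrix(hits, nrow = length(smiles))
  lapply(seq_along(smiles), function(i) catalog$name[hits[i, ]])
}

#' Lysosomotropism physicochemical rule
#'
#' Lysosomotropic compounds are weakly basic lipophilic amines; the heuristic
#' flags a compound when `logP > 2` (strict) and its most basic pKa lies in
#' `[6.5, 11]` (inclusive). pKa values are supplied externally (e.g. a sidecar
#' CSV); a missing pKa yields `NA` ("unknown").
#'
#' @param logp Numeric vector of logP values.
#' @param pka Numeric vector of basic pKa values (`NA` = unknown).
#' @return Logical vector (`NA` = unknown).
#' @export
flag_lysosomotropic <- function(logp, pka) {
  ifelse(is.na(pka), NA, logp > 2 & pka >= 6.5 & pka <= 11)
}
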