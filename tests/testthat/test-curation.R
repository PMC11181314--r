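toy_path <- tempfile(fileext = ".sdf")
toy_truth <- synth_toy_sdf(toy_path, n_corrupt = 1)

test_that("SDF reading skips corrupt records with a position log", {
  expect_message(rec <- read_compound_sdf(toy_path), "Skipped 1")
  expect_equal(nrow(rec), 8)
  expect_equal(attr(rec, "skipped"), 9)
  expect_equal(rec$identifier, toy_truth$identifier)
  expect_equal(rec$available_mg, toy_truth$available_mg)
})

std <- standardize_compounds(toy_truth)

test_that("standardization keeps the largest fragment and is idempotent", {
  # hydrochloride salt collapses onto its free base
  base_key <- std$inchikey[std$identifier == toy_truth$salt_of[!is.na(toy_truth$salt_of)]]
  salt_key <- std$inchikey[!is.na(toy_truth$salt_of)]
  expect_equal(salt_key, base_key)
  # single-fragment molecules are unchanged up to canonicalization
  expect_false(grepl(".", std$smiles_std[4], fixed = TRUE))
  # idempotence: standardizing the standardized set changes nothing
  again <- standardize_compounds(
    dplyr::transmute(std, identifier, smiles = smiles_std, available_mg)
  )
  expect_equal(again$smiles_std, std$smiles_std)
  expect_equal(again$inchikey, std$inchikey)
  expect_equal(again$num_heavy, std$num_heavy)
})

test_that("descriptors are chemically sane on known structures", {
  aspirin <- std[std$smiles == "CC(=O)Oc1ccccc1C(=O)O", ]
  expect_equal(aspirin$num_heavy, 13)
  expect_equal(aspirin$mw, 180.157, tolerance = 1e-3)
  expect_equal(aspirin$inchikey, "BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
  expect_equal(aspirin$fr_csp3, 1 / 9, tolerance = 1e-9)
  ethanol <- std[std$smiles == "CCO", ]
  expect_equal(ethanol$num_heavy, 3)
  # ground-truth small-molecule count below the heavy-atom filter
  expect_equal(sum(std$num_heavy < 25), sum(toy_truth$is_small))
})

test_that("unparseable structures are kept with missing key, not dropped", {
  bad <- tibble::tibble(identifier = c("ok", "broken"), smiles = c("CCO", "C1CC"))
  expect_message(out <- standardize_compounds(bad), "could not be parsed")
  expect_equal(nrow(out), 2)
  expect_true(is.na(out$inchikey[2]))
  expect_false(is.na(out$inchikey[1]))
})

test_that("the funnel reproduces the construction ground truth 8 -> 6 -> 4 -> 3", {
  ref_keys <- std$inchikey[std$overlaps_reference]
  fr <- apply_funnel(std, reference_keys = ref_keys)
  expect_equal(fr$stages$n_kept, c(8, 6, 4, 3))
  expect_equal(fr$stages$n_dropped, c(0, 2, 2, 1))
  expect_equal(glance(fr)$n_after_overlap, 3)
  rec <- tidy(fr)
  expect_setequal(rec$identifier[rec$exit_stage == "availability" & !is.na(rec$exit_stage)],
                  toy_truth$identifier[toy_truth$low_availability])
  expect_setequal(rec$identifier[rec$exit_stage == "size" & !is.na(rec$exit_stage)],
                  toy_truth$identifier[toy_truth$is_small])
  # stage counts are monotone non-increasing
  expect_true(all(diff(fr$stages$n_kept) <= 0))
  # empty input: all stage counts zero
  fr0 <- apply_funnel(std[0, ])
  expect_equal(fr0$stages$n_kept, rep(0L, 4))
  # neutral thresholds make size and overlap stages identities
  fr_id <- apply_funnel(std, reference_keys = character(), min_heavy = 0)
  expect_equal(fr_id$stages$n_kept[2], fr_id$stages$n_kept[4])
})

test_that("funnel boundaries are inclusive exactly as specified", {
  rec <- tibble::tibble(
    identifier = c("at_mg", "under_mg", "at_ha", "under_ha", "no_mg"),
    available_mg = c(2, 1.999, 10, 10, NA),
    num_heavy = c(30L, 30L, 25L, 24L, 30L),
    inchikey = sprintf("K%026d", 1:5)
  )
  fr <- apply_funnel(rec, reference_keys = character())
  kept <- fr$records$identifier[fr$records$kept]
  expect_setequal(kept, c("at_mg", "at_ha")) # 2 mg and 25 heavy atoms survive
  expect_equal(fr$n_missing_available, 1)
  expect_equal(fr$records$exit_stage[fr$records$identifier == "no_mg"], "availability")
  # overlap matching is full-string and case-exact
  fr2 <- apply_funnel(rec, reference_keys = tolower(rec$inchikey[1]))
  expect_true(fr2$records$kept[1])
  fr3 <- apply_funnel(rec, reference_keys = rec$inchikey[1])
  expect_false(fr3$records$kept[1])
})

test_that("MaxMin diversity selection is deterministic and prefers distinct structures", {
  pool <- tibble::tibble(
    identifier = c("A", "A_dup", "B"),
    smiles_std = c("CCCCCCCCCCCCOc1ccccc1",
                   "CCCCCCCCCCCCOc1ccccc1",
                   "O=C1CSC(=S)N1")
  )
  sel <- select_diverse(pool, 2, seed = 1)
  expect_true("B" %in% sel$identifier)
  expect_equal(sum(sel$identifier %in% c("A", "A_dup")), 1)

  chains <- tibble::tibble(
    identifier = sprintf("chain%02d", 6:25),
    smiles_std = vapply(6:25, function(k) strrep("C", k), character(1))
  )
  s1 <- select_diverse(chains, 8, seed = 99)
  s2 <- select_diverse(chains, 8, seed = 99)
  expect_identical(s1$identifier, s2$identifier)
  # n_pick >= pool returns everything
  expect_equal(nrow(select_diverse(chains, 50, seed = 1)), 20)
  expect_error(select_diverse(chains, 0, seed = 1), "n_pick")
  expect_error(select_diverse(chains, 2), "seed")
})

test_that("greedy MaxMin dominates random subsets of the same size", {
  set.seed(51)
  pool <- tibble::tibble(
    identifier = sprintf("m%02d", 1:15),
    smiles_std = c(
      vapply(5:14, function(k) strrep("C", k), character(1)),
      "c1ccccc1", "c1ccncc1", "O=C1CSC(=S)N1", "CCOC(=O)C", "CC(=O)Oc1ccccc1C(=O)O"
    )
  )
  fp <- compound_fingerprints(pool$smiles_std)
  dist <- as.matrix(1 - tcrossprod(fp) /
    (outer(rowSums(fp), rowSums(fp), "+") - tcrossprod(fp)))
  sel <- select_diverse(pool, 5, seed = 7)
  min_sel <- attr(sel, "min_pairwise_distance")
  rand_min <- replicate(100, {
    idx <- sample(15, 5)
    d <- dist[idx, idx]
    min(d[upper.tri(d)])
  })
  expect_true(all(min_sel >= rand_min))
})

test_that("PAINS flags match the catalog on canonical exemplars", {
  hits <- flag_pains(c(
    "c1ccccc1",                        # clean
    "O=C1CSC(=S)N1",                   # rhodanine core
    "O=C1N/C(=S)SC1=C/c1ccccc1",       # ene-rhodanine
    "Oc1ccc(cc1)/C=N/Nc1ccccc1",       # hydroxyphenyl hydrazone
    "CCO"
  ))
  expect_equal(hits[[1]], character(0))
  expect_true("rhodanine" %in% hits[[2]])
  expect_true(any(grepl("rhodanine", hits[[3]])))
  expect_true(any(grepl("hydroxyphenyl_hydrazone", hits[[4]])))
  expect_equal(hits[[5]], character(0))
  expect_error(flag_pains(c("CCO", NA)), "valid")
})

test_that("the lysosomotropism rule applies its exact bounds", {
  expect_true(flag_lysosomotropic(3.0, 8.0))
  expect_false(flag_lysosomotropic(1.9, 8.0))
  expect_true(is.na(flag_lysosomotropic(3.0, NA)))
  expect_false(flag_lysosomotropic(2.0, 8.0))  # logP bound is strict
  expect_true(flag_lysosomotropic(2.01, 6.5))  # pKa bounds inclusive
  expect_true(flag_lysosomotropic(2.01, 11))
  expect_false(flag_lysosomotropic(2.01, 11.01))
  expect_equal(
    flag_lysosomotropic(c(3, 1, 3), c(7, 7, NA)),
    c(TRUE, FALSE, NA)
  )
})
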