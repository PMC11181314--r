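# brute-force oracle for the sign-consistency rule
oracle_subprofile_keep <- function(z, consistency) {
  apply(z, 2, function(v) {
    max(sum(v > 0), sum(v < 0)) / length(v) >= consistency
  })
}

test_that("sign-consistency rule follows hand-evaluated cases", {
  z <- rbind(
    c(1, 2),
    c(0.5, 1),
    c(2, -1)
  )
  p <- make_profiles(z)
  sub <- build_subprofile(p, "toy", consistency = 0.85)
  # f001 signs (+,+,+): 3/3 retained; f002 signs (+,+,-): 2/3 dropped
  expect_equal(sub$feature_names, "f001")
  expect_equal(sub$median_z, 1)
  expect_equal(sub$n_defining, 3)
})

test_that("a single defining profile keeps all nonzero features", {
  z <- matrix(c(1.5, -2, 0, 3), 1, 4)
  p <- make_profiles(z)
  sub <- build_subprofile(p, "solo")
  expect_equal(sub$feature_names, c("f001", "f002", "f004"))
  expect_equal(sub$median_z, c(1.5, -2, 3))
})

test_that("the 85% boundary is inclusive and zeros count in the denominator", {
  # 17 positives / 3 negatives of 20: 0.85 exactly, retained
  z <- matrix(c(rep(1, 17), rep(-1, 3)), ncol = 1)
  p <- make_profiles(z)
  sub <- build_subprofile(p, "boundary", consistency = 0.85)
  expect_equal(sub$feature_names, "f001")
  # signs (+,+,0): 2/3 < 0.85 because the zero stays in the denominator
  z2 <- cbind(c(1, 1, 0), c(1, 1, 1))
  expect_equal(
    build_subprofile(make_profiles(z2), "zeros", consistency = 0.85)$feature_names,
    "f002"
  )
  expect_error(
    build_subprofile(make_profiles(cbind(c(1, -1, 0))), "none", consistency = 0.85),
    "no feature"
  )
})

test_that("subprofile construction agrees with the sign-count oracle", {
  set.seed(31)
  for (i in 1:40) {
    n_prof <- sample(1:10, 1)
    n_feat <- sample(2:10, 1)
    consistency <- runif(1, 0.5, 1)
    z <- matrix(sample(c(-2, -1, 0, 1, 2), n_prof * n_feat, replace = TRUE),
                n_prof, n_feat)
    keep <- oracle_subprofile_keep(z, consistency)
    p <- make_profiles(z)
    if (!any(keep)) {
      expect_error(build_subprofile(p, "x", consistency = consistency))
    } else {
      sub <- build_subprofile(p, "x", consistency = consistency)
      expect_equal(sub$feature_names, sprintf("f%03d", which(keep)))
      expect_equal(sub$median_z, unname(apply(z[, keep, drop = FALSE], 2, median)))
    }
  }
})

test_that("raising consistency never adds features", {
  set.seed(33)
  z <- matrix(rnorm(30 * 15), 30, 15)
  p <- make_profiles(z)
  sizes <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(co) {
    tryCatch(length(build_subprofile(p, "m", consistency = co)$feature_names),
             error = function(e) 0L)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cluster biosimilarity scores the subprofile feature subset", {
  set.seed(35)
  z <- matrix(rnorm(5 * 30, sd = 2), 5, 30) + rep(c(4, -4), length.out = 30)[col(matrix(0, 5, 30))]
  p <- make_profiles(z)
  sub <- build_subprofile(p, "c1", consistency = 0.8)
  # a profile equal to the median subprofile (padded arbitrarily outside) -> 100
  probe_z <- matrix(rnorm(30), 1, 30)
  probe_z[1, match(sub$feature_names, sprintf("f%03d", 1:30))] <- sub$median_z
  probe <- make_profiles(probe_z, compound_ids = "probe")
  expect_equal(cluster_biosimilarity(probe, sub)$biosimilarity, 100)
  # negated on the subset -> 0
  neg_z <- probe_z
  neg_z[1, match(sub$feature_names, sprintf("f%03d", 1:30))] <- -sub$median_z
  expect_equal(
    cluster_biosimilarity(make_profiles(neg_z, "neg"), sub)$biosimilarity, 0
  )
  # small perturbation stays highly biosimilar
  set.seed(36)
  pert_z <- probe_z
  idx <- match(sub$feature_names, sprintf("f%03d", 1:30))
  pert_z[1, idx] <- sub$median_z + rnorm(length(idx), sd = 0.1 * sd(sub$median_z))
  expect_gte(
    cluster_biosimilarity(make_profiles(pert_z, "pert"), sub)$biosimilarity, 95
  )
})

test_that("cluster assignment thresholds behave at the extremes", {
  set.seed(37)
  z_def <- matrix(rnorm(6 * 40, mean = rep(c(3, -3), 120)), 6, 40, byrow = TRUE)
  p_def <- make_profiles(z_def)
  sub <- build_subprofile(p_def, "k", consistency = 0.85)
  probe_z <- matrix(rnorm(40), 2, 40)
  probe_z[1, match(sub$feature_names, sprintf("f%03d", 1:40))] <- sub$median_z
  probes <- make_profiles(probe_z, c("exact", "noise"))
  # threshold 100: only the exact correlate
  a100 <- assign_clusters(probes, list(sub), threshold = 100)
  expect_equal(a100$assigned, list("k", character(0)))
  expect_equal(a100$top_cluster, c("k", "no cluster"))
  # threshold 0: every non-degenerate compound is assigned everywhere
  a0 <- assign_clusters(probes, list(sub), threshold = 0)
  expect_true(all(a0$n_assigned == 1))
  expect_equal(cluster_counts(a0)$n_compounds, c(2, 0))
})

test_that("residual clustering excludes subprofile features and merges twins first", {
  set.seed(39)
  base <- rnorm(50, sd = 2)
  z <- rbind(base, base + rnorm(50, sd = 0.05), -base)
  p <- make_profiles(z, c("twin1", "twin2", "anti"))
  hc <- cluster_residual(p, exclude = sprintf("f%03d", 1:10))
  expect_equal(attr(hc, "n_features_used"), 40)
  # the identical pair merges first
  expect_setequal(hc$labels[-hc$merge[1, ]], c("twin1", "twin2"))
  expect_error(cluster_residual(p, exclude = sprintf("f%03d", 1:50)), "No features")
})

test_that("residual feature complement arithmetic matches the published split", {
  feats <- sprintf("feat_%03d", 1:579)
  set.seed(40)
  z <- matrix(rnorm(3 * 579), 3, 579)
  colnames(z) <- feats
  p <- dplyr::bind_cols(tibble::tibble(compound_id = c("a", "b", "c")), tibble::as_tibble(z))
  attr(p, "features") <- feats
  hc <- cluster_residual(p, exclude = feats[1:288])
  expect_equal(attr(hc, "n_features_used"), 291)
})

test_that("residual clustering recovers two planted groups at k = 2", {
  set.seed(41)
  t1 <- rnorm(60, sd = 2)
  t2 <- rnorm(60, sd = 2)
  z <- rbind(
    t(replicate(5, t1 + rnorm(60, sd = 0.5))),
    t(replicate(5, t2 + rnorm(60, sd = 0.5)))
  )
  p <- make_profiles(z, sprintf("g%02d", 1:10))
  hc <- cluster_residual(p, exclude = character(0), features = sprintf("f%03d", 1:60))
  groups <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(groups[1:5])), 1)
  expect_equal(length(unique(groups[6:10])), 1)
  expect_true(groups[1] != groups[6])
})

test_that("subprofiles survive a serialization round trip", {
  set.seed(43)
  p <- make_profiles(matrix(rnorm(4 * 12, mean = 2), 4, 12))
  sub <- build_subprofile(p, "roundtrip", consistency = 0.75)
  path <- tempfile(fileext = ".csv")
  write_subprofile(sub, path)
  back <- read_subprofile(path)
  expect_equal(back$name, sub$name)
  expect_equal(back$feature_names, sub$feature_names)
  expect_equal(back$median_z, sub$median_z, tolerance = 1e-12)
  expect_equal(back$n_defining, sub$n_defining)
})
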