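test_that("Kabsch superposition recovers rigid motions and rejects bad input", {
  set.seed(1)
  P <- matrix(runif(15, -5, 5), 5, 3)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  R <- rot_axis(c(0, 0, 1), pi / 2)
  Q <- sweep(P %*% t(R), 2L, -c(1, 2, 3))
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(P, P[1:4, ]), class = "ph4_shape_error")
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), class = "ph4_shape_error")

  # all points coincident: documented identity fallback
  Z <- matrix(1, 4, 3)
  fit <- kabsch_superpose(Z, Z + 5)
  expect_equal(fit$rotation, diag(3))
  expect_equal(fit$translation, c(5, 5, 5))
})

test_that("mirror images cannot be superposed by a proper rotation", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Q <- P %*% diag(c(1, 1, -1))
  fit <- kabsch_superpose(P, Q)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # brute-force rotation-grid oracle agrees within grid resolution
  oracle <- grid_superpose_rmsd(P, Q, n = 36L)
  expect_lte(fit$rmsd, oracle + 1e-9)
  expect_lt(abs(fit$rmsd - oracle), 0.05)
})

test_that("independent rigid-fit route agrees with the SVD implementation", {
  set.seed(7)
  P <- matrix(rnorm(60), 20, 3)
  R <- rand_rotation()
  Q <- sweep(P %*% t(R), 2L, -runif(3, -4, 4)) +
    matrix(rnorm(60, sd = 0.2), 20, 3)
  fit <- kabsch_superpose(P, Q)
  aligned <- bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P)),
                            fixed.inds = 1:60, mobile.inds = 1:60)
  oracle_rmsd <- sqrt(mean(rowSums((matrix(aligned, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(fit$rmsd, oracle_rmsd, tolerance = 1e-6)
})

test_that("the distance prefilter enumerates exactly the admissible mappings", {
  query <- default_plant_query()
  qf <- query$features
  qxyz <- cbind(qf$x, qf$y, qf$z)

  fs <- synthetic_feature_set(qf$kind, qxyz)
  expect_length(distance_prefilter(query, fs), 1L)

  # duplicated compatible acceptor -> two mappings
  fs2 <- synthetic_feature_set(c(qf$kind, "ACC"), rbind(qxyz, qxyz[1, ] + 0.2))
  expect_length(distance_prefilter(query, fs2), 2L)

  # stretch one pair beyond the radius-sum slack -> no mapping
  bad <- qxyz
  bad[2, ] <- bad[2, ] * 3
  fs3 <- synthetic_feature_set(qf$kind, bad)
  expect_length(distance_prefilter(query, fs3), 0L)

  # missing kind -> no mapping
  fs4 <- synthetic_feature_set(qf$kind[-2], qxyz[-2, , drop = FALSE])
  expect_length(distance_prefilter(query, fs4), 0L)
})

test_that("excluded-volume clash uses a strict boundary rule", {
  vols <- excluded_volumes(rbind(c(0, 0, 0)), radius = 1.5)
  expect_true(check_excluded_volumes(rbind(c(0, 0, 0)), vols, 1.0))
  expect_false(check_excluded_volumes(rbind(c(2.6, 0, 0)), vols, 1.0))
  # exactly at radius + atom_radius: no clash (ties allowed)
  expect_false(check_excluded_volumes(rbind(c(2.5, 0, 0)), vols, 1.0))
  expect_true(check_excluded_volumes(rbind(c(2.4999, 0, 0)), vols, 1.0))
})

test_that("match_conformer finds the optimal mapping and transform", {
  query <- default_plant_query()
  qf <- query$features
  qxyz <- cbind(qf$x, qf$y, qf$z)
  conf <- conf_ethane()  # atoms irrelevant, no volumes in query

  fs <- synthetic_feature_set(qf$kind, qxyz)
  m <- match_conformer(fs, conf, query)
  expect_true(m$hit)
  expect_equal(m$rmsd, 0, tolerance = 1e-12)
  expect_equal(det(m$rotation), 1, tolerance = 1e-9)

  # a common displacement is absorbed by the translation
  fs_t <- synthetic_feature_set(qf$kind, sweep(qxyz, 2L, -c(0.5, 0, 0)))
  m <- match_conformer(fs_t, conf, query)
  expect_lt(m$rmsd, 1e-9)
  expect_true(m$hit)

  # jittered features: equal to the exhaustive no-prefilter oracle
  set.seed(13)
  for (rep in 1:25) {
    inst <- random_match_instance()
    got <- match_conformer(inst$fs, conf, inst$query)
    oracle <- exhaustive_best_rmsd(inst$query, inst$fs)
    expect_equal(got$rmsd, oracle$rmsd, tolerance = 1e-12)
  }

  # no mapping -> absent mapping, no hit
  fs_none <- synthetic_feature_set("ACC", rbind(c(0, 0, 0)))
  m <- match_conformer(fs_none, conf, query)
  expect_null(m$mapping)
  expect_false(m$hit)
  expect_equal(m$rmsd, Inf)
})

test_that("screening is rigid-invariant and handles edge cases", {
  tg <- small_plant_targets(3L, 3L, 3L, 0L)
  pl <- plant_matched_library(plant_spec(tg, jitter = 0, seed = 8L))
  exact <- pl$library[pl$labels$label == "active"]
  lib <- c(exact, lapply(seq_along(exact), function(i) {
    r <- random_rigid_transform(exact[[i]], seed = 100L + i)
    r$molecule_id <- paste0(r$molecule_id, "-moved")
    r
  }))
  rep <- screen_library(lib, pl$query)
  expect_equal(rep$n_hits, length(lib))
  expect_true(all(rep$results$rmsd < 1e-9))

  empty <- screen_library(list(), pl$query)
  expect_equal(empty$n_screened, 0L)
  expect_equal(empty$n_hits, 0L)

  # per-molecule reduction: best conformer rmsd, ties to lowest index
  two <- exact[[1]]
  two$conformer_index <- 1L
  rep2 <- screen_library(list(exact[[1]], two), pl$query)
  expect_equal(rep2$n_screened, 1L)
  expect_equal(rep2$results$conformer_index, 0L)
})

test_that("screen verdicts and RMSDs are invariant under rigid motions", {
  tg <- small_plant_targets(4L, 6L, 2L, 2L)
  pl <- plant_matched_library(plant_spec(tg, seed = 17L))
  rep0 <- screen_library(pl$library, pl$query)
  moved <- lapply(seq_along(pl$library), function(i) {
    random_rigid_transform(pl$library[[i]], seed = 500L + i)
  })
  rep1 <- screen_library(moved, pl$query)
  j <- dplyr::inner_join(rep0$results, rep1$results, by = "molecule_id")
  expect_identical(j$hit.x, j$hit.y)
  finite <- is.finite(j$rmsd.x)
  expect_lt(max(abs(j$rmsd.x[finite] - j$rmsd.y[finite])), 1e-9)
})

test_that("hit counts are monotone in threshold and excluded volumes", {
  tg <- small_plant_targets(6L, 10L, 4L, 3L)
  pl <- plant_matched_library(plant_spec(tg, seed = 23L))
  thresholds <- c(0.1, 0.5, 1.0, 2.0)
  hits <- vapply(thresholds, function(th) {
    screen_library(pl$library, pl$query, rmsd_threshold = th)$n_hits
  }, integer(1))
  expect_true(all(diff(hits) >= 0L))

  # adding an excluded volume can only remove hits
  q2 <- pl$query
  q2$excluded_volumes <- excluded_volumes(rbind(c(2, 2, 0)), radius = 2)
  expect_lte(screen_library(pl$library, q2)$n_hits,
             screen_library(pl$library, pl$query)$n_hits)
})
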