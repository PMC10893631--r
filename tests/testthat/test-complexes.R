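test_that("alpha-carbon alignment recovers rigid motions exactly", {
  cx <- make_toy_complex(n_hbonds = 2L, n_hydrophobes = 1L, seed = 4L)
  R <- rot_axis(c(1, 0.2, -0.5), 1.2)
  moved <- transform_complex(cx, R, c(10, -4, 2))
  moved$complex_id <- "moved"
  aligned <- align_complexes(list(cx, moved), reference = "toy")
  ca0 <- cx$protein[cx$alpha_carbons, ]
  ca1 <- aligned[[2]]$protein[aligned[[2]]$alpha_carbons, ]
  rmsd <- sqrt(mean((ca0$x - ca1$x)^2 + (ca0$y - ca1$y)^2 + (ca0$z - ca1$z)^2))
  expect_lt(rmsd, 1e-6)
  # ligand carries the same transform
  expect_equal(aligned[[2]]$ligand$atoms, cx$ligand$atoms, tolerance = 1e-6)

  # idempotence: re-aligning aligned complexes moves nothing
  again <- align_complexes(aligned, reference = "toy")
  expect_lt(max(abs(again[[2]]$protein$x - aligned[[2]]$protein$x)), 1e-9)
})

test_that("alignment agrees with an independent rigid-fit oracle on many pairs", {
  set.seed(31)
  n <- 100L
  prot <- tibble::tibble(
    residue_id = paste0("A:", 1:n), atom_name = "CA", element = "C",
    x = runif(n, -20, 20), y = runif(n, -20, 20), z = runif(n, -20, 20)
  )
  lig <- conformer_record("L", 0L,
                          tibble::tibble(element = "C", x = 0, y = 0, z = 0,
                                         charge = 0L))
  a <- complex_record("a", prot, lig)
  prot_b <- prot
  noise <- matrix(rnorm(3L * n, sd = 0.5), ncol = 3L)
  R <- rand_rotation()
  xyz <- (cbind(prot$x, prot$y, prot$z) + noise) %*% t(R)
  prot_b$x <- xyz[, 1] + 3; prot_b$y <- xyz[, 2] - 7; prot_b$z <- xyz[, 3] + 1
  b <- complex_record("b", prot_b, lig)
  aligned <- align_complexes(list(a, b), reference = "a")[[2]]

  fixed <- as.vector(t(cbind(prot$x, prot$y, prot$z)))
  mobile <- as.vector(t(cbind(prot_b$x, prot_b$y, prot_b$z)))
  oracle <- matrix(bio3d::fit.xyz(fixed, mobile,
                                  fixed.inds = seq_len(3 * n),
                                  mobile.inds = seq_len(3 * n)),
                   ncol = 3L, byrow = TRUE)
  got <- cbind(aligned$protein$x, aligned$protein$y, aligned$protein$z)
  expect_lt(max(abs(got - oracle)), 1e-6)
})

test_that("degenerate alignments are rejected", {
  lig <- conformer_record("L", 0L,
                          tibble::tibble(element = "C", x = 0, y = 0, z = 0,
                                         charge = 0L))
  two <- tibble::tibble(residue_id = paste0("A:", 1:2), atom_name = "CA",
                        element = "C", x = c(0, 1), y = 0, z = 0)
  a <- complex_record("a", two, lig)
  b <- complex_record("b", two, lig)
  expect_error(align_complexes(list(a, b), "a"), class = "ph4_too_few_pairs")

  line <- tibble::tibble(residue_id = paste0("A:", 1:5), atom_name = "CA",
                         element = "C", x = 1:5, y = 2 * (1:5), z = 3 * (1:5))
  a2 <- complex_record("a", line, lig)
  b2 <- complex_record("b", line, lig)
  expect_error(align_complexes(list(a2, b2), "a"), class = "ph4_degenerate")
})

test_that("hydrogen-bond detection applies both distance and angle cutoffs", {
  mk <- function(da_dist, on_axis_angle) {
    # ligand N-H donor with H on the N->O axis when angle = 180
    h <- c(1.02, 0, 0)
    a_dir <- if (on_axis_angle >= 180) c(1, 0, 0) else {
      phi <- (180 - on_axis_angle) * pi / 180
      # acceptor rotated off the N-H axis around the H position
      c(cos(phi), sin(phi), 0)
    }
    acc <- h + (da_dist - 1.02) * a_dir  # approximate placement
    lig <- conformer_record("L", 0L, tibble::tibble(
      element = c("N", "H"), x = c(0, h[1]), y = c(0, h[2]), z = 0,
      charge = 0L
    ), tibble::tibble(a1 = 1L, a2 = 2L, order = 1L))
    prot <- tibble::tibble(
      residue_id = c("A:1", "A:919"), atom_name = c("CA", "O"),
      element = c("C", "O"),
      x = c(20, acc[1]), y = c(20, acc[2]), z = c(20, acc[3])
    )
    complex_record("hb", prot, lig, alpha_carbons = 1L)
  }
  crit <- interaction_criteria()  # 3.5 A, 120 deg

  cx <- mk(2.9, 180)
  # exact distance control: place acceptor exactly at 2.9 on the axis
  cx$protein$x[2] <- 2.9
  fs <- perceive_features(cx$ligand)
  ints <- detect_interactions(cx, fs, crit)
  expect_equal(ints$kind, "HBOND_LIG_DON")
  expect_equal(ints$distance, 2.9, tolerance = 1e-9)
  expect_equal(ints$angle, 180, tolerance = 1e-6)
  expect_equal(ints$residue_id, "A:919")

  far <- cx; far$protein$x[2] <- 4.0
  expect_equal(nrow(detect_interactions(far, fs, crit)), 0L)

  # 90-degree D-H...A angle at 2.9 A: distance fine, angle fails
  bent <- cx
  bent$protein$x[2] <- 1.02
  bent$protein$y[2] <- sqrt(2.9^2 - 1.02^2)
  d <- sqrt(bent$protein$x[2]^2 + bent$protein$y[2]^2)
  expect_equal(d, 2.9, tolerance = 1e-9)
  expect_equal(nrow(detect_interactions(bent, fs, crit)), 0L)
})

test_that("ligand acceptors need a protein donor with an explicit hydrogen", {
  lig <- conformer_record("L", 0L, tibble::tibble(
    element = c("O", "C", "H", "H"),
    x = c(0, -1.23, -1.7, -1.7), y = c(0, 0, 0.9, -0.9), z = 0, charge = 0L
  ), tibble::tibble(a1 = c(1L, 2L, 2L), a2 = c(2L, 3L, 4L),
                    order = c(2L, 1L, 1L)))
  base_prot <- tibble::tibble(
    residue_id = c("A:1", "A:564"), atom_name = c("CA", "N"),
    element = c("C", "N"), x = c(15, 2.9), y = c(15, 0), z = c(15, 0)
  )
  fs <- perceive_features(lig)
  # no hydrogen on the protein nitrogen: not a donor, no H-bond
  cx <- complex_record("nh", base_prot, lig, alpha_carbons = 1L)
  expect_equal(nrow(detect_interactions(cx, fs)), 0L)
  # add the amide hydrogen pointing at the ligand oxygen
  with_h <- dplyr::bind_rows(base_prot, tibble::tibble(
    residue_id = "A:564", atom_name = "H", element = "H",
    x = 1.9, y = 0, z = 0
  ))
  cx2 <- complex_record("nh2", with_h, lig, alpha_carbons = 1L)
  ints <- detect_interactions(cx2, fs)
  expect_equal(ints$kind, "HBOND_LIG_ACC")
  expect_equal(ints$distance, 2.9, tolerance = 1e-9)
})

test_that("hydrophobic contacts require enough apolar atoms in range", {
  cx <- make_toy_complex(n_hbonds = 0L, n_hydrophobes = 1L, seed = 6L)
  fs <- perceive_features(cx$ligand)
  ints <- detect_interactions(cx, fs)
  expect_equal(ints$kind, "HYDROPHOBIC")
  # removing one shell atom drops below hydrophobic_min_group
  cx2 <- cx
  cb <- which(cx2$protein$atom_name == "CB")[1]
  cx2$protein <- cx2$protein[-cb, ]
  cx2$alpha_carbons <- which(cx2$protein$atom_name == "CA")
  expect_equal(nrow(detect_interactions(cx2, fs)), 0L)
})

test_that("interaction detection is invariant under joint rigid motions", {
  cx <- make_toy_complex(n_hbonds = 2L, n_hydrophobes = 2L, seed = 9L)
  fs <- perceive_features(cx$ligand)
  i0 <- detect_interactions(cx, fs)
  R <- rand_rotation()
  moved <- transform_complex(cx, R, c(5, 5, -3))
  fs1 <- perceive_features(moved$ligand)
  i1 <- detect_interactions(moved, fs1)
  expect_equal(nrow(i0), nrow(i1))
  expect_equal(sort(i0$kind), sort(i1$kind))
  expect_equal(sort(i0$distance), sort(i1$distance), tolerance = 1e-9)
  expect_equal(sort(i0$angle), sort(i1$angle), tolerance = 1e-6)
})

test_that("common-feature clustering respects tolerance and support", {
  mk_pts <- function(cxid, xyz, kind = "HBOND_LIG_ACC") {
    tibble::tibble(complex_id = cxid, kind = kind,
                   x = xyz[1], y = xyz[2], z = xyz[3],
                   residue_id = "A:1", atom_name = "O",
                   distance = 2.9, angle = 170)
  }
  near <- list(mk_pts("a", c(0, 0, 0)), mk_pts("b", c(0.5, 0, 0)))
  pool <- cluster_common_features(near, tolerance = 1.5, min_support = 2L)
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$kind, "ACC")
  expect_equal(c(pool$x, pool$y, pool$z), c(0.25, 0, 0))

  farr <- list(mk_pts("a", c(0, 0, 0)), mk_pts("b", c(3, 0, 0)))
  expect_equal(nrow(cluster_common_features(farr, 1.5, min_support = 2L)), 0L)
  expect_equal(nrow(cluster_common_features(farr, 1.5, min_support = 1L)), 2L)

  # complex order cannot matter
  p1 <- cluster_common_features(c(near, list(mk_pts("c", c(8, 0, 0), "HYDROPHOBIC"))),
                                1.5, min_support = 1L)
  p2 <- cluster_common_features(c(list(mk_pts("c", c(8, 0, 0), "HYDROPHOBIC")),
                                  rev(near)), 1.5, min_support = 1L)
  expect_equal(p1, p2)

  expect_error(cluster_common_features(near, tolerance = 0),
               class = "ph4_schema_error")
})

test_that("excluded-volume placement obeys shell, keepout and count rules", {
  cx <- make_toy_complex(n_hbonds = 1L, n_hydrophobes = 2L, seed = 5L)
  fs <- perceive_features(cx$ligand)
  pool <- cluster_common_features(list(detect_interactions(cx, fs)),
                                  min_support = 1L)
  vols <- place_excluded_volumes(list(cx), pool, shell = 5, keepout = 2,
                                 volume_radius = 1, max_count = 30L)
  expect_true(nrow(vols) >= 1L)
  # never within keepout of a feature center
  for (i in seq_len(nrow(vols))) {
    d <- sqrt((pool$x - vols$x[i])^2 + (pool$y - vols$y[i])^2 +
              (pool$z - vols$z[i])^2)
    expect_true(all(d > 2))
  }
  # shell too small -> nothing eligible
  expect_equal(nrow(place_excluded_volumes(list(cx), pool, shell = 0.1,
                                           keepout = 2, max_count = 30L)), 0L)

  # cap at max_count with a surplus of candidates
  n <- 40L
  th <- 2 * pi * seq_len(n) / n
  prot <- tibble::tibble(
    residue_id = paste0("A:", seq_len(n)), atom_name = "CB", element = "C",
    x = 3 * cos(th), y = 3 * sin(th), z = 0
  )
  lig <- conformer_record("L", 0L, tibble::tibble(element = "C", x = 0, y = 0,
                                                  z = 0, charge = 0L))
  ring <- complex_record("ring", prot, lig, alpha_carbons = 1L)
  empty_pool <- pool[0, ]
  vols30 <- place_excluded_volumes(list(ring), empty_pool, shell = 5,
                                   keepout = 2, max_count = 30L)
  expect_equal(nrow(vols30), 30L)

  # a candidate exactly at a feature center is always discarded
  at_feat <- pool[1, ]
  prot2 <- tibble::tibble(residue_id = "A:1", atom_name = "CB", element = "C",
                          x = at_feat$x, y = at_feat$y, z = at_feat$z)
  one <- complex_record(
    "one", prot2,
    conformer_record("L", 0L, tibble::tibble(element = "C", x = at_feat$x,
                                             y = at_feat$y, z = at_feat$z,
                                             charge = 0L)),
    alpha_carbons = 1L
  )
  expect_equal(nrow(place_excluded_volumes(list(one), pool, shell = 5,
                                           keepout = 2, max_count = 30L)), 0L)
})

test_that("hypothesis enumeration builds one model per named combination", {
  pool <- tibble::tibble(
    id = c("ACC1", "ACC2", "DON1", "HYD1"),
    kind = c("ACC", "ACC", "DON", "HYD"),
    x = c(0, 8.8, 6.9, 11.9), y = c(0, -2.4, 1.0, 2.3),
    z = c(0, 1.2, 0.5, -0.8), radius = 1.0, parent_id = NA_character_,
    support = 2L
  )
  vols <- excluded_volumes(rbind(c(0, 6, 0), c(6, -6, 0)), 1.0)

  spec17 <- stats::setNames(
    lapply(1:17, function(i) list(features = c("ACC1", "DON1",
                                               if (i %% 2) "HYD1" else "ACC2"))),
    sprintf("Ph4-%d", 1:17)
  )
  models <- enumerate_hypotheses(pool, spec17, vols)
  expect_length(models, 17L)
  expect_named(models, sprintf("Ph4-%d", 1:17))
  expect_true(all(vapply(models, function(m) nrow(m$excluded_volumes), 1L) == 2L))

  # toggling k optional features -> 2^k models
  k <- 3L
  opts <- c("ACC2", "DON1", "HYD1")
  subsets <- lapply(0:(2^k - 1), function(b) {
    list(features = c("ACC1", opts[as.logical(bitwAnd(b, 2^(0:(k - 1))))]))
  })
  names(subsets) <- paste0("m", seq_along(subsets))
  expect_length(enumerate_hypotheses(pool, subsets, vols), 2^k)

  expect_length(enumerate_hypotheses(pool, list(), vols), 0L)
  expect_error(
    enumerate_hypotheses(pool, list(x = list(features = "NOPE")), vols),
    class = "ph4_dangling_feature"
  )

  # radius overrides land on the right feature
  m <- enumerate_hypotheses(
    pool, list(w = list(features = c("ACC1", "HYD1"),
                        radii = list(HYD1 = 2.5))), vols
  )$w
  expect_equal(m$features$radius[m$features$id == "HYD1"], 2.5)
})

test_that("toy complexes round-trip through PDB", {
  cx <- make_toy_complex(n_hbonds = 1L, n_hydrophobes = 1L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(cx, path)
  back <- read_complex_pdb(path, ligand_res = "LIG")
  expect_equal(nrow(back$protein), nrow(cx$protein))
  expect_equal(length(back$alpha_carbons), length(cx$alpha_carbons))
  expect_equal(cbind(back$protein$x, back$protein$y, back$protein$z),
               cbind(cx$protein$x, cx$protein$y, cx$protein$z),
               tolerance = 1e-3)
  expect_equal(nrow(back$ligand$atoms), nrow(cx$ligand$atoms))
  expect_equal(cbind(back$ligand$atoms$x, back$ligand$atoms$y),
               cbind(cx$ligand$atoms$x, cx$ligand$atoms$y), tolerance = 1e-3)
})
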