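# Shared fixtures and independent oracles, built in code.

rot_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force oracle for rigid superposition: dense grid over Euler angles,
# translation handled in closed form by centering. Independent of the SVD
# route used by the implementation.
grid_superpose_rmsd <- function(P, Q, n = 40L) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  angles <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  half <- seq(0, pi, length.out = ceiling(n / 2))
  best <- Inf
  for (a in angles) for (b in half) for (g in angles) {
    R <- rot_axis(c(0, 0, 1), a) %*% rot_axis(c(0, 1, 0), b) %*%
      rot_axis(c(0, 0, 1), g)
    r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
    if (r < best) best <- r
  }
  best
}

# Exhaustive no-prefilter matching oracle: every injective kind-compatible
# assignment over the query's required features, each superposed in closed
# form; returns all mappings with their RMSDs.
exhaustive_mappings <- function(query, fs) {
  qf <- query$features[query$features$id %in% query$required, ]
  mf <- fs$features
  m <- nrow(qf)
  cand <- lapply(qf$kind, function(k) which(mf$kind == k))
  out <- list()
  recurse <- function(i, chosen) {
    if (i > m) {
      out[[length(out) + 1L]] <<- stats::setNames(chosen, qf$id)
      return(invisible())
    }
    for (c_i in cand[[i]]) {
      if (c_i %in% chosen) next
      recurse(i + 1L, c(chosen, c_i))
    }
  }
  recurse(1L, integer())
  out
}

exhaustive_best_rmsd <- function(query, fs) {
  qf <- query$features[query$features$id %in% query$required, ]
  qxyz <- cbind(qf$x, qf$y, qf$z)
  mf <- fs$features
  mxyz <- cbind(mf$x, mf$y, mf$z)
  maps <- exhaustive_mappings(query, fs)
  if (!length(maps)) return(list(rmsd = Inf, mappings = maps, rmsds = numeric()))
  rmsds <- vapply(maps, function(mp) {
    kabsch_superpose(mxyz[mp, , drop = FALSE], qxyz)$rmsd
  }, numeric(1))
  list(rmsd = min(rmsds), mappings = maps, rmsds = rmsds)
}

# A bare feature_set (no underlying molecule), for matcher-level tests.
synthetic_feature_set <- function(kinds, coords, molecule_id = "syn",
                                  radius = 1.0) {
  tbl <- tibble::tibble(
    id = paste0(kinds, seq_along(kinds)),
    kind = kinds,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    radius = radius, parent_id = NA_character_,
    atoms = as.list(seq_along(kinds))
  )
  structure(list(molecule_id = molecule_id, conformer_index = 0L,
                 features = tbl),
            class = "feature_set")
}

# Random matcher test instance: a query of <= 5 main features (at most two
# per kind) and a molecule carrying jittered copies plus a few extras.
random_match_instance <- function(max_extra = 3L) {
  kinds <- sample(rep(c("ACC", "DON", "HYD"), 2L), sample(3:5, 1L))
  qxyz <- matrix(runif(3L * length(kinds), -6, 6), ncol = 3L)
  query <- pharmacophore("q", dplyr::bind_rows(purrr::map2(
    seq_along(kinds), kinds,
    function(i, k) ph4_feature(paste0("Q", i), k, qxyz[i, ], radius = 1.0)
  )))
  n_extra <- sample(0:max_extra, 1L)
  mkinds <- c(kinds, sample(c("ACC", "DON", "HYD"), n_extra, replace = TRUE))
  mxyz <- rbind(qxyz + matrix(rnorm(length(kinds) * 3L, sd = 0.3), ncol = 3L),
                matrix(runif(n_extra * 3L, -8, 8), ncol = 3L))
  R <- rand_rotation()
  mxyz <- sweep(mxyz %*% t(R), 2L, runif(3L, -5, 5), `+`)
  fs <- synthetic_feature_set(mkinds, mxyz)
  list(query = query, fs = fs)
}

# Tiny molecule fixtures -------------------------------------------------

conf_methanol <- function() {
  conformer_record("methanol", 0L, tibble::tibble(
    element = c("C", "O", "H", "H", "H", "H"),
    x = c(0, 1.43, 1.78, -0.36, -0.36, -0.36),
    y = c(0, 0, 0.9, 1.03, -0.51, -0.51),
    z = c(0, 0, 0, 0, 0.89, -0.89),
    charge = 0L
  ), tibble::tibble(a1 = c(1L, 2L, 1L, 1L, 1L), a2 = c(2L, 3L, 4L, 5L, 6L),
                    order = 1L))
}

conf_benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  conformer_record("benzene", 0L, tibble::tibble(
    element = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
    charge = 0L
  ), tibble::tibble(a1 = 1:6, a2 = c(2:6, 1L),
                    order = c(2L, 1L, 2L, 1L, 2L, 1L)))
}

conf_ethane <- function() {
  conformer_record("ethane", 0L, tibble::tibble(
    element = c("C", "C"), x = c(0, 1.54), y = 0, z = 0, charge = 0L
  ), tibble::tibble(a1 = 1L, a2 = 2L, order = 1L))
}

conf_propane <- function() {
  conformer_record("propane", 0L, tibble::tibble(
    element = "C",
    x = c(-1.26, 0, 1.26), y = c(0.87, 0, 0.87), z = 0, charge = 0L
  ), tibble::tibble(a1 = c(1L, 2L), a2 = c(2L, 3L), order = 1L))
}

# One-target planting table for quick end-to-end tests.
small_plant_targets <- function(actives = 8L, decoys = 40L, tp = 5L, fp = 7L) {
  tibble::tibble(target = "KIN1", actives = actives, decoys = decoys,
                 tp = tp, fp = fp)
}
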