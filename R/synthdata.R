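# Synthetic-data generators: planted-match screening libraries with a
# prescribed confusion structure, toy protein-ligand complexes with known
# interactions, and rigid/jitter augmentations. All generators are pure
# functions of their seeds.

# Internal: uniform random rotation from a normalised Gaussian quaternion.
random_rotation_matrix <- function() {
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

random_unit_vector <- function() {
  v <- rnorm(3L)
  v / sqrt(sum(v^2))
}

#' Apply a random proper rigid motion to a conformer
#'
#' Rotation uniform over proper rotations (normalised Gaussian
#' quaternion), translation uniform in the cube `[-box, box]^3`. All
#' pairwise interatomic distances are preserved. Deterministic for a
#' given `seed`.
#'
#' @param conf A `conformer_record`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param box Half-width of the translation cube (angstroms).
#' @return The transformed `conformer_record`.
#' @export
random_rigid_transform <- function(conf, seed = NULL, box = 15) {
  gen <- function() {
    transform_conformer(conf, random_rotation_matrix(), runif(3L, -box, box))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

# ---- fragment builders ------------------------------------------------------
# Minimal chemically valid fragments whose perceived feature lands at a
# prescribed anchor: a formaldehyde oxygen for ACC, an ammonium nitrogen
# (positively charged, so donor-only) for DON, a propane chain centroid
# for HYD. Each fragment gets a random orientation from the current RNG.

frag_acceptor <- function(anchor) {
  R <- random_rotation_matrix()
  local <- rbind(
    O = c(0, 0, 0),
    C = c(1.22, 0, 0),
    H1 = c(1.77, 0.94, 0),
    H2 = c(1.77, -0.94, 0)
  )
  xyz <- sweep(local %*% t(R), 2L, anchor, `+`)
  list(
    atoms = tibble(element = c("O", "C", "H", "H"),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   charge = 0L),
    bonds = tibble(a1 = c(1L, 2L, 2L), a2 = c(2L, 3L, 4L),
                   order = c(2L, 1L, 1L))
  )
}

frag_donor <- function(anchor) {
  R <- random_rotation_matrix()
  d <- 1.02 / sqrt(3)
  local <- rbind(
    N = c(0, 0, 0),
    H1 = d * c(1, 1, 1), H2 = d * c(1, -1, -1),
    H3 = d * c(-1, 1, -1), H4 = d * c(-1, -1, 1)
  )
  xyz <- sweep(local %*% t(R), 2L, anchor, `+`)
  list(
    atoms = tibble(element = c("N", "H", "H", "H", "H"),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   charge = c(1L, 0L, 0L, 0L, 0L)),
    bonds = tibble(a1 = rep(1L, 4L), a2 = 2L:5L, order = 1L)
  )
}

frag_hydrophobe <- function(anchor) {
  R <- random_rotation_matrix()
  s <- sin(55.5 * pi / 180) * 1.54
  cth <- cos(55.5 * pi / 180) * 1.54
  local <- rbind(C1 = c(-s, cth, 0), C2 = c(0, 0, 0), C3 = c(s, cth, 0))
  local <- sweep(local, 2L, colMeans(local))  # centroid at origin
  xyz <- sweep(local %*% t(R), 2L, anchor, `+`)
  list(
    atoms = tibble(element = c("C", "C", "C"),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   charge = 0L),
    bonds = tibble(a1 = c(1L, 2L), a2 = c(2L, 3L), order = 1L)
  )
}

fragment_for_kind <- function(kind, anchor) {
  switch(kind,
         ACC = frag_acceptor(anchor),
         DON = frag_donor(anchor),
         HYD = frag_hydrophobe(anchor),
         ph4_abort("ph4_schema_error", paste("no fragment builder for kind", kind)))
}

assemble_fragments <- function(id, frags) {
  atoms <- bind_rows(map(frags, "atoms"))
  atoms$x <- unname(atoms$x); atoms$y <- unname(atoms$y)
  atoms$z <- unname(atoms$z)
  offs <- cumsum(c(0L, head(map_int(frags, ~ nrow(.x$atoms)), -1L)))
  bonds <- bind_rows(map2(frags, offs, function(fr, o) {
    if (is.null(fr$bonds) || !nrow(fr$bonds)) return(NULL)
    mutate(fr$bonds, a1 = .data$a1 + o, a2 = .data$a2 + o)
  }))
  if (!nrow(bonds)) bonds <- NULL
  conformer_record(id, 0L, atoms, bonds)
}

#' Default query pharmacophore for planted libraries
#'
#' Three main features (one acceptor, one donor, one hydrophobe) with
#' unit tolerance radii, pairwise distances of 5.2-5.5 angstroms and no
#' excluded volumes; the geometric scale is typical of a kinase
#' hinge/gate/back-pocket arrangement and every inter-feature distance
#' exceeds the prefilter slack, which makes planted non-matches analytic.
#'
#' @return A `pharmacophore` named `"plant-query"`.
#' @export
default_plant_query <- function() {
  pharmacophore(
    "plant-query",
    bind_rows(
      ph4_feature("Q-ACC", "ACC", c(0, 0, 0), radius = 1.0),
      ph4_feature("Q-DON", "DON", c(5.2, 0, 0), radius = 1.0),
      ph4_feature("Q-HYD", "HYD", c(2.4, 4.6, 1.0), radius = 1.0)
    )
  )
}

#' Randomly split planted totals across targets
#'
#' Multinomial split of total planted true/false positives across the
#' targets, proportional to each target's capacity and capped by it
#' (excess is moved deterministically to the target with most slack).
#'
#' @param composition Tibble with `target`, `actives`, `decoys`.
#' @param tp_total,fp_total Planted totals (must fit the capacities).
#' @param seed Integer seed.
#' @return `composition` with added integer columns `tp` and `fp`.
#' @export
split_planted_totals <- function(composition, tp_total, fp_total, seed = 1L) {
  stopifnot(tp_total <= sum(composition$actives),
            fp_total <= sum(composition$decoys))
  capped_split <- function(total, caps) {
    x <- as.integer(stats::rmultinom(1L, total, caps / sum(caps)))
    while (any(x > caps)) {
      i <- which.max(x - caps)
      j <- which.max(caps - x)
      move <- min(x[i] - caps[i], caps[j] - x[j])
      x[i] <- x[i] - move
      x[j] <- x[j] + move
    }
    x
  }
  withr::with_seed(as.integer(seed), {
    composition$tp <- capped_split(tp_total, composition$actives)
    composition$fp <- capped_split(fp_total, composition$decoys)
  })
  composition
}

#' Specification of a planted screening library
#'
#' Defines, per target, the number of actives and decoys and how many of
#' each are planted as geometric matches of the query (`tp` actives and
#' `fp` decoys). Planted matchers carry every required feature kind at
#' the query positions plus a bounded random jitter under a random rigid
#' motion; all remaining compounds are constructed to fail the distance
#' prefilter, so screening at the stated threshold reproduces the planted
#' confusion matrix exactly (an analytic, not probabilistic, guarantee).
#'
#' @param targets Tibble with columns `target`, `actives`, `decoys`,
#'   `tp`, `fp` (see [split_planted_totals()]).
#' @param query Query `pharmacophore` (main features only, no excluded
#'   volumes).
#' @param jitter Maximum per-feature displacement (angstroms) of planted
#'   matchers.
#' @param seed Integer seed; the library is a pure function of it.
#' @param nonmatch_mode How non-matchers are broken: `"missing_kind"`
#'   (one required feature kind absent, rotating over kinds) or
#'   `"scaled"` (all features present but inter-feature distances doubled
#'   about their centroid).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(targets, query = default_plant_query(), jitter = 0.3,
                       seed = 1L, nonmatch_mode = c("missing_kind", "scaled")) {
  targets <- as_tibble(targets)
  need <- c("target", "actives", "decoys", "tp", "fp")
  if (!all(need %in% names(targets))) {
    ph4_abort("ph4_schema_error",
              "targets needs columns target, actives, decoys, tp, fp")
  }
  if (any(targets$tp > targets$actives) || any(targets$fp > targets$decoys)) {
    ph4_abort("ph4_schema_error", "planted tp/fp exceed per-target capacities")
  }
  structure(
    list(
      targets = targets[, need], query = query,
      jitter = as.numeric(jitter), seed = as.integer(seed),
      nonmatch_mode = match.arg(nonmatch_mode)
    ),
    class = "plant_spec"
  )
}

#' Generate a planted screening library
#'
#' Builds the library described by a [plant_spec()]: for each target,
#' `tp` actives and `fp` decoys are planted matchers (fragments placing
#' every required feature kind at the query feature positions plus jitter,
#' under a random rigid motion), and the rest are analytic non-matchers.
#' Screening the output with `screen_library(..., rmsd_threshold)`
#' reproduces the planted confusion counts exactly. Deterministic given
#' the spec seed; the SDF and labels CSV written for equal specs are
#' byte-identical.
#'
#' The guarantee requires `jitter <= rmsd_threshold / 2` and a jitter
#' small enough for the prefilter slack (`2 * jitter` at most the
#' smallest pairwise radius sum); violations are refused with an
#' explanation rather than silently producing a library that may miss.
#'
#' @param spec A `plant_spec`.
#' @param rmsd_threshold Screening threshold the guarantee is stated for.
#' @param sdf,labels_csv Optional output paths for the SDF library and
#'   the labels CSV (`compound_id`, `target`, `label`).
#' @return An object of class `planted_library`: list with `library`
#'   (list of `conformer_record`s), `labels` (tibble), `expected`
#'   (per-target planted confusion counts) and `query`.
#' @export
plant_matched_library <- function(spec, rmsd_threshold = 1.0,
                                  sdf = NULL, labels_csv = NULL) {
  stopifnot(inherits(spec, "plant_spec"))
  query <- spec$query
  if (nrow(query$excluded_volumes)) {
    ph4_abort("ph4_query_volumes", paste(
      "planted-match guarantees assume a clash-free query;",
      "remove the excluded volumes or screen a custom library"
    ))
  }
  qf <- query$features[query$features$id %in% query$required, ]
  if (any(!qf$kind %in% ph4_main_kinds)) {
    ph4_abort("ph4_schema_error",
              "plant queries must require main feature kinds only")
  }
  min_slack <- min(outer(qf$radius, qf$radius, `+`)[upper.tri(diag(nrow(qf)))])
  if (spec$jitter > rmsd_threshold / 2 || 2 * spec$jitter > min_slack) {
    ph4_abort("ph4_jitter_too_large", sprintf(paste(
      "jitter %.3f cannot guarantee planted hits: it must be at most",
      "rmsd_threshold/2 = %.3f and at most half the smallest radius sum = %.3f"),
      spec$jitter, rmsd_threshold / 2, min_slack / 2))
  }
  if (spec$nonmatch_mode == "scaled") {
    dq <- pairwise_dist(feature_coords(qf))
    if (min(dq[upper.tri(dq)]) <= max(outer(qf$radius, qf$radius, `+`))) {
      ph4_abort("ph4_schema_error", paste(
        "scaled non-matchers need query inter-feature distances larger",
        "than every radius sum"
      ))
    }
  }
  qxyz <- feature_coords(qf)
  centroid <- colMeans(qxyz)
  kinds <- qf$kind

  build_matcher <- function(id) {
    frags <- map(seq_len(nrow(qf)), function(i) {
      jit <- random_unit_vector() * runif(1L, 0, spec$jitter)
      fragment_for_kind(kinds[i], qxyz[i, ] + jit)
    })
    random_rigid_transform(assemble_fragments(id, frags))
  }
  build_nonmatcher <- function(id, k) {
    if (spec$nonmatch_mode == "missing_kind") {
      drop_kind <- unique(kinds)[(k %% length(unique(kinds))) + 1L]
      keep <- which(kinds != drop_kind)
      frags <- map(keep, function(i) {
        fragment_for_kind(kinds[i], runif(3L, -8, 8))
      })
    } else {
      frags <- map(seq_len(nrow(qf)), function(i) {
        fragment_for_kind(kinds[i], centroid + 2 * (qxyz[i, ] - centroid))
      })
    }
    random_rigid_transform(assemble_fragments(id, frags))
  }

  lib <- list()
  lab <- list()
  withr::with_seed(spec$seed, {
    for (t in seq_len(nrow(spec$targets))) {
      row <- spec$targets[t, ]
      for (i in seq_len(row$actives)) {
        id <- sprintf("%s-A%04d", row$target, i)
        lib[[length(lib) + 1L]] <-
          if (i <= row$tp) build_matcher(id) else build_nonmatcher(id, i)
        lab[[length(lab) + 1L]] <-
          tibble(compound_id = id, target = row$target, label = "active")
      }
      for (i in seq_len(row$decoys)) {
        id <- sprintf("%s-D%04d", row$target, i)
        lib[[length(lib) + 1L]] <-
          if (i <= row$fp) build_matcher(id) else build_nonmatcher(id, i)
        lab[[length(lab) + 1L]] <-
          tibble(compound_id = id, target = row$target, label = "decoy")
      }
    }
  })
  labels <- bind_rows(lab)
  expected <- spec$targets |>
    mutate(tn = .data$decoys - .data$fp, fn = .data$actives - .data$tp) |>
    select("target", "tp", "fp", "tn", "fn")
  if (!is.null(sdf)) write_sdf(lib, sdf)
  if (!is.null(labels_csv)) readr::write_csv(labels, labels_csv)
  structure(
    list(library = lib, labels = labels, expected = expected, query = query,
         rmsd_threshold = rmsd_threshold),
    class = "planted_library"
  )
}

#' @export
print.planted_library <- function(x, ...) {
  cat(sprintf("<planted_library: %d molecules, %d planted matchers, query '%s'>\n",
              length(x$library), sum(x$expected$tp + x$expected$fp),
              x$query$name))
  print(x$expected)
  invisible(x)
}

#' Generate a toy protein-ligand complex with known interactions
#'
#' Builds a minimal complex whose ligand-protein interactions under the
#' default [interaction_criteria()] are exactly `n_hbonds` hydrogen bonds
#' (ligand hydroxyl donors against bare protein carbonyl-like oxygens, at
#' the prescribed donor-acceptor distance and D-H...A angle) and
#' `n_hydrophobes` hydrophobic contacts (propane centroids surrounded by
#' three apolar protein atoms). Interaction sites sit on a 9-angstrom
#' circle so they cannot interfere; five non-collinear alpha carbons on a
#' distant plane support alignment.
#'
#' @param n_hbonds,n_hydrophobes Numbers of planted interactions (>= 0).
#' @param hbond_distance Donor-acceptor heavy-atom distance (angstroms).
#' @param hbond_angle Planted D-H...A angle (degrees, in (90, 180]).
#' @param hydrophobic_dist Distance of the apolar shell atoms from the
#'   hydrophobic centroid; must be within the detection cutoff.
#' @param complex_id Identifier.
#' @param seed Integer seed (fragment orientations).
#' @return A `complex_record`.
#' @export
make_toy_complex <- function(n_hbonds = 1L, n_hydrophobes = 1L,
                             hbond_distance = 2.9, hbond_angle = 160,
                             hydrophobic_dist = 4.0,
                             complex_id = "toy", seed = 1L) {
  stopifnot(n_hbonds >= 0L, n_hydrophobes >= 0L)
  if (hbond_angle <= 90 || hbond_angle > 180) {
    ph4_abort("ph4_infeasible_geometry", "hbond_angle must be in (90, 180]")
  }
  if (hydrophobic_dist <= 0 || hydrophobic_dist > 4.5) {
    ph4_abort("ph4_infeasible_geometry",
              "hydrophobic_dist must be within the 4.5-angstrom detection cutoff")
  }
  n_sites <- n_hbonds + n_hydrophobes
  lig_frag <- list()
  prot <- list(tibble(
    residue_id = paste0("A:", 1:5), atom_name = "CA", element = "C",
    x = c(0, 8, 0, 8, 4), y = c(0, 0, 8, 8, 3), z = c(15, 15, 15, 16, 17)
  ))
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(n_sites)) {
      th <- 2 * pi * (j - 1) / max(n_sites, 1L)
      center <- 9 * c(cos(th), sin(th), 0)
      u <- c(cos(th), sin(th), 0)
      v <- c(-sin(th), cos(th), 0)
      if (j <= n_hbonds) {
        o_pos <- center
        h_pos <- o_pos + 0.96 * u
        ang_at <- function(phi) {
          a <- o_pos + hbond_distance * (cos(phi) * u + sin(phi) * v)
          dha_angle(o_pos, h_pos, a)
        }
        phi <- if (hbond_angle >= 180) 0 else {
          stats::uniroot(function(p) ang_at(p) - hbond_angle,
                         c(0, pi / 2), tol = 1e-10)$root
        }
        a_pos <- o_pos + hbond_distance * (cos(phi) * u + sin(phi) * v)
        lig_frag[[length(lig_frag) + 1L]] <- list(
          atoms = tibble(element = c("O", "H"),
                         x = c(o_pos[1], h_pos[1]), y = c(o_pos[2], h_pos[2]),
                         z = c(o_pos[3], h_pos[3]), charge = 0L),
          bonds = tibble(a1 = 1L, a2 = 2L, order = 1L)
        )
        prot[[length(prot) + 1L]] <- tibble(
          residue_id = paste0("A:", 100 + j), atom_name = "O", element = "O",
          x = a_pos[1], y = a_pos[2], z = a_pos[3]
        )
      } else {
        lig_frag[[length(lig_frag) + 1L]] <- frag_hydrophobe(center)
        shell <- map(c(0, 2 * pi / 3, 4 * pi / 3), function(a) {
          w <- cos(a) * u + sin(a) * v
          center + 0.9 * hydrophobic_dist * w
        })
        prot[[length(prot) + 1L]] <- tibble(
          residue_id = paste0("A:", 200 + j),
          atom_name = c("CB", "CG", "CD"), element = "C",
          x = map_dbl(shell, 1L), y = map_dbl(shell, 2L),
          z = map_dbl(shell, 3L)
        )
      }
    }
  })
  if (!length(lig_frag)) {
    lig_frag <- list(list(
      atoms = tibble(element = "C", x = 0, y = 0, z = 0, charge = 0L),
      bonds = NULL
    ))
  }
  ligand <- assemble_fragments(paste0(complex_id, "-lig"), lig_frag)
  complex_record(complex_id, bind_rows(prot), ligand)
}
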