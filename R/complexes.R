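#' Construct a protein-ligand complex record
#'
#' @param complex_id Identifier.
#' @param protein Tibble with columns `residue_id` (e.g. `"A:919"`),
#'   `atom_name` (PDB atom name, e.g. `"CA"`), `element`, `x`, `y`, `z`
#'   (angstroms).
#' @param ligand A `conformer_record` (the bound ligand in its bioactive
#'   pose, same frame as the protein).
#' @param alpha_carbons Integer indices into `protein` marking the alpha
#'   carbons used for alignment; defaults to rows with
#'   `atom_name == "CA"`. Must be non-empty.
#' @return An object of class `complex_record`.
#' @export
complex_record <- function(complex_id, protein, ligand, alpha_carbons = NULL) {
  protein <- as_tibble(protein)
  need <- c("residue_id", "atom_name", "element", "x", "y", "z")
  if (!all(need %in% names(protein)) || !nrow(protein)) {
    ph4_abort("ph4_schema_error",
              "protein needs columns residue_id, atom_name, element, x, y, z")
  }
  if (is.null(alpha_carbons)) alpha_carbons <- which(protein$atom_name == "CA")
  alpha_carbons <- as.integer(alpha_carbons)
  if (!length(alpha_carbons) ||
      any(alpha_carbons < 1L | alpha_carbons > nrow(protein))) {
    ph4_abort("ph4_schema_error", "alpha_carbons must be valid, non-empty indices")
  }
  stopifnot(inherits(ligand, "conformer_record"))
  structure(
    list(
      complex_id = as.character(complex_id),
      protein = protein[, need],
      ligand = ligand,
      alpha_carbons = alpha_carbons
    ),
    class = "complex_record"
  )
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf("<complex '%s': %d protein atoms (%d alpha-C), ligand '%s' (%d atoms)>\n",
              x$complex_id, nrow(x$protein), length(x$alpha_carbons),
              x$ligand$molecule_id, nrow(x$ligand$atoms)))
  invisible(x)
}

protein_coords <- function(cx) cbind(cx$protein$x, cx$protein$y, cx$protein$z)

#' Apply a rigid transform to a whole complex
#'
#' Protein and ligand move together.
#'
#' @param cx A `complex_record`.
#' @param rotation 3 x 3 proper rotation.
#' @param translation Length-3 vector.
#' @return The transformed `complex_record`.
#' @export
transform_complex <- function(cx, rotation, translation = c(0, 0, 0)) {
  m <- protein_coords(cx) %*% t(rotation)
  cx$protein$x <- m[, 1] + translation[[1]]
  cx$protein$y <- m[, 2] + translation[[2]]
  cx$protein$z <- m[, 3] + translation[[3]]
  cx$ligand <- transform_conformer(cx$ligand, rotation, translation)
  cx
}

#' Superpose complexes on their alpha carbons
#'
#' Rigidly aligns every non-reference complex onto the reference using the
#' least-squares (Kabsch) superposition of paired alpha-carbon
#' coordinates; the ligand and all protein atoms carry the same transform,
#' so the co-crystallised ligands end up aligned in one common frame.
#'
#' @param complexes List of `complex_record`s.
#' @param reference `complex_id` of the reference complex (left unmoved).
#' @param correspondence Residue pairing: `NULL` to pair alpha carbons
#'   whose `residue_id`s are shared with the reference, or a named list
#'   (one entry per non-reference complex id) of data frames with columns
#'   `ref` and `cx` giving paired residue ids. At least 3 pairs per
#'   complex are required, and the paired alpha carbons must span a plane
#'   (collinear sets are rejected).
#' @return The list of aligned `complex_record`s, in input order.
#' @export
align_complexes <- function(complexes, reference, correspondence = NULL) {
  ids <- map_chr(complexes, "complex_id")
  if (!reference %in% ids) {
    ph4_abort("ph4_schema_error", paste("reference complex not found:", reference))
  }
  ref <- complexes[[match(reference, ids)]]
  ref_ca <- ref$protein[ref$alpha_carbons, ]
  ref_xyz <- cbind(ref_ca$x, ref_ca$y, ref_ca$z)
  out <- complexes
  for (i in seq_along(complexes)) {
    cx <- complexes[[i]]
    if (cx$complex_id == reference) next
    ca <- cx$protein[cx$alpha_carbons, ]
    pairing <- if (!is.null(correspondence)) {
      as_tibble(correspondence[[cx$complex_id]])
    } else {
      shared <- intersect(ref_ca$residue_id, ca$residue_id)
      tibble(ref = sort(shared), cx = sort(shared))
    }
    if (is.null(pairing) || nrow(pairing) < 3L) {
      ph4_abort("ph4_too_few_pairs",
                sprintf("complex '%s': need >= 3 paired alpha carbons", cx$complex_id))
    }
    P <- cbind(ca$x, ca$y, ca$z)[match(pairing$cx, ca$residue_id), , drop = FALSE]
    Q <- ref_xyz[match(pairing$ref, ref_ca$residue_id), , drop = FALSE]
    if (anyNA(P) || anyNA(Q)) {
      ph4_abort("ph4_schema_error",
                sprintf("complex '%s': correspondence names unknown residues", cx$complex_id))
    }
    sv <- svd(sweep(P, 2L, colMeans(P)))
    if (sv$d[2L] < 1e-8) {
      ph4_abort("ph4_degenerate",
                sprintf("complex '%s': paired alpha carbons are collinear", cx$complex_id))
    }
    fit <- kabsch_superpose(P, Q)
    out[[i]] <- transform_complex(cx, fit$rotation, fit$translation)
  }
  out
}

#' Interaction detection criteria
#'
#' Geometric cutoffs for ligand-protein interaction detection. Defaults
#' are field-conventional: hydrogen bonds at donor-to-acceptor heavy-atom
#' distance of at most 3.5 angstroms with a D-H...A angle of at least 120
#' degrees; hydrophobic contacts where a ligand hydrophobic centroid lies
#' within 4.5 angstroms of at least 3 apolar (C/S) protein atoms.
#'
#' @param hbond_max_da,hbond_min_angle,hydrophobic_max_dist,hydrophobic_min_group
#'   See above; all positive, angle at most 180.
#' @return An object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_max_da = 3.5, hbond_min_angle = 120,
                                 hydrophobic_max_dist = 4.5,
                                 hydrophobic_min_group = 3L) {
  stopifnot(hbond_max_da > 0, hbond_min_angle > 0, hbond_min_angle <= 180,
            hydrophobic_max_dist > 0, hydrophobic_min_group > 0)
  structure(
    list(
      hbond_max_da = hbond_max_da, hbond_min_angle = hbond_min_angle,
      hydrophobic_max_dist = hydrophobic_max_dist,
      hydrophobic_min_group = as.integer(hydrophobic_min_group)
    ),
    class = "interaction_criteria"
  )
}

# Internal: D-H...A angle in degrees (angle at the hydrogen).
dha_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect ligand-protein interactions
#'
#' Reports, for a ligand's perceived feature set inside its complex:
#' \itemize{
#'   \item `HBOND_LIG_DON`: a ligand donor and a protein N/O acceptor with
#'     heavy-atom distance at most `hbond_max_da` and D-H...A angle (best
#'     over the donor's hydrogens) at least `hbond_min_angle`;
#'   \item `HBOND_LIG_ACC`: a ligand acceptor and a protein N/O donor
#'     bearing an explicit hydrogen (an H within 1.3 angstroms of the
#'     N/O), same distance and angle rules with the protein as donor;
#'   \item `HYDROPHOBIC`: a ligand hydrophobic centroid within
#'     `hydrophobic_max_dist` of at least `hydrophobic_min_group` apolar
#'     (C/S) protein atoms.
#' }
#' Verdicts are invariant under a rigid transform applied jointly to
#' protein and ligand.
#'
#' @param cx A `complex_record`.
#' @param fs The `feature_set` perceived from `cx$ligand`.
#' @param criteria An `interaction_criteria`.
#' @return Tibble with columns `complex_id`, `kind`, `x`, `y`, `z` (the
#'   ligand-side interaction point), `residue_id`, `atom_name` (the
#'   protein partner), `distance`, `angle` (`NA` for hydrophobic
#'   contacts).
#' @export
detect_interactions <- function(cx, fs, criteria = interaction_criteria()) {
  p <- cx$protein
  pxyz <- protein_coords(cx)
  lxyz <- atom_coords(cx$ligand)
  lat <- cx$ligand$atoms
  adj <- adjacency(nrow(lat), cx$ligand$bonds)
  is_polar <- p$element %in% c("N", "O")
  is_ph <- p$element == "H"
  # protein N/O with an attached hydrogen (distance-based, no CONECT info)
  prot_donor_h <- vector("list", nrow(p))
  if (any(is_ph) && any(is_polar)) {
    for (i in which(is_polar)) {
      d2 <- rowSums(sweep(pxyz[is_ph, , drop = FALSE], 2L, pxyz[i, ])^2)
      prot_donor_h[[i]] <- which(is_ph)[d2 <= 1.3^2]
    }
  }
  rows <- list()
  f <- fs$features
  for (i in seq_len(nrow(f))) {
    kind <- f$kind[i]
    if (kind == "DON") {
      d_idx <- f$atoms[[i]][1L]
      hs <- adj[[d_idx]][lat$element[adj[[d_idx]]] == "H"]
      if (!length(hs)) next
      for (pa in which(is_polar)) {
        dist <- sqrt(sum((lxyz[d_idx, ] - pxyz[pa, ])^2))
        if (dist > criteria$hbond_max_da) next
        ang <- max(map_dbl(hs, ~ dha_angle(lxyz[d_idx, ], lxyz[.x, ], pxyz[pa, ])))
        if (ang < criteria$hbond_min_angle) next
        rows[[length(rows) + 1L]] <- tibble(
          complex_id = cx$complex_id, kind = "HBOND_LIG_DON",
          x = lxyz[d_idx, 1], y = lxyz[d_idx, 2], z = lxyz[d_idx, 3],
          residue_id = p$residue_id[pa], atom_name = p$atom_name[pa],
          distance = dist, angle = ang
        )
      }
    } else if (kind == "ACC") {
      a_idx <- f$atoms[[i]][1L]
      for (pa in which(is_polar)) {
        hs <- prot_donor_h[[pa]]
        if (is.null(hs) || !length(hs)) next
        dist <- sqrt(sum((lxyz[a_idx, ] - pxyz[pa, ])^2))
        if (dist > criteria$hbond_max_da) next
        ang <- max(map_dbl(hs, ~ dha_angle(pxyz[pa, ], pxyz[.x, ], lxyz[a_idx, ])))
        if (ang < criteria$hbond_min_angle) next
        rows[[length(rows) + 1L]] <- tibble(
          complex_id = cx$complex_id, kind = "HBOND_LIG_ACC",
          x = lxyz[a_idx, 1], y = lxyz[a_idx, 2], z = lxyz[a_idx, 3],
          residue_id = p$residue_id[pa], atom_name = p$atom_name[pa],
          distance = dist, angle = ang
        )
      }
    } else if (kind == "HYD") {
      cen <- c(f$x[i], f$y[i], f$z[i])
      apolar <- which(p$element %in% c("C", "S"))
      if (!length(apolar)) next
      d <- sqrt(rowSums(sweep(pxyz[apolar, , drop = FALSE], 2L, cen)^2))
      close <- d <= criteria$hydrophobic_max_dist
      if (sum(close) < criteria$hydrophobic_min_group) next
      nearest <- apolar[which.min(d)]
      rows[[length(rows) + 1L]] <- tibble(
        complex_id = cx$complex_id, kind = "HYDROPHOBIC",
        x = cen[1], y = cen[2], z = cen[3],
        residue_id = p$residue_id[nearest], atom_name = p$atom_name[nearest],
        distance = min(d), angle = NA_real_
      )
    }
  }
  if (length(rows)) bind_rows(rows) else {
    tibble(complex_id = character(), kind = character(), x = numeric(),
           y = numeric(), z = numeric(), residue_id = character(),
           atom_name = character(), distance = numeric(), angle = numeric())
  }
}

#' Cluster interaction points into common pharmacophoric features
#'
#' Single-linkage clustering of like-kind ligand-side interaction points
#' from aligned complexes (link distance at most `tolerance`); clusters
#' supported by at least `min_support` distinct complexes become features
#' at the cluster centroid, with kind mapping `HBOND_LIG_ACC -> ACC`,
#' `HBOND_LIG_DON -> DON`, `HYDROPHOBIC -> HYD`. The output is
#' canonically ordered (kind, then centroid coordinates) and independent
#' of the input complex order.
#'
#' @param per_complex List of interaction tibbles from
#'   [detect_interactions()] (one per complex), or one stacked tibble.
#' @param tolerance Single-linkage distance cutoff (angstroms, > 0).
#' @param min_support Minimum number of distinct supporting complexes;
#'   defaults to the number of complexes present (features common to
#'   all).
#' @param radius Tolerance radius assigned to the pooled features.
#' @return A feature tibble (same columns as [ph4_feature()] plus
#'   `support`, the number of supporting complexes).
#' @export
cluster_common_features <- function(per_complex, tolerance = 1.5,
                                    min_support = NULL, radius = 1.0) {
  if (tolerance <= 0) ph4_abort("ph4_schema_error", "tolerance must be > 0")
  pts <- if (is.data.frame(per_complex)) as_tibble(per_complex) else bind_rows(per_complex)
  if (is.null(min_support)) min_support <- length(unique(pts$complex_id))
  kind_map <- c(HBOND_LIG_ACC = "ACC", HBOND_LIG_DON = "DON", HYDROPHOBIC = "HYD")
  out <- list()
  for (ik in names(kind_map)) {
    sub <- pts[pts$kind == ik, ]
    if (!nrow(sub)) next
    cl <- if (nrow(sub) == 1L) 1L else {
      hc <- hclust(stats::dist(cbind(sub$x, sub$y, sub$z)), method = "single")
      cutree(hc, h = tolerance)
    }
    for (k in unique(cl)) {
      members <- sub[cl == k, ]
      support <- length(unique(members$complex_id))
      if (support < min_support) next
      cen <- c(mean(members$x), mean(members$y), mean(members$z))
      out[[length(out) + 1L]] <- tibble(
        kind = kind_map[[ik]], x = cen[1], y = cen[2], z = cen[3],
        radius = radius, support = support
      )
    }
  }
  if (!length(out)) {
    return(tibble(id = character(), kind = character(), x = numeric(),
                  y = numeric(), z = numeric(), radius = numeric(),
                  parent_id = character(), support = integer()))
  }
  tbl <- bind_rows(out)
  tbl <- tbl[order(match(tbl$kind, ph4_main_kinds), tbl$x, tbl$y, tbl$z), ]
  tbl$id <- paste0(tbl$kind, stats::ave(seq_len(nrow(tbl)), tbl$kind, FUN = seq_along))
  tbl$parent_id <- NA_character_
  tbl[, c(feature_cols, "support")]
}

#' Place excluded volumes on binding-site protein atoms
#'
#' Candidate centers are protein heavy atoms lying within `shell` of any
#' ligand atom of any (aligned) complex; candidates within `keepout` of a
#' pooled feature center are discarded. Up to `max_count` volumes are then
#' kept by a greedy maximin rule: starting from the first candidate in
#' canonical order (residue id, atom name, complex id), repeatedly add the
#' candidate farthest from the chosen set (ties again broken canonically),
#' so the volumes spread over the site deterministically.
#'
#' @param complexes List of aligned `complex_record`s.
#' @param feature_pool Feature tibble (e.g. from
#'   [cluster_common_features()]); may have zero rows.
#' @param shell Ligand-distance shell for candidates (angstroms).
#' @param keepout Minimum allowed distance from any feature center.
#' @param volume_radius Radius given to each placed volume.
#' @param max_count Maximum number of volumes.
#' @return Excluded-volume tibble (`x`, `y`, `z`, `radius`).
#' @export
place_excluded_volumes <- function(complexes, feature_pool, shell = 5.0,
                                   keepout = 2.0, volume_radius = 1.0,
                                   max_count = 30L) {
  lig <- do.call(rbind, map(complexes, ~ atom_coords(.x$ligand)))
  cand <- bind_rows(map(complexes, function(cx) {
    heavy <- cx$protein$element != "H"
    sub <- cx$protein[heavy, ]
    xyz <- cbind(sub$x, sub$y, sub$z)
    keep <- map_lgl(seq_len(nrow(sub)), function(i) {
      min(rowSums(sweep(lig, 2L, xyz[i, ])^2)) <= shell^2
    })
    mutate(sub[keep, ], complex_id = cx$complex_id)
  }))
  if (!nrow(cand)) return(empty_volumes())
  if (nrow(feature_pool)) {
    fxyz <- cbind(feature_pool$x, feature_pool$y, feature_pool$z)
    ok <- map_lgl(seq_len(nrow(cand)), function(i) {
      min(rowSums(sweep(fxyz, 2L, c(cand$x[i], cand$y[i], cand$z[i]))^2)) > keepout^2
    })
    cand <- cand[ok, ]
  }
  if (!nrow(cand)) return(empty_volumes())
  cand <- cand[order(cand$residue_id, cand$atom_name, cand$complex_id), ]
  cxyz <- cbind(cand$x, cand$y, cand$z)
  n <- nrow(cand)
  chosen <- 1L
  min_d2 <- rowSums(sweep(cxyz, 2L, cxyz[1L, ])^2)
  while (length(chosen) < min(max_count, n)) {
    nxt <- which.max(replace(min_d2, chosen, -Inf))
    chosen <- c(chosen, nxt)
    min_d2 <- pmin(min_d2, rowSums(sweep(cxyz, 2L, cxyz[nxt, ])^2))
  }
  excluded_volumes(cxyz[chosen, , drop = FALSE], volume_radius)
}

#' Build candidate pharmacophores from a feature pool
#'
#' One pharmacophore per named hypothesis: each hypothesis selects a
#' subset of pooled feature ids and may override per-feature radii; every
#' model shares the supplied excluded volumes.
#'
#' @param feature_pool Feature tibble (with `id` column).
#' @param spec Named list of hypotheses, each a list with `features`
#'   (character ids) and optionally `radii` (named numeric overrides) and
#'   `required` (ids; defaults to all selected features).
#' @param volumes Excluded-volume tibble shared by all models (or `NULL`).
#' @return Named list of `pharmacophore`s, in `spec` order.
#' @export
enumerate_hypotheses <- function(feature_pool, spec, volumes = NULL) {
  out <- imap(spec, function(hyp, nm) {
    ids <- as.character(hyp$features)
    missing <- setdiff(ids, feature_pool$id)
    if (length(missing)) {
      ph4_abort("ph4_dangling_feature", paste(
        "hypothesis", nm, "references unknown feature(s):",
        paste(missing, collapse = ", ")
      ))
    }
    f <- feature_pool[match(ids, feature_pool$id), feature_cols]
    for (rid in names(hyp$radii %||% list())) {
      f$radius[f$id == rid] <- as.numeric(hyp$radii[[rid]])
    }
    pharmacophore(nm, f, volumes = volumes,
                  required = hyp$required %||% NULL)
  })
  out
}

#' Read a hypothesis specification from JSON
#'
#' Format: `{"<name>": {"features": [...], "radii": {"id": r, ...}?,
#' "required": [...]?}, ...}`.
#'
#' @param path JSON file path.
#' @return Named list usable as `spec` in [enumerate_hypotheses()].
#' @export
read_hypothesis_spec <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) ph4_abort("ph4_malformed_json", conditionMessage(e)))
  doc
}
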