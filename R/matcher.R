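#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' root-mean-square deviation between `R p_i + t` and `q_i` over paired
#' points, via SVD of the cross-covariance of the centred point sets.
#' Reflections are disallowed: when the optimal orthogonal transform would
#' be improper, the smallest singular direction is flipped, giving the
#' best proper rotation. For rank-deficient input where the rotation is
#' not unique (all points coincident), the identity rotation with the
#' centroid translation is returned.
#'
#' @param P,Q Numeric n x 3 matrices of paired points (n >= 3), P is
#'   moved onto Q.
#' @param allow_degenerate Accept coincident point sets (see above)
#'   instead of erroring.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd` (angstroms) at the optimum.
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' fit <- kabsch_superpose(P, P)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(P, Q, allow_degenerate = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L) {
    ph4_abort("ph4_shape_error", "P and Q must be n x 3 matrices of equal size")
  }
  if (nrow(P) < 3L) ph4_abort("ph4_shape_error", "need at least 3 point pairs")
  if (!all(is.finite(P)) || !all(is.finite(Q))) {
    ph4_abort("ph4_shape_error", "points must be finite")
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  if (sum(H^2) < 1e-24) {
    if (!allow_degenerate) ph4_abort("ph4_degenerate", "point set has no spatial extent")
    R <- diag(3)
  } else {
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  t_vec <- cq - as.vector(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

# Internal: compatible molecule-feature candidates per query feature
# (same kind; projections only map to projections of the same kind).
kind_candidates <- function(query_kinds, mol_kinds) {
  lapply(query_kinds, function(k) which(mol_kinds == k))
}

#' Enumerate distance-compatible feature mappings
#'
#' The screening prefilter: enumerates every injective, kind-compatible
#' assignment of molecule features to the query's required features whose
#' pairwise distances are compatible with the query's, i.e. for every
#' mapped pair of query features i, j
#' `|d_mol(i,j) - d_query(i,j)| <= slack_ij` with
#' `slack_ij = radius_i + radius_j`. The radius-sum slack is admissible
#' for tolerance-sphere matching: a mapping whose aligned per-feature
#' deviations all fit within the feature radii distorts no pair by more
#' than the two radii (triangle inequality).
#'
#' When `rmsd_threshold` is supplied the slack is widened to
#' `max(radius_i + radius_j, sqrt(2 m) * rmsd_threshold)` over the `m`
#' required features, which additionally guarantees that no mapping whose
#' optimal superposition RMSD is at most the threshold is eliminated: a
#' mapping with RMSD `r` has per-feature deviations with
#' `dev_i + dev_j <= sqrt(2 m) * r`, so any eliminated mapping must have
#' `r > rmsd_threshold`.
#'
#' @param query A `pharmacophore`.
#' @param fs A `feature_set`.
#' @param rmsd_threshold Optional hit threshold used to widen the slack
#'   (see above); `NULL` applies the radius-sum rule alone.
#' @return A list of mappings; each mapping is an integer vector of row
#'   indices into `fs$features`, named by the query feature ids, in
#'   lexicographic enumeration order.
#' @export
distance_prefilter <- function(query, fs, rmsd_threshold = NULL) {
  qf <- query$features[query$features$id %in% query$required, ]
  m <- nrow(qf)
  slack <- outer(qf$radius, qf$radius, `+`)
  if (!is.null(rmsd_threshold)) {
    slack <- pmax(slack, sqrt(2 * m) * rmsd_threshold)
  }
  enumerate_mappings(qf, fs$features, slack)
}

# Internal: backtracking enumeration of injective kind-compatible
# assignments under a pairwise distance-distortion slack matrix.
enumerate_mappings <- function(qf, mf, slack) {
  m <- nrow(qf)
  if (m == 0L || nrow(mf) == 0L) return(list())
  cand <- kind_candidates(qf$kind, mf$kind)
  if (any(!lengths(cand))) return(list())
  qd <- pairwise_dist(feature_coords(qf))
  md <- pairwise_dist(cbind(mf$x, mf$y, mf$z))
  out <- list()
  assign_next <- function(i, chosen) {
    if (i > m) {
      out[[length(out) + 1L]] <<- setNames(chosen, qf$id)
      return(invisible())
    }
    for (c_i in cand[[i]]) {
      if (c_i %in% chosen) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (abs(md[c_i, chosen[j]] - qd[i, j]) > slack[i, j]) { ok <- FALSE; break }
      }
      if (ok) assign_next(i + 1L, c(chosen, c_i))
    }
  }
  assign_next(1L, integer())
  out
}

#' Test ligand atoms against excluded volumes
#'
#' A clash occurs iff any atom center lies strictly closer than
#' `volume radius + atom_radius` to any excluded-volume center (an atom
#' exactly at the boundary does not clash; ties are allowed).
#'
#' @param atoms Numeric n x 3 matrix of atom positions (after the match
#'   transform).
#' @param volumes Excluded-volume tibble (`x`, `y`, `z`, `radius`).
#' @param atom_radius Generic heavy-atom radius added to each volume
#'   radius (angstroms).
#' @return Logical: `TRUE` if any atom clashes.
#' @export
check_excluded_volumes <- function(atoms, volumes, atom_radius = 1.0) {
  if (!nrow(volumes) || !nrow(atoms)) return(FALSE)
  atoms <- as.matrix(atoms)
  for (i in seq_len(nrow(volumes))) {
    lim <- volumes$radius[i] + atom_radius
    d2 <- (atoms[, 1] - volumes$x[i])^2 + (atoms[, 2] - volumes$y[i])^2 +
      (atoms[, 3] - volumes$z[i])^2
    if (any(d2 < lim^2 - 1e-12)) return(TRUE)
  }
  FALSE
}

#' Match one conformer against a pharmacophore
#'
#' Runs the full per-conformer screening step: enumerate prefiltered
#' feature mappings, rigidly superpose the mapped molecule feature centers
#' onto the query feature centers with [kabsch_superpose()], keep the
#' minimum-RMSD mapping (ties resolved by lexicographic enumeration
#' order), apply its transform to all conformer atoms, and test excluded
#' volumes. The conformer is a hit iff a mapping exists, its RMSD is at
#' most `rmsd_threshold`, and no excluded volume is violated.
#'
#' The result is exact: the threshold-aware prefilter slack can only
#' eliminate mappings whose RMSD exceeds the threshold, and whenever no
#' surviving mapping beats the threshold the search falls back to the
#' full kind-compatible enumeration, so the reported RMSD is always the
#' global minimum over all injective kind-compatible mappings (equal to
#' an exhaustive permutation search).
#'
#' @param fs The `feature_set` perceived from `conf` (with projected site
#'   points if the query uses them).
#' @param conf The `conformer_record`.
#' @param query A `pharmacophore`.
#' @param rmsd_threshold Hit threshold on the feature-center RMSD
#'   (angstroms).
#' @param atom_radius Atom radius for the excluded-volume test.
#' @return An object of class `match_result`: list with `molecule_id`,
#'   `conformer_index`, `mapping` (named integer vector or `NULL`),
#'   `rotation`, `translation`, `rmsd` (`Inf` when unmapped), `clash`,
#'   `hit`.
#' @export
match_conformer <- function(fs, conf, query, rmsd_threshold = 1.0,
                            atom_radius = 1.0) {
  mappings <- distance_prefilter(query, fs, rmsd_threshold)
  res <- list(
    molecule_id = fs$molecule_id,
    conformer_index = fs$conformer_index,
    mapping = NULL,
    rotation = diag(3), translation = c(0, 0, 0),
    rmsd = Inf, clash = FALSE, hit = FALSE
  )
  class(res) <- "match_result"
  qf <- query$features[query$features$id %in% query$required, ]
  qxyz <- feature_coords(qf)
  mf <- fs$features
  mxyz <- cbind(mf$x, mf$y, mf$z)
  best_of <- function(maps) {
    best <- NULL
    for (mp in maps) {
      fit <- kabsch_superpose(mxyz[mp, , drop = FALSE], qxyz)
      if (is.null(best) || fit$rmsd < best$fit$rmsd - 1e-15) {
        best <- list(mp = mp, fit = fit)
      }
    }
    best
  }
  best <- best_of(mappings)
  if (is.null(best) || best$fit$rmsd > rmsd_threshold) {
    # no sub-threshold survivor: redo without distance pruning so the
    # reported minimum is exact even for non-hits
    full <- enumerate_mappings(qf, mf, matrix(Inf, nrow(qf), nrow(qf)))
    best <- best_of(full)
  }
  if (is.null(best)) return(res)
  moved <- atom_coords(conf) %*% t(best$fit$rotation)
  moved <- sweep(moved, 2L, -best$fit$translation)
  clash <- check_excluded_volumes(moved, query$excluded_volumes, atom_radius)
  res$mapping <- best$mp
  res$rotation <- best$fit$rotation
  res$translation <- best$fit$translation
  res$rmsd <- best$fit$rmsd
  res$clash <- clash
  res$hit <- best$fit$rmsd <= rmsd_threshold && !clash
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match '%s' [%d]: rmsd %s, clash %s, hit %s>\n",
              x$molecule_id, x$conformer_index,
              if (is.finite(x$rmsd)) sprintf("%.3f", x$rmsd) else "-",
              x$clash, x$hit))
  invisible(x)
}

#' Screen a conformer library against a pharmacophore
#'
#' Perceives features (and projected site points) on every conformer,
#' matches each against the query, and reduces per molecule: a molecule
#' is a hit iff at least one of its conformers is a hit; its reported
#' result is the minimum-RMSD conformer (ties to the lowest conformer
#' index). Results are sorted ascending by RMSD (unmapped molecules
#' last, then by molecule id).
#'
#' @param library A list of `conformer_record`s (several records may share
#'   a molecule id, forming its conformer ensemble) or the path of an SDF
#'   file readable by [read_sdf()].
#' @param query A `pharmacophore`.
#' @param rules `perception_rules` applied to every conformer.
#' @param rmsd_threshold,atom_radius Passed to [match_conformer()].
#' @return An object of class `screen_report`: list with `query` (name),
#'   `results` (per-molecule tibble: `molecule_id`, `conformer_index`,
#'   `rmsd`, `clash`, `hit`), `n_screened`, `n_hits`, `n_skipped`.
#' @seealso [tidy.screen_report()], [confusion_from_screen()]
#' @export
screen_library <- function(library, query, rules = perception_rules(),
                           rmsd_threshold = 1.0, atom_radius = 1.0) {
  n_skipped <- 0L
  if (is.character(library)) {
    library <- read_sdf(library)
    n_skipped <- attr(library, "n_skipped") %||% 0L
  }
  needs_proj <- any(query$features$kind %in% ph4_proj_kinds)
  rows <- map(library, function(conf) {
    fs <- perceive_features(conf, rules)
    if (needs_proj) fs <- project_site_points(fs, conf, rules)
    m <- match_conformer(fs, conf, query, rmsd_threshold, atom_radius)
    tibble(
      molecule_id = m$molecule_id, conformer_index = m$conformer_index,
      rmsd = m$rmsd, clash = m$clash, hit = m$hit
    )
  })
  per_conf <- bind_rows(rows)
  results <- if (nrow(per_conf)) {
    per_conf |>
      group_by(.data$molecule_id) |>
      arrange(.data$rmsd, .data$conformer_index, .by_group = TRUE) |>
      summarise(
        conformer_index = .data$conformer_index[1L],
        rmsd = .data$rmsd[1L],
        clash = .data$clash[1L],
        hit = any(.data$hit),
        .groups = "drop"
      ) |>
      arrange(.data$rmsd, .data$molecule_id)
  } else {
    tibble(molecule_id = character(), conformer_index = integer(),
           rmsd = numeric(), clash = logical(), hit = logical())
  }
  structure(
    list(
      query = query$name,
      results = results,
      n_screened = nrow(results),
      n_hits = sum(results$hit),
      n_skipped = n_skipped,
      rmsd_threshold = rmsd_threshold
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report: query '%s', %d molecules screened, %d hits>\n",
              x$query, x$n_screened, x$n_hits))
  print(head(x$results, 10L))
  invisible(x)
}

#' Tidy a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return The per-molecule results tibble, sorted ascending by RMSD.
#' @export
tidy.screen_report <- function(x, ...) x$results

#' One-row summary of a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return Tibble with `query`, `n_screened`, `n_hits`, `n_skipped`,
#'   `best_rmsd`.
#' @export
glance.screen_report <- function(x, ...) {
  tibble(
    query = x$query, n_screened = x$n_screened, n_hits = x$n_hits,
    n_skipped = x$n_skipped,
    best_rmsd = if (nrow(x$results)) min(x$results$rmsd) else NA_real_
  )
}

#' Hit list of a screen report
#'
#' @param report A `screen_report`.
#' @return Tibble of hit molecules sorted ascending by RMSD.
#' @export
hit_list <- function(report) {
  filter(report$results, .data$hit)
}

#' Write a screen report to CSV
#'
#' Columns `molecule_id`, `conformer_index`, `rmsd` (3 decimals), `clash`,
#' `hit`.
#'
#' @param report A `screen_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(report, path) {
  out <- mutate(report$results,
                rmsd = ifelse(is.finite(.data$rmsd),
                              sprintf("%.3f", .data$rmsd), ""))
  readr::write_csv(out, path)
  invisible(path)
}
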