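#' Pharmacophore feature kinds
#'
#' Feature kinds used throughout the package: hydrogen-bond acceptor
#' (`ACC`), hydrogen-bond donor (`DON`), hydrophobic centroid (`HYD`), and
#' their projected site points (`ACC_PROJ`, `DON_PROJ`) which mark the
#' direction of the hydrogen bond (toward the putative protein partner
#' atom) rather than a ligand atom position.
#'
#' @format Character vectors.
#' @name ph4-kinds
NULL

ph4_main_kinds <- c("ACC", "DON", "HYD")
ph4_proj_kinds <- c("ACC_PROJ", "DON_PROJ")
ph4_all_kinds  <- c(ph4_main_kinds, ph4_proj_kinds)

feature_cols <- c("id", "kind", "x", "y", "z", "radius", "parent_id")

#' Create a single pharmacophore feature
#'
#' A feature is a typed tolerance sphere in 3D space (coordinates in
#' angstroms). Projected kinds (`ACC_PROJ`, `DON_PROJ`) must name the main
#' feature they belong to via `parent_id`.
#'
#' @param id Short unique label, e.g. `"F1"`.
#' @param kind One of `"ACC"`, `"DON"`, `"HYD"`, `"ACC_PROJ"`, `"DON_PROJ"`.
#' @param center Numeric length-3 coordinate (angstroms).
#' @param radius Tolerance sphere radius in angstroms (> 0). Defaults to
#'   1.0 for main features and 1.5 for projected site points.
#' @param parent_id Id of the owning main feature (projected kinds only).
#' @return A one-row tibble with columns `id`, `kind`, `x`, `y`, `z`,
#'   `radius`, `parent_id`.
#' @examples
#' ph4_feature("F1", "ACC", c(0, 0, 0))
#' @export
ph4_feature <- function(id, kind, center, radius = NULL, parent_id = NA_character_) {
  kind <- match.arg(kind, ph4_all_kinds)
  if (!is_point3(center)) {
    ph4_abort("ph4_schema_error", "`center` must be a finite numeric length-3 vector")
  }
  if (is.null(radius)) {
    radius <- if (kind %in% ph4_main_kinds) 1.0 else 1.5
  }
  tibble(
    id = as.character(id), kind = kind,
    x = center[[1]], y = center[[2]], z = center[[3]],
    radius = as.numeric(radius), parent_id = as.character(parent_id)
  )
}

#' Create an excluded-volume table
#'
#' Excluded volumes are spheres marking receptor-occupied space; a ligand
#' atom entering one invalidates a match. `centers` is an n x 3 matrix of
#' coordinates and `radius` a scalar or length-n vector of radii.
#'
#' @param centers Numeric matrix (n x 3), angstroms.
#' @param radius Sphere radius/radii in angstroms (> 0).
#' @return Tibble with columns `x`, `y`, `z`, `radius`.
#' @export
excluded_volumes <- function(centers, radius = 1.0) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  tibble(
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = rep_len(as.numeric(radius), nrow(centers))
  )
}

empty_volumes <- function() {
  tibble(x = numeric(), y = numeric(), z = numeric(), radius = numeric())
}

#' Construct a pharmacophore model
#'
#' A pharmacophore is a named, ordered set of typed features (with optional
#' projected site points), a set of excluded volumes, and the subset of
#' feature ids that a molecule must match (`required`; defaults to all
#' features, i.e. no partial matching).
#'
#' @param name Model name.
#' @param features Tibble/data frame of features as produced by
#'   [ph4_feature()] (rows are concatenated in order).
#' @param volumes Excluded-volume tibble from [excluded_volumes()], or
#'   `NULL` for none.
#' @param required Character vector of feature ids that must all be matched;
#'   `NULL` means all features are required.
#' @return An object of class `pharmacophore`.
#' @seealso [read_pharmacophore()], [interfeature_distances()]
#' @examples
#' q <- pharmacophore(
#'   "toy",
#'   dplyr::bind_rows(
#'     ph4_feature("A", "ACC", c(0, 0, 0)),
#'     ph4_feature("D", "DON", c(5, 0, 0)),
#'     ph4_feature("H", "HYD", c(2.5, 4, 0))
#'   )
#' )
#' interfeature_distances(q)
#' @export
pharmacophore <- function(name, features, volumes = NULL, required = NULL) {
  features <- as_tibble(features)
  if (!all(feature_cols %in% names(features))) {
    ph4_abort("ph4_schema_error", paste(
      "feature table must have columns:", paste(feature_cols, collapse = ", ")
    ))
  }
  features <- features[, feature_cols]
  if (is.null(volumes)) volumes <- empty_volumes()
  volumes <- as_tibble(volumes)
  if (is.null(required)) required <- features$id
  model <- structure(
    list(
      name = as.character(name),
      features = features,
      excluded_volumes = volumes,
      required = as.character(required)
    ),
    class = "pharmacophore"
  )
  validate_pharmacophore(model)
}

#' Validate a pharmacophore model
#'
#' Checks all structural invariants: unique feature ids, positive radii,
#' finite coordinates, at least one main feature, projected features
#' carrying a `parent_id` that resolves to a main feature (and main
#' features carrying none), and `required` being a subset of the feature
#' ids. Errors are classed (`ph4_schema_error`, `ph4_dangling_parent`) so
#' failure modes can be told apart.
#'
#' @param model A `pharmacophore`.
#' @return The model, invisibly-checked (returned unchanged).
#' @export
validate_pharmacophore <- function(model) {
  f <- model$features
  v <- model$excluded_volumes
  if (nrow(f) < 1L) ph4_abort("ph4_schema_error", "model has no features")
  if (anyDuplicated(f$id)) ph4_abort("ph4_schema_error", "feature ids must be unique")
  if (!all(f$kind %in% ph4_all_kinds)) {
    ph4_abort("ph4_schema_error", "unknown feature kind")
  }
  if (!all(is.finite(c(f$x, f$y, f$z)))) {
    ph4_abort("ph4_schema_error", "feature coordinates must be finite")
  }
  if (!all(is.finite(f$radius)) || any(f$radius <= 0)) {
    ph4_abort("ph4_schema_error", "feature radii must be > 0")
  }
  is_proj <- f$kind %in% ph4_proj_kinds
  if (!any(!is_proj)) ph4_abort("ph4_schema_error", "model needs at least one main feature")
  if (any(!is_proj & !is.na(f$parent_id))) {
    ph4_abort("ph4_schema_error", "main features must not carry a parent_id")
  }
  if (any(is_proj & is.na(f$parent_id))) {
    ph4_abort("ph4_dangling_parent", "projected features must carry a parent_id")
  }
  main_ids <- f$id[!is_proj]
  bad <- is_proj & !(f$parent_id %in% main_ids)
  if (any(bad)) {
    ph4_abort("ph4_dangling_parent", paste(
      "projected feature(s) reference missing parent:",
      paste(f$id[bad], collapse = ", ")
    ))
  }
  if (nrow(v)) {
    if (!all(is.finite(c(v$x, v$y, v$z, v$radius))) || any(v$radius <= 0)) {
      ph4_abort("ph4_schema_error", "excluded volumes need finite centers and radius > 0")
    }
  }
  if (!all(model$required %in% f$id)) {
    ph4_abort("ph4_schema_error", "`required` must be a subset of feature ids")
  }
  model
}

#' @export
print.pharmacophore <- function(x, ...) {
  n_main <- sum(x$features$kind %in% ph4_main_kinds)
  cat(sprintf(
    "<pharmacophore '%s': %d features (%d main, %d projected), %d excluded volumes, %d required>\n",
    x$name, nrow(x$features), n_main, nrow(x$features) - n_main,
    nrow(x$excluded_volumes), length(x$required)
  ))
  print(x$features, ...)
  invisible(x)
}

#' @export
tidy.pharmacophore <- function(x, ...) x$features

#' @export
glance.pharmacophore <- function(x, ...) {
  tibble(
    name = x$name,
    n_features = nrow(x$features),
    n_main = sum(x$features$kind %in% ph4_main_kinds),
    n_projected = sum(x$features$kind %in% ph4_proj_kinds),
    n_excluded_volumes = nrow(x$excluded_volumes),
    n_required = length(x$required)
  )
}

# Internal: feature centers as an n x 3 matrix with id rownames.
feature_coords <- function(features) {
  m <- cbind(features$x, features$y, features$z)
  rownames(m) <- features$id
  m
}

#' Pairwise inter-feature distances
#'
#' Symmetric matrix of Euclidean distances (angstroms) between all feature
#' centers of a model, in feature order. Distances are invariant under any
#' rigid motion of the model.
#'
#' @param model A `pharmacophore` with at least 2 features.
#' @return A symmetric numeric matrix with zero diagonal; dimnames are the
#'   feature ids.
#' @export
interfeature_distances <- function(model) {
  if (nrow(model$features) < 2L) {
    ph4_abort("ph4_too_few_features", "need at least 2 features for distances")
  }
  pairwise_dist(feature_coords(model$features))
}

#' Apply a rigid transform to a pharmacophore
#'
#' Rotates and translates every feature center and excluded-volume center:
#' `p -> rotation %*% p + translation`. Radii are unchanged.
#'
#' @param model A `pharmacophore`.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Numeric length-3 vector (angstroms).
#' @return The transformed `pharmacophore`.
#' @export
transform_pharmacophore <- function(model, rotation, translation = c(0, 0, 0)) {
  f <- feature_coords(model$features) %*% t(rotation)
  model$features$x <- f[, 1] + translation[[1]]
  model$features$y <- f[, 2] + translation[[2]]
  model$features$z <- f[, 3] + translation[[3]]
  if (nrow(model$excluded_volumes)) {
    v <- cbind(model$excluded_volumes$x, model$excluded_volumes$y,
               model$excluded_volumes$z) %*% t(rotation)
    model$excluded_volumes$x <- v[, 1] + translation[[1]]
    model$excluded_volumes$y <- v[, 2] + translation[[2]]
    model$excluded_volumes$z <- v[, 3] + translation[[3]]
  }
  model
}

# ---- JSON serialization -----------------------------------------------------

#' Read a pharmacophore model from JSON
#'
#' The on-disk format is plain JSON:
#' `{"name", "features": [{"id", "kind", "center": [x,y,z], "radius",
#' "parent_id"?}], "excluded_volumes": [{"center": [x,y,z], "radius"}],
#' "required_feature_ids": [...]}`. A missing `radius` falls back to
#' `main_radius` / `proj_radius`. All model invariants are enforced on
#' load; malformed JSON, schema violations and dangling parent references
#' raise distinct error classes (`ph4_malformed_json`, `ph4_schema_error`,
#' `ph4_dangling_parent`).
#'
#' @param path File path.
#' @param main_radius,proj_radius Default radii (angstroms) for features
#'   without an explicit radius.
#' @return A `pharmacophore`.
#' @export
read_pharmacophore <- function(path, main_radius = 1.0, proj_radius = 1.5) {
  if (!file.exists(path)) ph4_abort("ph4_io_error", paste("no such file:", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) ph4_abort("ph4_malformed_json", conditionMessage(e))
  )
  if (!is.list(doc) || is.null(doc$name) || is.null(doc$features)) {
    ph4_abort("ph4_schema_error", "pharmacophore JSON needs 'name' and 'features'")
  }
  feats <- map(doc$features, function(ft) {
    if (is.null(ft$id) || is.null(ft$kind) || is.null(ft$center) ||
        length(ft$center) != 3L) {
      ph4_abort("ph4_schema_error", "each feature needs id, kind and a 3D center")
    }
    kind <- as.character(ft$kind)
    if (!kind %in% ph4_all_kinds) {
      ph4_abort("ph4_schema_error", paste("unknown feature kind:", kind))
    }
    radius <- ft$radius %||%
      (if (kind %in% ph4_main_kinds) main_radius else proj_radius)
    ph4_feature(
      id = ft$id, kind = kind, center = as.numeric(unlist(ft$center)),
      radius = radius, parent_id = as.character(ft$parent_id %||% NA_character_)
    )
  })
  vols <- map(doc$excluded_volumes %||% list(), function(v) {
    if (is.null(v$center) || length(v$center) != 3L || is.null(v$radius)) {
      ph4_abort("ph4_schema_error", "each excluded volume needs a 3D center and radius")
    }
    excluded_volumes(matrix(as.numeric(unlist(v$center)), 1L), v$radius)
  })
  pharmacophore(
    name = doc$name,
    features = bind_rows(feats),
    volumes = if (length(vols)) bind_rows(vols) else NULL,
    required = as.character(unlist(doc$required_feature_ids %||% list()))
  )
}

# Internal: fixed-precision number formatting used by the JSON writer so
# that saving the same model twice yields byte-identical files.
fmt6 <- function(x) {
  s <- sprintf("%.6f", x)
  sub("^-(0\\.0{6})$", "\\1", s)  # normalise -0.000000
}

#' Write a pharmacophore model to JSON
#'
#' The writer is canonical: fixed key order and fixed 6-decimal float
#' formatting, so two saves of the same model are byte-identical and the
#' file round-trips through [read_pharmacophore()] to an equal model.
#'
#' @param model A valid `pharmacophore`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  validate_pharmacophore(model)
  f <- model$features
  feat_json <- map_chr(seq_len(nrow(f)), function(i) {
    parent <- if (is.na(f$parent_id[i])) "" else {
      sprintf(",\"parent_id\":%s", jsonlite::toJSON(f$parent_id[i], auto_unbox = TRUE))
    }
    sprintf(
      "{\"id\":%s,\"kind\":\"%s\",\"center\":[%s,%s,%s],\"radius\":%s%s}",
      jsonlite::toJSON(f$id[i], auto_unbox = TRUE), f$kind[i],
      fmt6(f$x[i]), fmt6(f$y[i]), fmt6(f$z[i]), fmt6(f$radius[i]), parent
    )
  })
  v <- model$excluded_volumes
  vol_json <- if (nrow(v)) {
    map_chr(seq_len(nrow(v)), function(i) {
      sprintf("{\"center\":[%s,%s,%s],\"radius\":%s}",
              fmt6(v$x[i]), fmt6(v$y[i]), fmt6(v$z[i]), fmt6(v$radius[i]))
    })
  } else character()
  txt <- paste0(
    "{\"name\":", jsonlite::toJSON(model$name, auto_unbox = TRUE),
    ",\"features\":[", paste(feat_json, collapse = ","), "]",
    ",\"excluded_volumes\":[", paste(vol_json, collapse = ","), "]",
    ",\"required_feature_ids\":",
    jsonlite::toJSON(model$required), "}"
  )
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) ph4_abort("ph4_io_error", conditionMessage(e)))
  on.exit(close(con))
  writeBin(charToRaw(paste0(txt, "\n")), con)
  invisible(path)
}

#' An illustrative multi-kinase pharmacophore model
#'
#' Builds a synthetic seven-feature model with the layout typical of a
#' type II kinase-inhibitor pharmacophore: a hinge-region H-bond acceptor,
#' an alpha-C-helix glutamate H-bond donor and a DFG-motif aspartate
#' acceptor (each with its projected site point pointing toward the
#' protein partner), a broad hydrophobic feature for the allosteric back
#' pocket, and thirty excluded volumes on a shell around the feature axis.
#' The geometry is illustrative, not derived from any crystal structure.
#'
#' @param n_volumes Number of excluded volumes (default 30).
#' @return A `pharmacophore` named `"multikinase-typeII-synthetic"`.
#' @export
example_multikinase_model <- function(n_volumes = 30L) {
  feats <- bind_rows(
    ph4_feature("F1", "ACC", c(0.0, 0.0, 0.0), radius = 1.0),   # hinge
    ph4_feature("F2", "DON", c(6.9, 1.0, 0.5), radius = 1.0),   # alpha-C Glu
    ph4_feature("F3", "ACC", c(8.8, -2.4, 1.2), radius = 1.0),  # DFG Asp
    ph4_feature("F4", "HYD", c(11.9, 2.3, -0.8), radius = 2.0), # back pocket
    ph4_feature("F5", "ACC_PROJ", c(-2.8, 0.9, 0.4), radius = 1.5, parent_id = "F1"),
    ph4_feature("F6", "DON_PROJ", c(6.3, 3.9, 0.9), radius = 1.5, parent_id = "F2"),
    ph4_feature("F7", "ACC_PROJ", c(9.6, -5.2, 1.5), radius = 1.5, parent_id = "F3")
  )
  # excluded volumes: two rings of points on a cylinder around the long
  # axis of the feature arrangement, clear of every feature sphere
  axis_pts <- seq(-2, 14, length.out = ceiling(n_volumes / 2))
  ang <- seq(0, 2 * pi, length.out = n_volumes + 1L)[seq_len(n_volumes)]
  centers <- cbind(
    rep(axis_pts, length.out = n_volumes),
    6.5 * cos(ang),
    6.5 * sin(ang)
  )
  pharmacophore(
    "multikinase-typeII-synthetic", feats,
    volumes = excluded_volumes(centers, radius = 1.0)
  )
}
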