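#' Feature perception rules
#'
#' Declarative rules mapping a conformer's bond graph to pharmacophoric
#' features, following conventional pharmacophore typing:
#' \itemize{
#'   \item donors: N or O heavy atoms bearing at least one explicit
#'     hydrogen;
#'   \item acceptors: N or O atoms that are not positively charged, with
#'     amide nitrogens excluded;
#'   \item hydrophobes: carbon rings of at least `hydrophobe_ring_min`
#'     atoms and acyclic all-carbon chains of at least
#'     `hydrophobe_min_atoms` atoms, each contributing one unweighted
#'     centroid feature.
#' }
#' Projected site points are placed `projection_distance` angstroms from
#' the parent heavy atom: donors along the heavy-atom-to-hydrogen unit
#' vector (the direction of the donated hydrogen), acceptors opposite the
#' mean unit vector to their bonded heavy neighbours (the lone-pair
#' direction).
#'
#' @param donor_elements,acceptor_elements Element symbols eligible as
#'   donor/acceptor heavy atoms.
#' @param exclude_amide_nitrogen Drop N atoms bonded to a carbonyl carbon
#'   from the acceptor set.
#' @param hydrophobe_min_atoms Minimum atoms in an acyclic carbon chain.
#' @param hydrophobe_ring_min Minimum atoms in a carbon ring.
#' @param projection_distance Distance (angstroms, > 0) of projected site
#'   points from the parent heavy atom; default 3.0, a typical
#'   donor-to-acceptor hydrogen-bond distance.
#' @param main_radius,proj_radius Tolerance radii (angstroms) assigned to
#'   perceived main/projected features.
#' @return An object of class `perception_rules`.
#' @export
perception_rules <- function(donor_elements = c("N", "O"),
                             acceptor_elements = c("N", "O"),
                             exclude_amide_nitrogen = TRUE,
                             hydrophobe_min_atoms = 3L,
                             hydrophobe_ring_min = 5L,
                             projection_distance = 3.0,
                             main_radius = 1.0,
                             proj_radius = 1.5) {
  if (projection_distance <= 0) {
    ph4_abort("ph4_schema_error", "projection_distance must be > 0")
  }
  if (!length(donor_elements) || !length(acceptor_elements)) {
    ph4_abort("ph4_schema_error", "donor/acceptor element lists must be non-empty")
  }
  structure(
    list(
      donor_elements = donor_elements,
      acceptor_elements = acceptor_elements,
      exclude_amide_nitrogen = isTRUE(exclude_amide_nitrogen),
      hydrophobe_min_atoms = as.integer(hydrophobe_min_atoms),
      hydrophobe_ring_min = as.integer(hydrophobe_ring_min),
      projection_distance = as.numeric(projection_distance),
      main_radius = as.numeric(main_radius),
      proj_radius = as.numeric(proj_radius)
    ),
    class = "perception_rules"
  )
}

# Internal: adjacency list (list of integer neighbour vectors) from bonds.
adjacency <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) sort(unique(v)))
}

# Internal: connected components of the subgraph induced by `keep` (logical).
graph_components <- function(keep, adj) {
  n <- length(keep)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in which(keep)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- adj[[v]]
      nb <- nb[keep[nb] & is.na(comp[nb])]
      stack <- c(stack, nb)
    }
  }
  comp
}

# Internal: 2-core of a vertex subset (iteratively prune degree-1 vertices);
# the surviving vertices are exactly those lying on cycles.
two_core <- function(vertices, adj) {
  inset <- logical(length(adj))
  inset[vertices] <- TRUE
  repeat {
    deg <- map_int(seq_along(adj), function(v) {
      if (!inset[v]) return(99L)
      sum(inset[adj[[v]]])
    })
    drop <- inset & deg <= 1L
    if (!any(drop)) break
    inset[drop] <- FALSE
  }
  which(inset)
}

#' Perceive pharmacophoric features of a conformer
#'
#' Applies [perception_rules()] to the conformer's atoms and bond graph and
#' returns the perceived main features (acceptors, donors, hydrophobic
#' centroids). Output is deterministic: features are ordered by kind
#' (`ACC`, `DON`, `HYD`) and then by lowest owning atom index, and ids are
#' assigned sequentially within kind (`ACC1`, `DON1`, ...). Explicit
#' hydrogens are required for donor perception.
#'
#' @param conf A `conformer_record`.
#' @param rules A `perception_rules` object.
#' @return An object of class `feature_set`: a list with `molecule_id`,
#'   `conformer_index` and a `features` tibble (feature columns plus an
#'   `atoms` list-column of owning atom indices).
#' @seealso [project_site_points()]
#' @export
perceive_features <- function(conf, rules = perception_rules()) {
  stopifnot(inherits(conf, "conformer_record"))
  a <- conf$atoms
  adj <- adjacency(nrow(a), conf$bonds)
  is_h <- a$element == "H"

  has_h <- map_lgl(seq_len(nrow(a)), function(i) any(is_h[adj[[i]]]))
  donors <- which(a$element %in% rules$donor_elements & has_h)

  is_amide_n <- if (rules$exclude_amide_nitrogen) {
    map_lgl(seq_len(nrow(a)), function(i) {
      if (a$element[i] != "N") return(FALSE)
      carbons <- adj[[i]][a$element[adj[[i]]] == "C"]
      any(map_lgl(carbons, function(cc) {
        db <- conf$bonds$order == 2L &
          ((conf$bonds$a1 == cc & a$element[conf$bonds$a2] == "O") |
           (conf$bonds$a2 == cc & a$element[conf$bonds$a1] == "O"))
        any(db)
      }))
    })
  } else rep(FALSE, nrow(a))
  acceptors <- which(a$element %in% rules$acceptor_elements &
                     a$charge <= 0L & !is_amide_n)

  coords <- atom_coords(conf)
  rows <- list()
  for (i in acceptors) {
    rows[[length(rows) + 1L]] <- list(kind = "ACC", center = coords[i, ], atoms = i)
  }
  for (i in donors) {
    rows[[length(rows) + 1L]] <- list(kind = "DON", center = coords[i, ], atoms = i)
  }
  # hydrophobes from the carbon-only subgraph
  is_c <- a$element == "C"
  comp <- graph_components(is_c, adj)
  for (k in seq_len(max(comp, 0L, na.rm = TRUE))) {
    members <- which(!is.na(comp) & comp == k)
    core <- two_core(members, adj)
    core <- core[core %in% members]
    group <- if (length(core)) {
      if (length(core) >= rules$hydrophobe_ring_min) core else integer()
    } else if (length(members) >= rules$hydrophobe_min_atoms) {
      members
    } else integer()
    if (length(group)) {
      rows[[length(rows) + 1L]] <- list(
        kind = "HYD",
        center = colMeans(coords[group, , drop = FALSE]),
        atoms = group
      )
    }
  }

  if (length(rows)) {
    tbl <- tibble(
      kind = map_chr(rows, "kind"),
      x = map_dbl(rows, ~ .x$center[[1]]),
      y = map_dbl(rows, ~ .x$center[[2]]),
      z = map_dbl(rows, ~ .x$center[[3]]),
      atoms = map(rows, ~ as.integer(.x$atoms))
    )
    ord <- order(match(tbl$kind, ph4_main_kinds), map_int(tbl$atoms, min))
    tbl <- tbl[ord, ]
    tbl$id <- paste0(tbl$kind, stats::ave(seq_len(nrow(tbl)), tbl$kind, FUN = seq_along))
    tbl$radius <- rules$main_radius
    tbl$parent_id <- NA_character_
    tbl <- tbl[, c(feature_cols, "atoms")]
  } else {
    tbl <- tibble(
      id = character(), kind = character(), x = numeric(), y = numeric(),
      z = numeric(), radius = numeric(), parent_id = character(),
      atoms = list()
    )
  }
  structure(
    list(
      molecule_id = conf$molecule_id,
      conformer_index = conf$conformer_index,
      features = tbl
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s' [%d]: %d features>\n",
              x$molecule_id, x$conformer_index, nrow(x$features)))
  print(x$features, ...)
  invisible(x)
}

#' @export
tidy.feature_set <- function(x, ...) x$features

#' Add projected site points to a perceived feature set
#'
#' Each donor gains a `DON_PROJ` point at `projection_distance` along the
#' donor-heavy-atom-to-hydrogen unit vector (lowest-index bonded hydrogen
#' when several are present); each acceptor gains an `ACC_PROJ` point at
#' `projection_distance` opposite the mean unit vector to its bonded heavy
#' neighbours (falling back to all bonded atoms when it has none, and
#' skipping the projection when the direction is degenerate). The
#' projected point is always exactly `projection_distance` from its parent
#' feature center.
#'
#' @param fs A `feature_set` perceived from `conf`.
#' @param conf The owning `conformer_record`.
#' @param rules The `perception_rules` used for perception.
#' @return `fs` with projected features appended (ordered `ACC_PROJ` then
#'   `DON_PROJ`, then by owning atom index).
#' @export
project_site_points <- function(fs, conf, rules = perception_rules()) {
  stopifnot(inherits(fs, "feature_set"), inherits(conf, "conformer_record"))
  a <- conf$atoms
  adj <- adjacency(nrow(a), conf$bonds)
  coords <- atom_coords(conf)
  d <- rules$projection_distance
  proj <- list()
  f <- fs$features
  for (i in seq_len(nrow(f))) {
    kind <- f$kind[i]
    if (!kind %in% c("ACC", "DON")) next
    owner <- f$atoms[[i]][1L]
    nb <- adj[[owner]]
    if (kind == "DON") {
      hs <- nb[a$element[nb] == "H"]
      if (!length(hs)) {
        ph4_abort("ph4_invariant", "donor feature without a bonded hydrogen")
      }
      dir <- coords[hs[1L], ] - coords[owner, ]
    } else {
      heavy <- nb[a$element[nb] != "H"]
      ref <- if (length(heavy)) heavy else nb
      if (!length(ref)) next
      units <- t(apply(coords[ref, , drop = FALSE], 1L,
                       function(p) {
                         v <- p - coords[owner, ]
                         v / sqrt(sum(v^2))
                       }))
      dir <- -colMeans(units)
    }
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-6) next
    pt <- coords[owner, ] + d * dir / nrm
    proj[[length(proj) + 1L]] <- tibble(
      id = paste0(f$id[i], "p"),
      kind = if (kind == "ACC") "ACC_PROJ" else "DON_PROJ",
      x = pt[[1]], y = pt[[2]], z = pt[[3]],
      radius = rules$proj_radius,
      parent_id = f$id[i],
      atoms = list(as.integer(owner))
    )
  }
  if (length(proj)) {
    ptbl <- bind_rows(proj)
    ord <- order(match(ptbl$kind, ph4_proj_kinds), map_int(ptbl$atoms, min))
    fs$features <- bind_rows(f, ptbl[ord, ])
  }
  fs
}
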