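#' Construct a conformer record
#'
#' One 3D conformer of a small molecule: an atom table (element, Cartesian
#' coordinates in angstroms, formal charge) and a bond table (atom index
#' pairs and integer bond order). Atoms may form several covalently
#' disconnected fragments (as in salts or mixtures); feature perception
#' operates on the bond graph, so explicit hydrogens are required wherever
#' a donor is expected.
#'
#' @param molecule_id Molecule identifier (SDF title line).
#' @param conformer_index Non-negative integer index within the molecule's
#'   conformer ensemble.
#' @param atoms Tibble/data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (formal charge, default 0).
#' @param bonds Tibble/data frame with columns `a1`, `a2`, `order`
#'   (1-based atom indices), or `NULL` for none.
#' @return An object of class `conformer_record`.
#' @export
conformer_record <- function(molecule_id, conformer_index, atoms, bonds = NULL) {
  atoms <- as_tibble(atoms)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)) || nrow(atoms) < 1L) {
    ph4_abort("ph4_schema_error", "atoms need columns element, x, y, z and >= 1 row")
  }
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    ph4_abort("ph4_schema_error", "atom coordinates must be finite")
  }
  if (is.null(bonds)) bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  bonds <- as_tibble(bonds)
  if (nrow(bonds)) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1L | idx > nrow(atoms))) {
      ph4_abort("ph4_schema_error", "bond atom indices out of range")
    }
  }
  structure(
    list(
      molecule_id = as.character(molecule_id),
      conformer_index = as.integer(conformer_index),
      atoms = atoms[, c("element", "x", "y", "z", "charge")],
      bonds = bonds[, c("a1", "a2", "order")]
    ),
    class = "conformer_record"
  )
}

#' @export
print.conformer_record <- function(x, ...) {
  cat(sprintf("<conformer '%s' [%d]: %d atoms, %d bonds>\n",
              x$molecule_id, x$conformer_index, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# Internal: atom coordinates as an n x 3 matrix.
atom_coords <- function(conf) cbind(conf$atoms$x, conf$atoms$y, conf$atoms$z)

#' Apply a rigid transform to a conformer
#'
#' @param conf A `conformer_record`.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Numeric length-3 vector (angstroms).
#' @return The transformed `conformer_record`.
#' @export
transform_conformer <- function(conf, rotation, translation = c(0, 0, 0)) {
  m <- atom_coords(conf) %*% t(rotation)
  conf$atoms$x <- m[, 1] + translation[[1]]
  conf$atoms$y <- m[, 2] + translation[[2]]
  conf$atoms$z <- m[, 3] + translation[[3]]
  conf
}

# ---- SDF (V2000) I/O --------------------------------------------------------
#
# Minimal MDL SDF V2000 reader/writer. The writer is byte-stable (fixed
# field widths, fixed float formatting) so generated libraries are
# reproducible; the reader preserves formal charges from `M  CHG` lines,
# which the acceptor perception rule depends on.

#' Read a multi-record SDF (V2000) conformer library
#'
#' Records sharing a molecule id are interpreted as one molecule's
#' conformer ensemble; conformer indices are taken from a
#' `conformer_index` data field when present, otherwise assigned in file
#' order per molecule (0-based). Formal charges are read from `M  CHG`
#' property lines.
#'
#' @param path SDF file path.
#' @param id_prop Optional name of an SDF data field to use as the
#'   molecule id instead of the title line.
#' @return A list of `conformer_record`s, in file order.
#' @export
read_sdf <- function(path, id_prop = NULL) {
  if (!file.exists(path)) ph4_abort("ph4_io_error", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ph4_abort("ph4_malformed_sdf", "no '$$$$' record terminator found")
  starts <- c(1L, head(ends, -1L) + 1L)
  seen <- new.env(parent = emptyenv())
  records <- vector("list", length(starts))
  n_bad <- 0L
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:(ends[r] - 1L)]
    rec <- tryCatch(suppressWarnings(parse_sdf_record(block, id_prop)),
                    error = function(e) NULL)
    if (is.null(rec)) {
      n_bad <- n_bad + 1L
      warn(sprintf("skipping unreadable SDF record %d", r))
      next
    }
    if (is.na(rec$conformer_index)) {
      k <- (get0(rec$molecule_id, envir = seen, ifnotfound = -1L)) + 1L
      assign(rec$molecule_id, k, envir = seen)
      rec$conformer_index <- k
    }
    records[[r]] <- rec
  }
  records <- records[!map_lgl(records, is.null)]
  attr(records, "n_skipped") <- n_bad
  records
}

parse_sdf_record <- function(block, id_prop = NULL) {
  if (length(block) < 4L) stop("truncated record")
  title <- trimws(block[1L])
  counts <- block[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L) stop("bad counts line")
  atom_lines <- block[5L:(4L + na)]
  atoms <- tibble(
    element = trimws(substr(atom_lines, 32L, 34L)),
    x = as.numeric(substr(atom_lines, 1L, 10L)),
    y = as.numeric(substr(atom_lines, 11L, 20L)),
    z = as.numeric(substr(atom_lines, 21L, 30L)),
    charge = 0L
  )
  bonds <- if (nb > 0L) {
    bl <- block[(5L + na):(4L + na + nb)]
    tibble(
      a1 = as.integer(substr(bl, 1L, 3L)),
      a2 = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L))
    )
  } else NULL
  rest <- block[-seq_len(4L + na + max(nb, 0L))]
  for (ln in grep("^M  CHG", rest, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1]])
    npair <- flds[1L]
    for (k in seq_len(npair)) {
      atoms$charge[flds[2L * k]] <- flds[2L * k + 1L]
    }
  }
  props <- parse_sdf_props(rest)
  mol_id <- if (!is.null(id_prop)) {
    props[[id_prop]] %||% stop("missing id property")
  } else title
  ci <- suppressWarnings(as.integer(props[["conformer_index"]] %||% NA))
  rec <- conformer_record(mol_id, 0L, atoms, bonds)
  rec$conformer_index <- ci
  rec
}

parse_sdf_props <- function(lines) {
  hits <- grep("^> *<", lines)
  props <- list()
  for (h in hits) {
    key <- sub("^> *<([^>]*)>.*$", "\\1", lines[h])
    if (h + 1L <= length(lines)) props[[key]] <- trimws(lines[h + 1L])
  }
  props
}

#' Write conformer records to a multi-record SDF (V2000)
#'
#' Field widths and float formatting are fixed, so writing the same
#' records twice produces byte-identical files. Formal charges are emitted
#' as `M  CHG` lines; each record carries its conformer index as a
#' `conformer_index` data field.
#'
#' @param records A list of `conformer_record`s (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(records, path) {
  if (inherits(records, "conformer_record")) records <- list(records)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) ph4_abort("ph4_io_error", conditionMessage(e)))
  on.exit(close(con))
  out <- map_chr(records, format_sdf_record)
  writeBin(charToRaw(paste0(paste(out, collapse = ""), "")), con)
  invisible(path)
}

format_sdf_record <- function(rec) {
  a <- rec$atoms
  b <- rec$bonds
  lines <- c(
    rec$molecule_id,
    "  ph4screen",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element)
  )
  if (nrow(b)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order))
  }
  chg <- which(a$charge != 0L)
  for (i in if (length(chg)) seq(1L, length(chg), by = 8L) else integer()) {
    idx <- chg[i:min(i + 7L, length(chg))]
    lines <- c(lines, paste0(
      sprintf("M  CHG%3d", length(idx)),
      paste(sprintf("%4d%4d", idx, a$charge[idx]), collapse = "")
    ))
  }
  lines <- c(
    lines, "M  END",
    "> <conformer_index>", as.character(rec$conformer_index), "",
    "$$$$"
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}
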