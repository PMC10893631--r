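# PDB I/O for protein-ligand complexes, via bio3d. PDB files carry no
# ligand connectivity, so ligand bonds are inferred from covalent radii.

covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

# Internal: guess bonds from interatomic distances (<= 1.3 x radii sum).
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(tibble(a1 = integer(), a2 = integer(), order = integer()))
  r <- unname(covalent_radii[atoms$element])
  r[is.na(r)] <- 0.77
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  d <- pairwise_dist(xyz)
  lim <- 1.3 * outer(r, r, `+`)
  idx <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
  tibble(a1 = as.integer(idx[, 1]), a2 = as.integer(idx[, 2]), order = 1L)
}

#' Read a protein-ligand complex from a PDB file
#'
#' Protein atoms come from `ATOM` records; the ligand is selected from
#' `HETATM` records by residue name. Ligand bonds are inferred from
#' covalent radii (PDB carries no connectivity); formal charges are taken
#' as zero. Alpha carbons are the protein `CA` atoms.
#'
#' @param path PDB file path.
#' @param ligand_res Residue name of the ligand (e.g. `"LIG"`).
#' @param complex_id Identifier; defaults to the file name without
#'   extension.
#' @return A `complex_record`.
#' @export
read_complex_pdb <- function(path, ligand_res, complex_id = NULL) {
  if (!file.exists(path)) ph4_abort("ph4_io_error", paste("no such file:", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  prot <- at[at$type == "ATOM", ]
  lig <- at[at$type == "HETATM" & at$resid == ligand_res, ]
  if (!nrow(prot)) ph4_abort("ph4_schema_error", "no ATOM records in PDB")
  if (!nrow(lig)) {
    ph4_abort("ph4_schema_error", paste("no HETATM records with residue name", ligand_res))
  }
  elem <- function(df) {
    e <- trimws(df$elesy)
    fallback <- substr(trimws(df$elety), 1L, 1L)
    ifelse(is.na(e) | e == "", fallback, e)
  }
  protein <- tibble(
    residue_id = paste0(prot$chain, ":", prot$resno),
    atom_name = trimws(prot$elety),
    element = elem(prot),
    x = prot$x, y = prot$y, z = prot$z
  )
  lat <- tibble(element = elem(lig), x = lig$x, y = lig$y, z = lig$z, charge = 0L)
  ligand <- conformer_record(ligand_res, 0L, lat, infer_bonds(lat))
  complex_record(complex_id %||% sub("\\.[^.]*$", "", basename(path)),
                 protein, ligand)
}

#' Write a complex to a PDB file
#'
#' Protein atoms as `ATOM`, ligand atoms as `HETATM` (residue name
#' `LIG`), via `bio3d::write.pdb`. Ligand bonds and formal charges are
#' not representable in PDB and are dropped.
#'
#' @param cx A `complex_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(cx, path) {
  p <- cx$protein
  l <- cx$ligand$atoms
  resno <- suppressWarnings(as.integer(sub("^.*:", "", p$residue_id)))
  resno[is.na(resno)] <- seq_len(sum(is.na(resno)))
  chain <- sub(":.*$", "", p$residue_id)
  chain[!nzchar(chain)] <- "A"
  n <- nrow(p) + nrow(l)
  xyz <- c(t(cbind(c(p$x, l$x), c(p$y, l$y), c(p$z, l$z))))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = c(rep("ATOM", nrow(p)), rep("HETATM", nrow(l))),
    resno = c(resno, rep(max(resno) + 1L, nrow(l))),
    resid = c(rep("PRT", nrow(p)), rep("LIG", nrow(l))),
    chain = c(chain, rep("L", nrow(l))),
    eleno = seq_len(n),
    elety = c(p$atom_name, l$element),
    elesy = c(p$element, l$element)
  )
  invisible(path)
}
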