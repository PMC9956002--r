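#' Read a multi-model PDB trajectory
#'
#' Parses a trajectory stored as a multi-model PDB (MODEL/ENDMDL records,
#' identical atom ordering in every model) into the labelled-coordinates
#' form used by [detect_contacts()]. Parsing is delegated to
#' \pkg{bio3d}'s PDB reader.
#'
#' Any frame source can stand in for this reader: [detect_contacts()] only
#' needs a list with an `atoms` tibble (columns `resno`, `resid`, `elety`,
#' `chain`) and a `coords` list of n_atoms-by-3 matrices, so DCD/XTC
#' backends can be plugged in by building the same structure.
#'
#' @param path Path to a multi-model PDB file.
#' @return A list of class `tbs_trajectory` with elements `atoms` (tibble:
#'   `atom`, `resno`, `resid`, `elety`, `chain`) and `coords` (list of
#'   numeric matrices, one per frame, rows = atoms, columns = x, y, z).
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- tibble(
    atom = seq_len(nrow(pdb$atom)),
    resno = as.integer(pdb$atom$resno),
    resid = as.character(pdb$atom$resid),
    elety = as.character(pdb$atom$elety),
    chain = as.character(pdb$atom$chain)
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- nrow(atoms)
  if (ncol(xyz) != 3 * n_atoms) {
    abort("malformed trajectory: coordinate count does not match atom count")
  }
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  structure(list(atoms = atoms, coords = coords), class = "tbs_trajectory")
}

#' @export
print.tbs_trajectory <- function(x, ...) {
  cat(sprintf("<tbs_trajectory> %d atoms, %d frames\n",
              nrow(x$atoms), length(x$coords)))
  invisible(x)
}

#' Detect per-frame enzyme-ligand contacts
#'
#' A protein residue is in contact at a frame when the minimum distance
#' between any of its atoms and any atom of any ligand copy is less than or
#' equal to `cutoff` (default 2.7 angstrom, at the boundary the contact IS
#' recorded). Residues are indexed 1-based in the order their residue
#' numbers are first encountered among protein atoms; frames 0-based.
#'
#' Distances are plain Euclidean with no periodic-image correction, so
#' trajectories must be imaged before export; this is documented as a
#' limitation of the multi-model PDB path.
#'
#' @param traj A trajectory from [read_trajectory_pdb()] (or any list with
#'   the same `atoms`/`coords` shape).
#' @param ligand_resname Residue name(s) identifying ligand atoms; all
#'   matching copies count (contact with ANY copy suffices).
#' @param cutoff Contact distance in angstrom (default 2.7).
#' @param heavy_atoms_only If `TRUE`, hydrogen atoms (element inferred from
#'   the atom name) are dropped from both selections before measuring.
#' @param dt_ps Frame spacing in picoseconds stored in the result.
#' @param substrate,replica Identifiers stored in the result.
#' @return A [contact_matrix()] over the protein residues.
#' @export
detect_contacts <- function(traj, ligand_resname, cutoff = 2.7,
                            heavy_atoms_only = FALSE, dt_ps = 2,
                            substrate = ligand_resname[1], replica = "r1") {
  if (length(traj$coords) == 0) abort("trajectory has no frames")
  if (length(ligand_resname) == 0 || !any(traj$atoms$resid %in% ligand_resname)) {
    abort("ligand selection is empty: no atoms match `ligand_resname`")
  }
  n_atoms <- nrow(traj$atoms)
  ok <- vapply(traj$coords, function(xy) is.matrix(xy) && nrow(xy) == n_atoms,
               logical(1))
  if (!all(ok)) abort("malformed trajectory: atom count differs across frames")

  atoms <- traj$atoms
  is_lig <- atoms$resid %in% ligand_resname
  if (heavy_atoms_only) {
    is_h <- grepl("^[0-9]*H", atoms$elety)
    keep <- !is_h
  } else {
    keep <- rep(TRUE, n_atoms)
  }
  lig_idx <- which(is_lig & keep)
  prot_atoms <- atoms[!is_lig & keep, , drop = FALSE]
  if (length(lig_idx) == 0) abort("ligand selection is empty after filtering")
  if (nrow(prot_atoms) == 0) abort("protein selection is empty")

  # 1-based sequential residue indexing in order of first appearance
  res_keys <- paste(prot_atoms$chain, prot_atoms$resno, sep = ":")
  res_levels <- unique(res_keys)
  res_index <- match(res_keys, res_levels)
  n_residues <- length(res_levels)
  prot_idx <- prot_atoms$atom

  cutoff2 <- cutoff^2
  rows <- list()
  for (f in seq_along(traj$coords)) {
    xyz <- traj$coords[[f]]
    p <- xyz[prot_idx, , drop = FALSE]
    l <- xyz[lig_idx, , drop = FALSE]
    # squared distances protein-atoms x ligand-atoms
    d2 <- outer(rowSums(p^2), rowSums(l^2), "+") - 2 * tcrossprod(p, l)
    min_d2 <- apply(d2, 1, min)
    hit <- tapply(min_d2, res_index, min) <= cutoff2 + 1e-9
    res_hit <- as.integer(names(hit))[hit]
    if (length(res_hit) > 0) {
      rows[[length(rows) + 1L]] <- tibble(residue = res_hit, frame = f - 1L)
    }
  }
  entries <- if (length(rows) > 0) bind_rows(rows) else
    tibble(residue = integer(), frame = integer())
  contact_matrix(entries, n_residues = n_residues,
                 n_frames = length(traj$coords), dt_ps = dt_ps,
                 substrate = substrate, replica = replica)
}
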