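# Labeled coordinate frames and the structural metrics read from them:
# inter-ligand carbonyl-carbon distance (ligand internalization depth) and
# Ser117 side-chain O-O separations across the dimer-dimer interface.

#' Construct a structure frame
#'
#' A labeled coordinate frame: one row per atom with its name, residue,
#' chain (tetramer subunits A-D, plus ligand chains) and position in
#' Angstrom.
#'
#' @param atoms Data frame with columns `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id`, `x`, `y`, `z` and optionally `record`
#'   (`"ATOM"`/`"HETATM"`, default `"ATOM"`).
#' @return Object of class `structure_frame` (a data frame).
#' @export
structure_frame <- function(atoms) {
  req <- c("atom_name", "residue_name", "residue_number", "chain_id",
           "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  class(atoms) <- c("structure_frame", "data.frame")
  atoms
}

#' Read a structure frame from PDB or CSV
#'
#' PDB files are parsed with [bio3d::read.pdb()]; CSV files must carry the
#' [structure_frame()] columns.
#'
#' @param path Path to a `.pdb` or `.csv` file.
#' @return A [structure_frame()].
#' @export
read_structure_frame <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    structure_frame(data.frame(
      atom_name = a$elety, residue_name = a$resid,
      residue_number = a$resno, chain_id = a$chain,
      x = a$x, y = a$y, z = a$z, record = a$type,
      stringsAsFactors = FALSE
    ))
  } else {
    structure_frame(utils::read.csv(path, stringsAsFactors = FALSE))
  }
}

#' Write a structure frame to a PDB file
#'
#' @param frame A [structure_frame()].
#' @param path Output path. Coordinates are written at the format's 1e-3
#'   Angstrom precision.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(frame, path) {
  stopifnot(inherits(frame, "structure_frame"))
  xyz <- as.vector(t(as.matrix(frame[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = frame$record,
                   resno = frame$residue_number,
                   resid = frame$residue_name,
                   elety = frame$atom_name,
                   chain = frame$chain_id)
  invisible(path)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

frame_xyz <- function(frame, rows) {
  as.numeric(frame[rows, c("x", "y", "z")])
}

#' Inter-ligand internalization depth
#'
#' Distance between the carbonyl carbons of the two ligand copies bound in
#' the thyroxine channel. Larger distances indicate ligands displaced
#' toward the channel mouths; shorter distances indicate deeper
#' internalization.
#'
#' @param frame A [structure_frame()] containing exactly two ligand copies.
#' @param ligand_res Ligand residue name (HETATM records), e.g. `"LIG"`.
#' @param carbonyl_atom Name of the carbonyl carbon atom within the ligand
#'   (default `"C7"`).
#' @return Distance in Angstrom.
#' @export
interligand_depth <- function(frame, ligand_res = "LIG",
                              carbonyl_atom = "C7") {
  stopifnot(inherits(frame, "structure_frame"))
  sel <- which(frame$residue_name == ligand_res &
               frame$atom_name == carbonyl_atom)
  if (length(sel) != 2L)
    stop(sprintf(
      "expected exactly 2 atoms matching residue '%s' atom '%s', found %d",
      ligand_res, carbonyl_atom, length(sel)), call. = FALSE)
  euclid(frame_xyz(frame, sel[1L]), frame_xyz(frame, sel[2L]))
}

#' Ser117 O-O distances across the dimer-dimer interface
#'
#' Distances between the side-chain oxygens (atom `OG`) of the facing
#' Ser117 residues in subunit pairs (A, C) and (B, D). Shorter distances
#' mark a tighter, kinetically stabilized dimer-dimer interface.
#'
#' @param frame A [structure_frame()] with a Ser117 `OG` atom in each of
#'   chains A-D.
#' @param residue_number Residue number of the interface serine
#'   (default 117).
#' @return Named numeric vector `c(AC = ..., BD = ...)`, Angstrom.
#' @export
ser117_oo_distances <- function(frame, residue_number = 117) {
  stopifnot(inherits(frame, "structure_frame"))
  og <- lapply(c("A", "B", "C", "D"), function(ch)
    which(frame$chain_id == ch &
          frame$residue_number == residue_number &
          frame$atom_name == "OG"))
  missing <- c("A", "B", "C", "D")[lengths(og) == 0L]
  if (length(missing) > 0L)
    stop("missing Ser117 OG atom in chain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- lapply(og, function(i) frame_xyz(frame, i[1L]))
  names(p) <- c("A", "B", "C", "D")
  c(AC = euclid(p$A, p$C), BD = euclid(p$B, p$D))
}
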