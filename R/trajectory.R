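#' Coordinate-ensemble (trajectory) container
#'
#' Holds an ordered set of frames for one or two peptide chains with a
#' constant atom roster. Coordinates are in Angstrom, residues are 1-based,
#' chains are identified by PDB chain ID. Phosphoserine uses the residue
#' name `SEP`.
#'
#' @param atoms Data frame with columns `name` (atom label), `resname`
#'   (3-letter code), `resindex` (1-based integer) and `chain` (letter).
#' @param coords Numeric array of dimension `(n_atoms, 3, n_frames)`.
#' @param frame_interval_ps Time between frames, ps (> 0).
#'
#' @return An object of class `rs_trajectory`.
#' @export
rs_trajectory <- function(atoms, coords, frame_interval_ps = 150) {
  req <- c("name", "resname", "resindex", "chain")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms))) {
    stop("'atoms' needs columns name, resname, resindex, chain",
         call. = FALSE)
  }
  if (length(dim(coords)) != 3L || dim(coords)[1] != nrow(atoms) ||
      dim(coords)[2] != 3L) {
    stop("'coords' must be an (n_atoms, 3, n_frames) array", call. = FALSE)
  }
  if (any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (!is.finite(frame_interval_ps) || frame_interval_ps <= 0) {
    stop("'frame_interval_ps' must be > 0", call. = FALSE)
  }
  atoms$name <- as.character(atoms$name)
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$resindex <- as.integer(atoms$resindex)
  atoms$chain <- as.character(atoms$chain)
  structure(
    list(atoms = atoms, coords = coords,
         frame_interval_ps = frame_interval_ps,
         chain_ids = sort(unique(atoms$chain))),
    class = "rs_trajectory"
  )
}

#' @export
print.rs_trajectory <- function(x, ...) {
  cat(sprintf("<rs_trajectory> %d atoms, %d frames, chains %s, dt %g ps\n",
              nrow(x$atoms), n_frames(x),
              paste(x$chain_ids, collapse = "/"), x$frame_interval_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `rs_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "rs_trajectory"))
  dim(traj$coords)[3]
}

#' Extract one frame as an atom table
#'
#' @param traj An `rs_trajectory`.
#' @param i Frame index (1-based).
#' @return Data frame with columns `name`, `resname`, `resindex`, `chain`,
#'   `x`, `y`, `z` -- the input format of the interaction detectors.
#' @export
frame_atoms <- function(traj, i) {
  stopifnot(inherits(traj, "rs_trajectory"))
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range",
                                         call. = FALSE)
  out <- traj$atoms
  out$x <- traj$coords[, 1, i]
  out$y <- traj$coords[, 2, i]
  out$z <- traj$coords[, 3, i]
  out
}

# Residue names with side-chain geometry known to this package (standard 20
# plus phosphoserine).
KNOWN_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "SEP", "THR", "TRP", "TYR",
  "VAL"
)

#' Write a trajectory as a multi-model PDB file
#'
#' Emits one `MODEL`/`ENDMDL` block per frame with standard `ATOM` records
#' (occupancy 1.00, B-factor 0.00, element from the first letter of the atom
#' name). Phosphoserine is written with residue name `SEP`.
#'
#' @param traj An `rs_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "rs_trajectory"))
  at <- traj$atoms
  nm <- ifelse(nchar(at$name) >= 4L,
               substr(at$name, 1, 4),
               sprintf(" %-3s", at$name))
  elem <- substr(at$name, 1, 1)
  con <- file(path, open = "wt")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), nm, at$resname, at$chain, at$resindex,
      traj$coords[, 1, f], traj$coords[, 2, f], traj$coords[, 3, f],
      1.00, 0.00, elem
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Parses a `MODEL`/`ENDMDL` multi-model PDB via [bio3d::read.pdb()]. Models
#' become frames in model order. `SEP` residues are parsed as phosphoserine,
#' with the phosphate oxygens (`O1P`, `O2P`, `O3P`) available as hydrogen
#' bond/salt-bridge acceptors downstream. Residue names outside the standard
#' set trigger a warning; their side chains simply contribute no interaction
#' sites in the detectors.
#'
#' @param path Path to a PDB file.
#' @param frame_interval_ps Time between models, ps (default 150).
#' @return An `rs_trajectory`.
#' @export
read_multimodel_pdb <- function(path, frame_interval_ps = 150) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      stop("failed to parse multi-model PDB (", conditionMessage(e), ")",
           call. = FALSE)
    }
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natoms <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * natoms) {
    stop("inconsistent atom counts across models", call. = FALSE)
  }
  unknown <- setdiff(unique(toupper(pdb$atom$resid)), KNOWN_RESIDUES)
  if (length(unknown)) {
    warning("unknown residue name(s) skipped for side-chain sites: ",
            paste(unknown, collapse = ", "))
  }
  atoms <- data.frame(
    name = pdb$atom$elety,
    resname = toupper(pdb$atom$resid),
    resindex = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain)
  )
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(natoms, 3, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m
  }
  rs_trajectory(atoms, coords, frame_interval_ps = frame_interval_ps)
}
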