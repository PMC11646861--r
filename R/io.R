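#' Read a molecular topology from PDB or GRO
#'
#' PDB files are parsed with bio3d; GRO files with a fixed-width reader.
#' Coordinates in the file are discarded here (see [load_system()] to keep
#' them); only atom/residue metadata are retained. Angstrom-based PDB input
#' is converted to nm on load.
#'
#' @param path file path ending in `.pdb` or `.gro`.
#' @param ligand optional ligand residue name, stored on the topology.
#' @param ligand_charges see [topology()].
#' @return a [topology()].
#' @export
read_topology <- function(path, ligand = NULL, ligand_charges = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    atoms <- parse_gro(path)$atoms
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    atoms <- data.frame(name = pdb$atom$elety,
                        resid = pdb$atom$resno,
                        resname = pdb$atom$resid,
                        chain = ifelse(is.na(pdb$atom$chain), "A",
                                       pdb$atom$chain),
                        stringsAsFactors = FALSE)
  }
  topology(atoms, ligand = ligand, ligand_charges = ligand_charges)
}

# Fixed-width GROMACS .gro parser: resid(5) resname(5) atom(5) serial(5)
# then x, y, z in nm (8.3 each). Returns atoms + coordinates.
parse_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  atoms <- data.frame(
    name = trimws(substr(body, 11, 15)),
    resid = as.integer(trimws(substr(body, 1, 5))),
    resname = trimws(substr(body, 6, 10)),
    stringsAsFactors = FALSE)
  xyz <- cbind(as.numeric(substr(body, 21, 28)),
               as.numeric(substr(body, 29, 36)),
               as.numeric(substr(body, 37, 44)))
  list(atoms = atoms, xyz = xyz,
       box = as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3])
}

#' Load a topology plus coordinate trajectories
#'
#' Accepts a PDB or GRO topology and one or more trajectory files:
#' multi-model PDB or DCD (read with bio3d). Frames are concatenated in
#' input order. PDB/DCD coordinates (Angstrom) are converted to nm.
#'
#' @param topology_path topology file (.pdb or .gro).
#' @param trajectory_paths character vector of trajectory files (.pdb
#'   multi-model or .dcd). If omitted, the topology file's own coordinates
#'   become a single frame.
#' @param stride keep every `stride`-th frame (first frame always kept).
#' @param dt frame spacing in ps used to synthesise times (trajectory
#'   containers carry no reliable time stamps), applied before striding.
#' @param ligand,ligand_charges passed to [topology()].
#' @return a [trajectory()].
#' @export
load_system <- function(topology_path, trajectory_paths = NULL, stride = 1,
                        dt = 50, ligand = NULL, ligand_charges = NULL) {
  stopifnot(stride >= 1)
  top <- read_topology(topology_path, ligand, ligand_charges)
  na <- nrow(top$atoms)
  frames <- list()
  if (is.null(trajectory_paths)) trajectory_paths <- topology_path
  for (p in trajectory_paths) {
    if (!file.exists(p)) stop("cannot read file: ", p)
    ext <- tolower(tools::file_ext(p))
    xyz <- if (ext == "dcd") {
      bio3d::read.dcd(p, verbose = FALSE) / 10
    } else if (ext == "gro") {
      matrix(t(parse_gro(p)$xyz), nrow = 1)
    } else {
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      pdb$xyz / 10
    }
    xyz <- as.matrix(xyz)
    if (ncol(xyz) != 3 * na) {
      stop("trajectory '", p, "' has ", ncol(xyz) / 3,
           " atoms but topology has ", na,
           " (topology/trajectory incompatibility)")
    }
    frames[[length(frames) + 1]] <- xyz
  }
  xyz <- do.call(rbind, frames)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3 * na, by = 3), drop = FALSE]
  keep <- seq(1, nf, by = stride)
  traj <- trajectory(top, coords[keep, , , drop = FALSE],
                     times = (keep - 1) * dt)
  message(sprintf("loaded %d frames, %d atoms, %.6g ps",
                  n_frames(traj), na,
                  traj$times[n_frames(traj)] - traj$times[1]))
  traj
}

#' Write a trajectory as a multi-model PDB
#'
#' Coordinates are written in Angstrom (PDB convention); reloading with
#' [load_system()] round-trips coordinates to the PDB's 3-decimal Angstrom
#' precision (1e-4 nm).
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- frame_coords(traj, f) * 10
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)) %% 100000, substr(nm, 1, 4), substr(a$resname, 1, 3),
      substr(a$chain, 1, 1), a$resid %% 10000, x[, 1], x[, 2], x[, 3],
      a$elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
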