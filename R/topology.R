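# Bondi van der Waals radii (nm); "X" is the fallback for unknown elements
# and for synthetic dummy atoms without an explicit per-atom radius.
.vdw_radii_nm <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                   S = 0.180, P = 0.180, F = 0.147, X = 0.150)

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, X = 12.0)

#' Guess an element symbol from an atom name
#'
#' Uses the leading alphabetic character of the atom name after stripping
#' digits and primes, which is correct for standard protein/ligand atom
#' names (e.g. `"HG11"` is hydrogen, `"OG"` oxygen, `"NZ"` nitrogen).
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols (`"X"` when unrecognised).
#' @export
guess_element <- function(name) {
  e <- substr(sub("^[0-9']+", "", toupper(name)), 1, 1)
  ifelse(e %in% names(.vdw_radii_nm), e, "X")
}

#' Construct a molecular topology
#'
#' A topology holds per-atom metadata (name, element, residue, chain) and a
#' derived ordered residue table. It is the static half of a [trajectory()];
#' coordinates live in the trajectory.
#'
#' @param atoms data.frame with columns `name`, `resid`, `resname`, and
#'   optionally `elem`, `chain`, `radius` (per-atom occupancy radius, nm,
#'   used by the pocket module in preference to element van der Waals radii).
#' @param ligand optional residue name of a ligand (e.g. `"STR"`); atoms of
#'   this residue are selectable with `class = "ligand"`.
#' @param ligand_charges optional list of charged-group declarations for the
#'   ligand, each `list(atoms = <character>, charge = +1 or -1)`. Required by
#'   salt-bridge detection when a ligand is present (no protonation-state
#'   inference is ever performed).
#' @return object of class `"topology"`: list with `atoms` (data.frame with
#'   added `heavy` flag), `residues` (ordered data.frame `resid`, `resname`,
#'   `chain`), `ligand`, `ligand_charges`.
#' @export
topology <- function(atoms, ligand = NULL, ligand_charges = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 0)
  for (col in c("name", "resid", "resname")) {
    if (is.null(atoms[[col]])) stop("atoms must have a '", col, "' column")
  }
  atoms$resid <- as.integer(atoms$resid)
  if (is.null(atoms$elem)) atoms$elem <- guess_element(atoms$name)
  if (any(is.na(atoms$elem) | atoms$elem == "")) {
    stop("every atom must have an element")
  }
  if (is.null(atoms$chain)) atoms$chain <- "A"
  atoms$heavy <- atoms$elem != "H"

  key <- paste(atoms$chain, atoms$resid, sep = "|")
  first <- !duplicated(key)
  residues <- data.frame(resid = atoms$resid[first],
                         resname = atoms$resname[first],
                         chain = atoms$chain[first],
                         stringsAsFactors = FALSE)
  for (ch in unique(residues$chain)) {
    r <- residues$resid[residues$chain == ch]
    if (length(r) > 1 && any(diff(r) <= 0)) {
      stop("residue indices must be strictly increasing within chain ", ch)
    }
  }
  if (!is.null(ligand) && !ligand %in% atoms$resname) {
    stop("ligand residue name '", ligand, "' not present in topology")
  }
  structure(list(atoms = atoms, residues = residues, ligand = ligand,
                 ligand_charges = ligand_charges),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,", nrow(x$residues), "residues")
  if (!is.null(x$ligand)) cat(", ligand", x$ligand)
  cat("\n")
  invisible(x)
}

n_residues <- function(top) nrow(top$residues)

#' Resolve an atom selection
#'
#' Selections are deterministic ordered atom index vectors. Filters combine
#' with AND.
#'
#' @param top a [topology()].
#' @param resid optional residue indices to keep.
#' @param name optional atom names to keep.
#' @param class one of `"all"`, `"heavy"`, `"ca"` (alpha carbons),
#'   `"backbone"` (N, CA, C, O), `"protein"` (non-ligand), `"ligand"`.
#' @return sorted integer vector of atom indices.
#' @export
select_atoms <- function(top, resid = NULL, name = NULL,
                         class = c("all", "heavy", "ca", "backbone",
                                   "protein", "ligand")) {
  class <- match.arg(class)
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  keep <- keep & switch(class,
    all = TRUE,
    heavy = a$heavy,
    ca = a$name == "CA",
    backbone = a$name %in% c("N", "CA", "C", "O"),
    protein = if (is.null(top$ligand)) TRUE else a$resname != top$ligand,
    ligand = {
      if (is.null(top$ligand)) stop("topology declares no ligand")
      a$resname == top$ligand
    })
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  which(keep)
}
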