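#' Toy solute: an atom table with nonbonded parameters
#'
#' The basic structural data model shared by the end-point and contact
#' stages: a flat table of atoms carrying coordinates, partial charges,
#' radii, Lennard-Jones parameters and masses. It deliberately carries no
#' bonded topology; only per-atom nonbonded parameters are modelled.
#'
#' @param atoms A data.frame with (at least) columns `x`, `y`, `z`
#'   (coordinates, A), `charge` (e), `radius` (A), `mass` (amu). Optional
#'   columns, filled with defaults when absent: `serial` (PDB serial,
#'   preserved for round-trips), `name` (atom name), `element`, `resname`,
#'   `resno`, `chain`, `role` (one of "backbone", "sidechain", "ligand"),
#'   `eps` (LJ well depth, kcal/mol) and `sigma` (LJ sigma, A).
#'
#' @return A data.frame of class `toy_solute`.
#' @export
toy_solute <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "charge", "radius", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("toy_solute: missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stop("toy_solute: at least one atom required")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$name)) atoms$name <- paste0("X", seq_len(n))
  if (is.null(atoms$element)) atoms$element <- "C"
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$resno)) atoms$resno <- 1L
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$role)) atoms$role <- "sidechain"
  if (is.null(atoms$eps)) atoms$eps <- 0
  if (is.null(atoms$sigma)) atoms$sigma <- 2 * atoms$radius / 2^(1 / 6)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("toy_solute: coordinates must be finite")
  if (any(atoms$radius <= 0)) stop("toy_solute: radii must be positive")
  if (any(atoms$mass <= 0)) stop("toy_solute: masses must be positive")
  if (!all(atoms$role %in% c("backbone", "sidechain", "ligand"))) {
    stop("toy_solute: role must be backbone, sidechain or ligand")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) stop("toy_solute: duplicate atom (chain, resno, name) records")
  class(atoms) <- c("toy_solute", "data.frame")
  atoms
}

solute_xyz <- function(solute) {
  as.matrix(solute[, c("x", "y", "z"), drop = FALSE])
}

#' @export
print.toy_solute <- function(x, ...) {
  cat(sprintf("<toy_solute> %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              paste(unique(x$chain), collapse = " ")))
  invisible(x)
}

#' Snapshot ensemble: frames over one topology
#'
#' An ordered series of coordinate frames for a fixed [toy_solute()]
#' topology -- the package's stand-in for an equilibrium trajectory.
#'
#' @param topology A [toy_solute()] whose parameters apply to every frame.
#' @param xyz A numeric array `n_atoms x 3 x n_frames` of coordinates (A),
#'   or a list of `n_atoms x 3` matrices. When omitted, a single frame is
#'   taken from the topology coordinates.
#' @param origin One of "complex", "protein", "ligand": which leg of the
#'   single-trajectory protocol the frames describe.
#' @param stride Frame stride metadata (frames kept every `stride` steps).
#'
#' @return An object of class `snapshot_ensemble` with fields `topology`,
#'   `xyz` (array), `origin`, `stride`.
#' @export
snapshot_ensemble <- function(topology, xyz = NULL, origin = "complex", stride = 1L) {
  if (!inherits(topology, "toy_solute")) stop("snapshot_ensemble: topology must be a toy_solute")
  n <- nrow(topology)
  if (is.null(xyz)) xyz <- array(solute_xyz(topology), dim = c(n, 3, 1))
  if (is.list(xyz)) {
    xyz <- array(unlist(lapply(xyz, as.matrix)), dim = c(n, 3, length(xyz)))
  }
  if (!is.array(xyz) || length(dim(xyz)) != 3L || dim(xyz)[1] != n || dim(xyz)[2] != 3L) {
    stop("snapshot_ensemble: xyz must be an n_atoms x 3 x n_frames array matching the topology")
  }
  if (dim(xyz)[3] < 1L) stop("snapshot_ensemble: at least one frame required")
  if (any(!is.finite(xyz))) stop("snapshot_ensemble: coordinates must be finite")
  origin <- match.arg(origin, c("complex", "protein", "ligand"))
  structure(list(topology = topology, xyz = xyz, origin = origin, stride = as.integer(stride)),
            class = "snapshot_ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble A [snapshot_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  dim(ensemble$xyz)[3]
}

#' Extract one frame as an n x 3 coordinate matrix
#' @param ensemble A [snapshot_ensemble()].
#' @param i Frame index (1-based).
#' @return Numeric `n_atoms x 3` matrix.
#' @export
frame_coords <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  if (i < 1L || i > n_frames(ensemble)) stop("frame_coords: frame index out of range")
  ensemble$xyz[, , i, drop = TRUE]
}

#' Restrict an ensemble to an atom subset
#'
#' Sub-selects atoms from every frame, keeping the frame order. Used by the
#' single-trajectory protocol to derive protein-only and ligand-only
#' ensembles from the complex trajectory.
#'
#' @param ensemble A [snapshot_ensemble()].
#' @param idx Integer or logical atom index into the topology.
#' @param origin Origin tag for the sub-ensemble.
#' @return A [snapshot_ensemble()] over the selected atoms.
#' @export
subset_ensemble <- function(ensemble, idx, origin = ensemble$origin) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  topo <- ensemble$topology[idx, , drop = FALSE]
  class(topo) <- c("toy_solute", "data.frame")
  snapshot_ensemble(topo, ensemble$xyz[idx, , , drop = FALSE], origin = origin,
                    stride = ensemble$stride)
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat(sprintf("<snapshot_ensemble> %d frames x %d atoms (%s)\n",
              n_frames(x), nrow(x$topology), x$origin))
  invisible(x)
}

#' Free-energy estimate container
#'
#' @param value Estimate in kcal/mol.
#' @param sd One standard deviation, kcal/mol (>= 0); `NA` when not
#'   estimated.
#' @param method One of "EXP", "MBAR", "WHAM", "MMPBSA", "EXPERIMENT".
#' @param breakdown Optional named list/vector of per-interval or per-term
#'   contributions.
#' @param notes Optional character notes (gauge conventions, flags).
#' @return An object of class `free_energy_estimate`.
#' @export
free_energy_estimate <- function(value, sd = NA_real_, method = "MBAR",
                                 breakdown = NULL, notes = character()) {
  if (!is.na(sd) && sd < 0) stop("free_energy_estimate: sd must be >= 0")
  structure(list(value = as.numeric(value), sd = as.numeric(sd),
                 method = method, breakdown = breakdown, notes = notes),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate:%s> %.4f +/- %s kcal/mol\n",
              x$method, x$value, ifelse(is.na(x$sd), "NA", sprintf("%.4f", x$sd))))
  if (length(x$notes)) cat("  ", paste(x$notes, collapse = "; "), "\n", sep = "")
  invisible(x)
}
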