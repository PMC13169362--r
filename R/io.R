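# Readers/writers for the formats touched: multi-model PDB (via bio3d),
# GROMACS XVG time series, and typed CSV/TSV tables with sidecar
# nonbonded parameters.

#' Read a (multi-model) PDB file into the package's data model
#'
#' Parses ATOM/HETATM records through bio3d; MODEL/ENDMDL blocks become
#' ensemble frames. Coordinates are in A. Nonbonded parameters (charge,
#' radius, LJ) are not part of the PDB format; supply them as a sidecar
#' table via `params` (see [read_params_table()]) or accept the neutral
#' defaults (q = 0, radius 1.7 A, mass 12 amu).
#'
#' @param path PDB file path.
#' @param params Optional data.frame with columns `serial`, `charge`,
#'   `radius`, `eps`, `sigma`, `mass` matched to the ATOM serial numbers.
#' @param ligand_chain Chain id(s) whose atoms get role "ligand".
#' @return List with `solute` (first-frame [toy_solute()]) and `ensemble`
#'   (a [snapshot_ensemble()] over all models).
#' @export
read_pdb <- function(path, params = NULL, ligand_chain = NULL) {
  if (!file.exists(path)) stop("read_pdb: file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n <- nrow(at)
  role <- ifelse(!is.null(ligand_chain) & at$chain %in% ligand_chain, "ligand",
                 ifelse(toupper(at$elety) %in% BACKBONE_NAMES, "backbone", "sidechain"))
  atoms <- data.frame(
    serial = at$eleno, name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "", substr(at$elety, 1, 1), at$elesy),
    resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain), role = role,
    x = at$x, y = at$y, z = at$z,
    charge = 0, radius = 1.7, mass = 12.011, eps = 0, sigma = 3.4,
    stringsAsFactors = FALSE)
  if (!is.null(params)) {
    m <- match(atoms$serial, params$serial)
    if (any(is.na(m))) stop("read_pdb: params table missing serials: ",
                            paste(utils::head(atoms$serial[is.na(m)]), collapse = ", "))
    for (col in intersect(c("charge", "radius", "eps", "sigma", "mass"), names(params))) {
      atoms[[col]] <- params[[col]][m]
    }
  }
  solute <- toy_solute(atoms)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  arr <- array(NA_real_, dim = c(n, 3, nf))
  for (f in seq_len(nf)) arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  if (any(!is.finite(arr))) stop("read_pdb: inconsistent atom count across models")
  list(solute = solute, ensemble = snapshot_ensemble(solute, arr))
}

#' Write a solute or ensemble to a (multi-model) PDB file
#'
#' Emits one MODEL/ENDMDL block per frame through bio3d, preserving
#' serials, names, residue numbering and chain ids; coordinates keep the
#' format's three decimals, so round-trips are stable at that precision.
#'
#' @param solute A [toy_solute()] (used for the topology columns).
#' @param path Output path.
#' @param ensemble Optional [snapshot_ensemble()]; default a single frame
#'   from the solute coordinates.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(solute, path, ensemble = NULL) {
  if (is.null(ensemble)) ensemble <- snapshot_ensemble(solute)
  if (n_frames(ensemble) < 1L) stop("write_pdb: empty ensemble")
  n <- nrow(solute)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_frames(ensemble) > 1L
  for (f in seq_len(n_frames(ensemble))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xy <- frame_coords(ensemble, f)
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     solute$serial, substr(solute$name, 1, 4),
                     substr(solute$resname, 1, 3), solute$chain, solute$resno,
                     xy[, 1], xy[, 2], xy[, 3], 1.0, 0.0,
                     substr(solute$element, 1, 2))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a GROMACS XVG time series
#'
#' Skips '#' and '@' comment/legend lines and parses whitespace-separated
#' numeric columns. By GROMACS convention column 1 is time (ps) and
#' column 2 a coordinate in nm; under `unit_policy = "A"` coordinate
#' columns (all but the first) are multiplied by 10 into A.
#'
#' @param path XVG file path.
#' @param unit_policy "A" (convert nm to A, default) or "as_is".
#' @return Data.frame; first column `time`, remaining `V1`, `V2`, ...
#' @export
read_xvg <- function(path, unit_policy = c("A", "as_is")) {
  unit_policy <- match.arg(unit_policy)
  if (!file.exists(path)) stop("read_xvg: file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  ncols <- lengths(rows)
  if (!length(rows)) stop("read_xvg: no data rows")
  if (length(unique(ncols)) != 1L) stop("read_xvg: ragged rows")
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncols[1])))
  if (any(!is.finite(vals))) {
    bad <- which(keep)[which(apply(matrix(!is.finite(vals), nrow = ncols[1]), 2, any))[1]]
    stop(sprintf("read_xvg: non-numeric data at line %d", bad))
  }
  df <- as.data.frame(t(matrix(vals, nrow = ncols[1])))
  names(df) <- c("time", paste0("V", seq_len(ncols[1] - 1L)))
  if (unit_policy == "A" && ncol(df) > 1L) {
    df[, -1] <- df[, -1, drop = FALSE] * 10
  }
  df
}

#' Read a typed delimited table against a schema
#'
#' Reads a CSV/TSV with a mandatory header and checks that the required
#' columns are present; unknown columns are preserved.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param sep Field separator ("," default; "\t" for TSV).
#' @return Data.frame.
#' @export
read_table_schema <- function(path, required = character(), sep = ",") {
  if (!file.exists(path)) stop("read_table_schema: file not found: ", path)
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE),
                 error = function(e) stop("read_table_schema: ", conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("read_table_schema: missing required column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a sidecar nonbonded-parameter table
#'
#' TSV/CSV with columns `serial`, `charge`, `radius`, `eps`, `sigma` (and
#' optionally `mass`) keyed to PDB serials, as consumed by [read_pdb()].
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data.frame.
#' @export
read_params_table <- function(path, sep = "\t") {
  read_table_schema(path, required = c("serial", "charge", "radius"), sep = sep)
}

#' Write a delimited table
#'
#' @param df Data.frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_table_schema <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IC50 CSV into records
#'
#' Expects columns `ligand`, `target`, `ic50_nM` and optionally
#' `sigma_nM`, `source`; concentrations are converted to molar.
#'
#' @param path CSV path.
#' @return Data.frame compatible with [ic50_to_dG()].
#' @export
read_ic50_csv <- function(path) {
  df <- read_table_schema(path, required = c("ligand", "target", "ic50_nM"))
  out <- data.frame(ligand = df$ligand, target = df$target,
                    ic50 = df$ic50_nM * 1e-9,
                    sigma = if ("sigma_nM" %in% names(df)) df$sigma_nM * 1e-9 else NA_real_,
                    stringsAsFactors = FALSE)
  if ("source" %in% names(df)) out$note <- df$source
  out
}
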