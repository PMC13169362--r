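# Residue-level contact analysis: ligand heavy atoms vs side-chain
# centres of mass, contact frequencies over frames, shared/exclusive
# classification across paralogues, per-residue energy decomposition.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

is_heavy <- function(solute) {
  !(toupper(solute$element) %in% c("H", "D")) & !grepl("^H", toupper(solute$name))
}

#' Side-chain centre of mass of one residue
#'
#' Mass-weighted centre of the non-backbone heavy atoms (backbone = N,
#' CA, C, O). Glycine, having no side-chain heavy atom, falls back to its
#' CA position.
#'
#' @param solute A [toy_solute()] topology.
#' @param resno,chain Residue number and chain id selecting the residue.
#' @param coords Optional frame coordinates.
#' @return Length-3 coordinates (A).
#' @export
sidechain_com <- function(solute, resno, chain = NULL, coords = NULL) {
  xyz <- if (is.null(coords)) solute_xyz(solute) else as.matrix(coords)
  sel <- solute$resno == resno
  if (!is.null(chain)) sel <- sel & solute$chain == chain
  if (!any(sel)) stop(sprintf("sidechain_com: residue %s not present", resno))
  heavy <- sel & is_heavy(solute)
  sc <- heavy & !(toupper(solute$name) %in% BACKBONE_NAMES)
  if (any(sc)) {
    return(center_of_mass(xyz[sc, , drop = FALSE], solute$mass[sc]))
  }
  # glycine fallback: CA position
  if (any(solute$resname[sel] %in% c("GLY", "G")) || any(toupper(solute$name[heavy]) == "CA")) {
    ca <- heavy & toupper(solute$name) == "CA"
    if (any(ca)) return(as.numeric(xyz[which(ca)[1], ]))
  }
  stop(sprintf("sidechain_com: residue %s has no side-chain heavy atoms and no CA", resno))
}

#' Per-residue ligand contact frequencies over an ensemble
#'
#' A residue is in contact in a frame iff the minimum distance between any
#' ligand heavy atom and the residue's side-chain centre of mass is at
#' most `cutoff`. The frequency is the fraction of considered frames in
#' contact.
#'
#' @param ensemble A [snapshot_ensemble()] of the complex.
#' @param ligand_idx Atom selection of the ligand (hydrogens are ignored
#'   even if selected).
#' @param residues Data.frame with columns `resno` and optionally `chain`;
#'   default: every non-ligand residue in the topology.
#' @param cutoff Contact distance cutoff, A (default 5.0).
#' @param stride Consider every `stride`-th frame.
#' @return An object of class `contact_map`: data.frame `frequencies`
#'   (resno, chain, frequency), plus `cutoff`, `n_frames`,
#'   `ligand_atoms`.
#' @export
contact_frequencies <- function(ensemble, ligand_idx, residues = NULL,
                                cutoff = 5.0, stride = 1L) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  topo <- ensemble$topology
  ligand_idx <- to_index(ligand_idx, nrow(topo))
  ligand_idx <- ligand_idx[is_heavy(topo)[ligand_idx]]
  if (!length(ligand_idx)) stop("contact_frequencies: empty ligand heavy-atom selection")
  if (is.null(residues)) {
    non_lig <- setdiff(seq_len(nrow(topo)), ligand_idx)
    residues <- unique(data.frame(resno = topo$resno[non_lig],
                                  chain = topo$chain[non_lig]))
    residues <- residues[topo$role[match(paste(residues$chain, residues$resno),
                                         paste(topo$chain, topo$resno))] != "ligand", ,
                         drop = FALSE]
  }
  if (is.null(residues$chain)) residues$chain <- NA_character_
  frames <- seq(1L, n_frames(ensemble), by = stride)
  hits <- matrix(0L, nrow = nrow(residues), ncol = length(frames))
  for (fi in seq_along(frames)) {
    xy <- frame_coords(ensemble, frames[fi])
    L <- xy[ligand_idx, , drop = FALSE]
    for (ri in seq_len(nrow(residues))) {
      com <- sidechain_com(topo, residues$resno[ri],
                           chain = if (is.na(residues$chain[ri])) NULL else residues$chain[ri],
                           coords = xy)
      dmin <- sqrt(min(rowSums(sweep(L, 2, com)^2)))
      hits[ri, fi] <- as.integer(dmin <= cutoff)
    }
  }
  freq <- rowMeans(hits)
  structure(list(frequencies = data.frame(resno = residues$resno,
                                          chain = residues$chain,
                                          frequency = freq,
                                          stringsAsFactors = FALSE),
                 cutoff = cutoff, n_frames = length(frames),
                 ligand_atoms = ligand_idx),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n_con <- sum(x$frequencies$frequency > 0)
  cat(sprintf("<contact_map> %d residues (%d contacting), cutoff %.1f A, %d frames\n",
              nrow(x$frequencies), n_con, x$cutoff, x$n_frames))
  invisible(x)
}

#' Classify paralogue contacts as shared or exclusive
#'
#' Given contact maps of the same ligand bound to two paralogues and a
#' one-to-one residue correspondence, a pair is *shared* when both
#' frequencies reach `threshold`, *exclusive* to one structure when only
#' its frequency does. Contacting residues absent from the mapping are
#' reported separately, never dropped.
#'
#' @param mapA,mapB [contact_frequencies()] outputs for structures A and
#'   B, computed at the same cutoff.
#' @param mapping Data.frame with columns `resA`, `resB` (residue numbers;
#'   one-to-one).
#' @param threshold Contact frequency threshold (default 0.5).
#' @return An object of class `contact_classification`: `shared`,
#'   `exclusive_A`, `exclusive_B` (data.frames of residue pairs with both
#'   frequencies), `unmapped_A`, `unmapped_B`, `threshold`.
#' @export
classify_contacts <- function(mapA, mapB, mapping, threshold = 0.5) {
  stopifnot(inherits(mapA, "contact_map"), inherits(mapB, "contact_map"))
  if (!isTRUE(all.equal(mapA$cutoff, mapB$cutoff))) {
    stop("classify_contacts: maps computed at different cutoffs")
  }
  mapping <- as.data.frame(mapping)
  if (anyDuplicated(mapping$resA) || anyDuplicated(mapping$resB)) {
    stop("classify_contacts: mapping must be one-to-one")
  }
  fa <- mapA$frequencies; fb <- mapB$frequencies
  ia <- match(mapping$resA, fa$resno)
  ib <- match(mapping$resB, fb$resno)
  if (any(is.na(ia)) || any(is.na(ib))) {
    stop("classify_contacts: mapping references residues absent from a map")
  }
  tab <- data.frame(resA = mapping$resA, resB = mapping$resB,
                    freqA = fa$frequency[ia], freqB = fb$frequency[ib])
  inA <- tab$freqA >= threshold
  inB <- tab$freqB >= threshold
  unmapped_A <- fa[!(fa$resno %in% mapping$resA) & fa$frequency >= threshold, , drop = FALSE]
  unmapped_B <- fb[!(fb$resno %in% mapping$resB) & fb$frequency >= threshold, , drop = FALSE]
  structure(list(shared = tab[inA & inB, , drop = FALSE],
                 exclusive_A = tab[inA & !inB, , drop = FALSE],
                 exclusive_B = tab[!inA & inB, , drop = FALSE],
                 unmapped_A = unmapped_A, unmapped_B = unmapped_B,
                 threshold = threshold, cutoff = mapA$cutoff),
            class = "contact_classification")
}

#' @export
print.contact_classification <- function(x, ...) {
  cat(sprintf("<contact_classification> threshold %.2f: %d shared, %d exclusive-A, %d exclusive-B\n",
              x$threshold, nrow(x$shared), nrow(x$exclusive_A), nrow(x$exclusive_B)))
  invisible(x)
}

#' Per-residue ligand interaction energies
#'
#' Frame-averaged Coulomb and Lennard-Jones energies between the ligand
#' selection and each residue's atoms, sorted most stabilising (lowest
#' total) first. Because residues partition the protein atoms, the
#' per-residue energies sum exactly to the total protein-ligand
#' interaction energy.
#'
#' @param ensemble A [snapshot_ensemble()].
#' @param ligand_idx Ligand atom selection.
#' @param ctx A [thermo_context()].
#' @param residues Optional residue table as in [contact_frequencies()].
#' @return Data.frame with `resno`, `chain`, `elec`, `vdw`, `total`
#'   (kcal/mol), sorted ascending by total.
#' @export
per_residue_interaction_energy <- function(ensemble, ligand_idx, ctx,
                                           residues = NULL) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  assert_ctx(ctx)
  topo <- ensemble$topology
  ligand_idx <- to_index(ligand_idx, nrow(topo))
  if (is.null(residues)) {
    non_lig <- setdiff(seq_len(nrow(topo)), ligand_idx)
    residues <- unique(data.frame(resno = topo$resno[non_lig],
                                  chain = topo$chain[non_lig]))
  }
  nf <- n_frames(ensemble)
  acc <- matrix(0, nrow = nrow(residues), ncol = 2,
                dimnames = list(NULL, c("elec", "vdw")))
  for (f in seq_len(nf)) {
    xy <- frame_coords(ensemble, f)
    for (ri in seq_len(nrow(residues))) {
      sel <- topo$resno == residues$resno[ri]
      if (!is.null(residues$chain) && !is.na(residues$chain[ri])) {
        sel <- sel & topo$chain == residues$chain[ri]
      }
      idx <- setdiff(which(sel), ligand_idx)
      if (!length(idx)) next
      e <- mm_interaction_energy(topo, idx, ligand_idx, ctx, coords = xy)
      acc[ri, ] <- acc[ri, ] + e
    }
  }
  acc <- acc / nf
  out <- data.frame(resno = residues$resno,
                    chain = if (is.null(residues$chain)) NA_character_ else residues$chain,
                    elec = acc[, "elec"], vdw = acc[, "vdw"],
                    total = acc[, "elec"] + acc[, "vdw"],
                    stringsAsFactors = FALSE)
  out[order(out$total), , drop = FALSE]
}
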