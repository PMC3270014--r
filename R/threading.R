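# ---------------------------------------------------------------------------
# In-silico base-pair substitution and threading
# ---------------------------------------------------------------------------

normalize_base <- function(base) {
  base <- toupper(base)
  if (base %in% c("A", "C", "G", "T")) base <- paste0("D", base)
  if (!base %in% .standard_dna_residues)
    stop("unknown base: ", base)
  base
}

# Replace the base moiety of one DNA residue with library geometry for
# new_res: backbone rows are untouched (coordinates bitwise identical), the
# old base atoms are removed, and the new base is placed by superposing the
# library glycosidic frame (C1', glycosidic N, ring anchor) onto the
# residue's frame.  The residue is renamed so atom typing follows the new
# identity.
replace_residue_base <- function(atoms, chain, resno, new_res) {
  in_res <- atoms$chain == chain & atoms$resno == resno
  if (!any(in_res)) stop("no residue ", resno, " in chain ", chain)
  old_res <- atoms$resname[in_res][1]
  frame_old <- glycosidic_frame_atoms(old_res)
  frame_new <- glycosidic_frame_atoms(new_res)
  res_atoms <- atoms[in_res, , drop = FALSE]
  if (!all(frame_old %in% res_atoms$atom))
    stop("residue ", chain, ":", resno, " lacks glycosidic frame atoms ",
         paste(setdiff(frame_old, res_atoms$atom), collapse = ", "))
  fixed <- coords(res_atoms[match(frame_old, res_atoms$atom), , drop = FALSE])
  moving <- lib_coords(new_res, frame_new)
  tf <- kabsch(moving, fixed)$transform
  lib <- base_library()[[new_res]]
  new_base <- lib[lib$atom %in% base_moiety_atoms(new_res), , drop = FALSE]
  placed <- apply_transform(as.matrix(new_base[, c("x", "y", "z")]), tf)
  keep_backbone <- in_res & !(atoms$atom %in% base_moiety_atoms(old_res))
  backbone <- atoms[keep_backbone, , drop = FALSE]
  backbone$resname <- new_res
  added <- data.frame(chain = chain, resno = resno, resname = new_res,
                      atom = new_base$atom, element = new_base$element,
                      x = placed[, 1], y = placed[, 2], z = placed[, 3],
                      occupancy = 1, stringsAsFactors = FALSE)
  first <- which(in_res)[1]
  before <- atoms[seq_len(nrow(atoms)) < first & !in_res, , drop = FALSE]
  after <- atoms[seq_len(nrow(atoms)) > first & !in_res, , drop = FALSE]
  rbind(before, backbone, added, after)
}

#' Substitute a Watson-Crick base pair in silico
#'
#' Sets the reference-strand base at duplex position `i` to `base` and its
#' partner to the Watson-Crick complement.  Sugar-phosphate backbone
#' coordinates are bitwise unchanged on both strands; the base moieties are
#' rebuilt from the idealized library by superposing the common glycosidic
#' frame (C1' plus the glycosidic nitrogen and its ring anchor: N9/C4 for
#' purines, N1/C2 for pyrimidines).  Residue names are updated so atom
#' typing reflects the new identity.
#'
#' @param cx a `complex`.
#' @param duplex a [detect_duplex()] result for `cx`.
#' @param i paired position index (5'→3' along the reference strand).
#' @param base new reference-strand base: `"A"/"C"/"G"/"T"` or
#'   `"DA"/"DC"/"DG"/"DT"`.
#' @return The modified `complex`.
#' @export
substitute_base_pair <- function(cx, duplex, i, base) {
  stopifnot(inherits(cx, "complex"), inherits(duplex, "duplex_info"))
  if (!(i >= 1 && i <= duplex$n_paired))
    stop("position ", i, " is not a paired position (duplex has ",
         duplex$n_paired, " pairs)")
  base <- normalize_base(base)
  pair <- duplex$pairs[i, ]
  atoms <- replace_residue_base(cx$atoms, pair$chain1, pair$resno1, base)
  atoms <- replace_residue_base(atoms, pair$chain2, pair$resno2,
                                wc_complement(base))
  out <- as_complex(atoms, resolution = cx$resolution, method = cx$method,
                    model_index = cx$model_index)
  out
}

#' Per-position binding free energies of the four bases
#'
#' For each base identity `A, C, G, T`, substitutes the Watson-Crick pair
#' at position `i` and sums the pair potential between all protein heavy
#' atoms and the heavy atoms of the two substituted nucleotides within the
#' 10 A cutoff.  With `base_only = TRUE` the sum is restricted to the base
#' moieties (excluding the sugar-phosphate backbone).
#'
#' @param cx a `complex`.
#' @param duplex a [detect_duplex()] result.
#' @param i paired position index.
#' @param pot a [derive_potential()] table.
#' @param base_only restrict the per-position sum to base-moiety atoms
#'   (default `FALSE`: full nucleotides, so backbone atom types follow the
#'   substituted identity).
#' @return Object of class `position_energies`: `position`, `energies`
#'   (named numeric, A/C/G/T), `contacted` (any protein atom within the
#'   cutoff of any variant's nucleotides; when `FALSE` all four energies
#'   are 0).
#' @export
position_energies <- function(cx, duplex, i, pot, base_only = FALSE) {
  stopifnot(inherits(pot, "pair_potential_table"))
  pa <- atoms_of_kind(cx, "protein")
  energies <- c(A = 0, C = 0, G = 0, T = 0)
  any_contact <- FALSE
  pair <- duplex$pairs[i, ]
  for (b in names(energies)) {
    cxb <- substitute_base_pair(cx, duplex, i, b)
    at <- cxb$atoms
    in_pos <- (at$chain == pair$chain1 & at$resno == pair$resno1) |
              (at$chain == pair$chain2 & at$resno == pair$resno2)
    nuc <- at[in_pos, , drop = FALSE]
    if (base_only)
      nuc <- nuc[!(nuc$atom %in% .dna_backbone_atoms), , drop = FALSE]
    res <- pair_energy_kernel(pa, nuc, pot)
    energies[b] <- res$energy
    any_contact <- any_contact || res$n_pairs > 0
  }
  structure(list(position = i, energies = energies,
                 contacted = any_contact),
            class = "position_energies")
}

# Boltzmann column with max-shift for numerical stability.
boltzmann_column <- function(energies, beta) {
  w <- exp(-(energies - min(energies)) / beta)
  w / sum(w)
}

#' Predict a position weight matrix by threading
#'
#' Threads every paired duplex position through the four base identities,
#' converts the per-position free energies `dG_i(base)` to column
#' probabilities `p ~ exp(-dG / beta)`, and assembles the columns 5'→3'
#' along the reference strand.  Positions with no protein atom within the
#' cutoff get uniform columns and are flagged as non-contacted: the method
#' is only informative about positions the protein can physically touch.
#'
#' @param cx a `complex` (typically a superimposed complex from
#'   [build_superimposed_complex()] or a native co-crystal).
#' @param duplex a [detect_duplex()] result; defaults to detecting it from
#'   `cx`.
#' @param pot a [derive_potential()] table.
#' @param params a [potential_params()]; `params$beta` (default 15) is the
#'   emission temperature.
#' @param base_only see [position_energies()].
#' @return A [pwm()] with per-column `contacted` flags and the energy
#'   matrix in `attr(, "energies")`.
#' @export
predict_pwm <- function(cx, duplex = detect_duplex(cx), pot,
                        params = potential_params(), base_only = FALSE) {
  if (duplex$n_paired < 1) stop("duplex has no paired position")
  cols <- matrix(NA_real_, duplex$n_paired, 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  emat <- cols
  contacted <- logical(duplex$n_paired)
  for (i in seq_len(duplex$n_paired)) {
    pe <- position_energies(cx, duplex, i, pot, base_only = base_only)
    emat[i, ] <- pe$energies
    cols[i, ] <- boltzmann_column(pe$energies, params$beta)
    contacted[i] <- pe$contacted
  }
  out <- pwm(cols, contacted = contacted,
             reference_strand = duplex$reference_strand,
             beta = params$beta)
  attr(out, "energies") <- emat
  out
}
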