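# ---------------------------------------------------------------------------
# Synthetic fixtures: idealized B-DNA, toy protein-DNA complexes with
# planted contacts, and planted-preference corpora for end-to-end checks
# ---------------------------------------------------------------------------

#' Generate an idealized B-form DNA duplex
#'
#' Stacks rigid Watson-Crick pair templates (built from the idealized
#' nucleotide library) with uniform rise and twist along the z axis.
#' Geometry is idealized, not sequence-dependent: every pair uses library
#' base geometry and one fixed conformer per nucleotide, which is
#' sufficient for contact counting, duplex detection and threading tests
#' but is not a physical model of DNA.
#'
#' @param sequence reference-strand sequence 5'→3', alphabet ACGT,
#'   length >= 2.
#' @param chains chain ids for the reference and complementary strand.
#' @param rise helical rise per step in Angstrom (default 3.38).
#' @param twist helical twist per step in degrees (default 36).
#' @return A `complex` with two DNA chains; [detect_duplex()] pairs every
#'   position.
#' @export
make_bdna <- function(sequence, chains = c("A", "B"), rise = 3.38,
                      twist = 36) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2) stop("sequence must have length >= 2")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("sequence must be over the alphabet ACGT")
  templates <- wc_pair_templates()
  L <- length(bases)
  lib <- base_library()
  rows <- list()
  for (p in seq_len(L)) {
    tpl <- templates[[paste0("D", bases[p])]]
    R <- rot_z((p - 1) * twist * pi / 180)
    shift <- c(0, 0, (p - 1) * rise)
    place <- function(xyz, resname, chain, resno) {
      moved <- sweep(xyz %*% t(R), 2, shift, "+")
      data.frame(chain = chain, resno = resno, resname = resname,
                 atom = rownames(xyz),
                 element = lib[[resname]][rownames(xyz), "element"],
                 x = moved[, 1], y = moved[, 2], z = moved[, 3],
                 occupancy = 1, stringsAsFactors = FALSE)
    }
    rows[[2 * p - 1]] <- place(tpl$ref, tpl$ref_name, chains[1], p)
    rows[[2 * p]] <- place(tpl$partner, tpl$partner_name, chains[2],
                           L + 1L - p)
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(match(atoms$chain, chains), atoms$resno), ]
  rownames(atoms) <- NULL
  as_complex(atoms)
}

# Idealized poly-ALA geometry offsets (local frame: radial, tangent, z).
.ala_offsets <- list(N = c(0.0, -1.33, 0.60), CA = c(0, 0, 0),
                     C = c(0.0, 1.33, 0.60), O = c(0.5, 1.80, 1.55),
                     CB = c(1.53, 0, 0))

# Place a poly-alanine arc of n residues on a circle of given radius about
# the z axis, centered at height z0.  CB points radially outward (away
# from the DNA).
poly_ala_arc <- function(n, radius = 28, z0 = 0, chain = "P",
                         jitter = 0.15) {
  step <- 3.8 / radius
  rows <- list()
  for (i in seq_len(n)) {
    th <- (i - 1) * step
    rad <- c(cos(th), sin(th), 0)
    tan <- c(-sin(th), cos(th), 0)
    ca <- radius * rad + c(0, 0, z0)
    for (a in names(.ala_offsets)) {
      o <- .ala_offsets[[a]]
      xyz <- ca + o[1] * rad + o[2] * tan + c(0, 0, o[3]) +
        stats::runif(3, -jitter, jitter)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, resname = "ALA", atom = a,
        element = substring(a, 1, 1), x = xyz[1], y = xyz[2], z = xyz[3],
        occupancy = 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Resolve a planted-contact target to coordinates.  contact fields:
#   residue: protein resno whose atom is relocated (default: sequential)
#   atom:    protein atom name (default "CB")
#   position: duplex position (reference strand)
#   dna_atom: DNA atom name anchoring the contact (default "P")
#   strand:  "ref" or "partner"
#   distance: planted distance in Angstrom
#   mode:    "radial" (outward from the helix axis, default) or "groove"
#            (in the base plane, outward through the major-groove edge)
resolve_contact_site <- function(dna_atoms, duplex, contact,
                                 avoid_xyz = NULL) {
  pos <- contact$position
  if (pos < 1 || pos > duplex$n_paired)
    stop("planted contact position ", pos, " outside the duplex")
  pair <- duplex$pairs[pos, ]
  use_ref <- is.null(contact$strand) || contact$strand == "ref"
  ch <- if (use_ref) pair$chain1 else pair$chain2
  rn <- if (use_ref) pair$resno1 else pair$resno2
  res <- dna_atoms[dna_atoms$chain == ch & dna_atoms$resno == rn, ,
                   drop = FALSE]
  mode <- if (is.null(contact$mode)) "radial" else contact$mode
  if (mode == "groove") {
    resname <- res$resname[1]
    anchor_name <- if (is_purine_residue(resname)) "N7" else "C5"
    anchor <- as.numeric(res[res$atom == anchor_name, c("x", "y", "z")])
    base <- res[res$atom %in% base_moiety_atoms(resname), , drop = FALSE]
    ctr <- colMeans(coords(base))
    pl <- fit_plane(coords(base))
    u <- anchor - ctr
    u <- u - sum(u * pl$normal) * pl$normal      # project into base plane
    u <- u / sqrt(sum(u^2))
    list(anchor = anchor, dir = u)
  } else {
    atom_name <- if (is.null(contact$dna_atom)) "P" else contact$dna_atom
    hit <- res[res$atom == atom_name, , drop = FALSE]
    if (!nrow(hit))
      stop("DNA residue ", ch, ":", rn, " has no atom ", atom_name)
    anchor <- as.numeric(hit[1, c("x", "y", "z")])
    u0 <- c(anchor[1], anchor[2], 0)
    u0 <- u0 / sqrt(sum(u0^2))
    # fan of outward candidate directions (radial plus fixed tilts); keep
    # the one whose planted site clears the rest of the duplex best
    tilts <- expand.grid(az = seq(-90, 90, by = 15) * pi / 180,
                         el = seq(-70, 70, by = 10) * pi / 180)
    dna_xyz <- rbind(coords(dna_atoms), avoid_xyz)
    best <- NULL
    for (k in seq_len(nrow(tilts))) {
      u <- c(cos(tilts$el[k]) * (rot_z(tilts$az[k])[1:2, 1:2] %*% u0[1:2]),
             sin(tilts$el[k]))
      tgt <- anchor + contact$distance * u
      clr <- sqrt(min(cross_dist2(matrix(tgt, 1), dna_xyz)))
      if (is.null(best) || clr > best$clr) best <- list(u = u, clr = clr)
    }
    list(anchor = anchor, dir = best$u)
  }
}

#' Generate a toy protein-DNA complex with planted contacts
#'
#' Builds an idealized B-DNA duplex plus a synthetic poly-alanine chain
#' placed on an arc far from the DNA, then relocates designated side-chain
#' atoms to planted distances from designated DNA atoms.  The output is
#' deterministic for a given seed, carries X-ray-like metadata so the
#' selection filters can be exercised, and parses/round-trips through the
#' structure I/O.
#'
#' @param dna_sequence reference-strand sequence (ACGT).
#' @param protein_size number of alanine residues (default 45).
#' @param planted_contacts list of contacts; each a list with fields
#'   `residue`, `atom`, `position`, `dna_atom`, `strand`, `distance`,
#'   `mode` (see Details in the source; defaults plant a CB radially off a
#'   backbone phosphate).
#' @param seed integer seed controlling the arc jitter.
#' @param resolution,method metadata stamped on the complex (defaults
#'   2.0 A, X-ray) so the knowledgebase profile accepts it.
#' @return A `complex` with one protein and two DNA chains.
#' @export
make_toy_complex <- function(dna_sequence = "GATTACCA", protein_size = 45,
                             planted_contacts = list(), seed = 1,
                             resolution = 2.0,
                             method = "X-RAY DIFFRACTION") {
  dna <- make_bdna(dna_sequence)
  duplex <- detect_duplex(dna)
  zmid <- mean(range(dna$atoms$z))
  prot <- with_seed(seed,
                    poly_ala_arc(protein_size, z0 = zmid, chain = "P"))
  planted_rows <- integer()
  planted_xyz <- NULL
  for (contact in planted_contacts) {
    site <- resolve_contact_site(dna$atoms, duplex, contact,
                                 avoid_xyz = planted_xyz)
    target <- site$anchor + contact$distance * site$dir
    res_no <- contact$residue
    atom_name <- if (is.null(contact$atom)) "CB" else contact$atom
    row <- which(prot$resno == res_no & prot$atom == atom_name)
    if (length(row) != 1)
      stop("no unique protein atom ", atom_name, " in residue ", res_no)
    prot[row, c("x", "y", "z")] <- as.list(target)
    planted_rows <- c(planted_rows, row)
    planted_xyz <- rbind(planted_xyz, target)
  }
  atoms <- rbind(dna$atoms, prot)
  if (length(planted_rows)) {
    # planted atoms must not sit on top of any other atom
    xyz <- coords(atoms)
    d2 <- cross_dist2(coords(prot[planted_rows, , drop = FALSE]), xyz)
    d2[d2 < 1e-12] <- Inf                    # self
    if (min(d2) < 1.5^2)
      stop("infeasible planting: planted atom within 1.5 A of another atom")
  }
  as_complex(atoms, resolution = resolution, method = method)
}

# Default filter-satisfying contacts: CBs of the first residues planted
# 4.2 A radially off backbone phosphates at spread duplex positions.
default_backbone_contacts <- function(n = 5, L) {
  positions <- ((seq_len(n) - 1L) %% (L - 1L)) + 2L  # avoid 5'-terminal
  lapply(seq_len(n), function(k)
    list(residue = k + 1L, atom = "CB", position = positions[k],
         dna_atom = "P", strand = if (k %% 2) "ref" else "partner",
         distance = 4.2, mode = "radial"))
}

#' Generate a corpus of complexes with a planted base preference
#'
#' Each complex pairs a random-sequence idealized duplex (with the
#' preferred base fixed at the planted position) with a poly-alanine
#' protein whose probe CB atom sits in the major groove of the planted
#' position, 3.4 A off the base's groove edge; five further CB atoms touch
#' backbone phosphates at sequence-neutral positions so the complex passes
#' the knowledgebase selection filters.  A knowledgebase accumulated from
#' such a corpus encodes short-range enrichment only for the preferred
#' base's atom types, so threading a held-out complex built the same way
#' should recover the preference.
#'
#' @param n number of complexes.
#' @param preference planted base (`"A"`, `"C"`, `"G"` or `"T"`).
#' @param seed integer seed; the corpus is deterministic given it.
#' @param length duplex length (default 8).
#' @param planted_position duplex position carrying the preference
#'   (default 4).
#' @return List of `n` `complex` objects.
#' @export
make_planted_kb_corpus <- function(n, preference = "G", seed = 1,
                                   length = 8, planted_position = 4) {
  preference <- toupper(preference)
  stopifnot(n >= 1, preference %in% c("A", "C", "G", "T"),
            planted_position >= 1, planted_position <= length)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n))
  lapply(seq_len(n), function(k)
    make_planted_complex(preference, seed = seeds[k], length = length,
                         planted_position = planted_position))
}

#' @rdname make_planted_kb_corpus
#' @param probe_distance distance of the probe CB from the groove edge.
#' @export
make_planted_complex <- function(preference = "G", seed = 1, length = 8,
                                 planted_position = 4,
                                 probe_distance = 3.4) {
  bases <- c("A", "C", "G", "T")
  seqc <- with_seed(seed, sample(bases, length, replace = TRUE))
  seqc[planted_position] <- toupper(preference)
  contacts <- c(
    default_backbone_contacts(5, length),
    list(list(residue = 12L, atom = "CB", position = planted_position,
              strand = "ref", distance = probe_distance,
              mode = "groove")))
  make_toy_complex(paste(seqc, collapse = ""), protein_size = 45,
                   planted_contacts = contacts, seed = seed)
}
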