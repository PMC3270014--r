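#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# Complex: a parsed macromolecular structure
# ---------------------------------------------------------------------------

#' Construct a Complex from an atom table
#'
#' A `Complex` is the package's container for a structure: a heavy-atom
#' table partitioned into chains, each chain classified as protein, DNA or
#' other by its residue composition, plus optional experimental metadata.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z` and optionally `occupancy`.
#'   Nomenclature is normalized and hydrogens are dropped.
#' @param resolution numeric resolution in Angstrom, or `NA`.
#' @param method experimental method string (e.g. `"X-RAY DIFFRACTION"`),
#'   or `NA`.
#' @param model_index which model the atoms came from (bookkeeping only).
#' @return Object of class `complex`.
#' @export
as_complex <- function(atoms, resolution = NA_real_, method = NA_character_,
                       model_index = 1L) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (!nrow(atoms)) stop("empty structure: no atoms")
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  nm <- normalize_nomenclature(atoms$resname, atoms$atom)
  atoms$resname <- nm$residue_name
  atoms$atom <- nm$atom_name
  atoms$element <- trimws(atoms$element)
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank))
    atoms$element[blank] <- substring(gsub("[0-9']", "", atoms$atom[blank]),
                                      1, 1)
  atoms <- atoms[toupper(atoms$element) != "H" &
                 toupper(atoms$element) != "D", , drop = FALSE]
  if (!nrow(atoms)) stop("empty structure: only hydrogens present")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms,
         chain_kind = classify_chains(atoms),
         resolution = as.numeric(resolution),
         method = as.character(method),
         model_index = as.integer(model_index)),
    class = "complex")
}

# Chain kind by residue composition: all-DNA residues -> dna, majority
# standard amino acids -> protein, anything else -> other.
classify_chains <- function(atoms) {
  res <- unique(atoms[, c("chain", "resno", "resname")])
  vapply(split(res$resname, res$chain), function(rn) {
    if (all(is_dna_residue(rn))) "dna"
    else if (mean(is_protein_residue(rn)) > 0.5) "protein"
    else "other"
  }, character(1))
}

#' @export
print.complex <- function(x, ...) {
  kinds <- table(factor(x$chain_kind, c("protein", "dna", "other")))
  cat(sprintf(
    "<complex> %d heavy atoms, %d chains (%d protein, %d dna, %d other)\n",
    nrow(x$atoms), length(x$chain_kind), kinds["protein"], kinds["dna"],
    kinds["other"]))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution %.2f A (%s)\n", x$resolution,
                ifelse(is.na(x$method), "method unknown", x$method)))
  invisible(x)
}

chain_ids <- function(cx, kind) names(cx$chain_kind)[cx$chain_kind == kind]

# Atom subsets by polymer kind.
atoms_of_kind <- function(cx, kind) {
  cx$atoms[cx$atoms$chain %in% chain_ids(cx, kind), , drop = FALSE]
}

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Squared cross-distances between the rows of two coordinate matrices.
# Computed per coordinate (not via the crossprod expansion) so distances
# constructed to sit exactly on a bin edge bin exactly.
cross_dist2 <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2
  d2 <- d2 + outer(a[, 2], b[, 2], "-")^2
  d2 + outer(a[, 3], b[, 3], "-")^2
}

# ---------------------------------------------------------------------------
# PDB reading / writing (format handling via bio3d)
# ---------------------------------------------------------------------------

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), keeps heavy atoms of the
#' selected model only, resolves alternate locations to the highest
#' occupancy (ties: first in file order), and reads resolution/method from
#' the header when present.
#'
#' @param pdb PDB-format text (single string or character vector of lines),
#'   or a path to a `.pdb` file.
#' @param model_index model to extract from multi-model files (default 1).
#' @return A [as_complex()] object.
#' @export
read_structure <- function(pdb, model_index = 1L) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb) || !file.exists(pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(if (length(pdb) == 1) strsplit(pdb, "\n")[[1]] else pdb, path)
  }
  header <- tryCatch(readLines(path, n = 2000), error = function(e) character())
  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  at <- parsed$atom
  if (is.null(at) || !nrow(at)) stop("empty structure: no ATOM records")
  n_models <- nrow(parsed$xyz)
  if (model_index < 1 || model_index > n_models)
    stop("model_index ", model_index, " out of range (", n_models, " models)")
  xyz <- matrix(parsed$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest occupancy per (chain, resno, insert, atom)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, at$resid, sep = "|")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                      atom = at$elety, element = at$elesy,
                      x = at$x, y = at$y, z = at$z, occupancy = at$o,
                      stringsAsFactors = FALSE)
  unknown <- unique(atoms$resname[!is_dna_residue(atoms$resname) &
                                  !is_protein_residue(atoms$resname)])
  if (length(unknown))
    message("retaining non-standard residues as kind 'other': ",
            paste(utils::head(unknown, 10), collapse = ", "))
  as_complex(atoms,
             resolution = parse_resolution(header),
             method = parse_method(header),
             model_index = model_index)
}

parse_resolution <- function(lines) {
  hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  m <- regmatches(hit[1],
                  regexpr("[0-9]+\\.?[0-9]*(?=[ ]*ANGSTROM)", hit[1],
                          perl = TRUE))
  if (!length(m)) NA_real_ else as.numeric(m)
}

parse_method <- function(lines) {
  hit <- grep("^EXPDTA", lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub("^EXPDTA\\s*", "", hit[1]))
}

#' Write a Complex as a PDB file
#'
#' Emits standard ATOM records (fixed-width columns via \pkg{bio3d}) plus
#' minimal EXPDTA / REMARK 2 header lines when metadata is present, so the
#' file round-trips through [read_structure()].
#'
#' @param cx a `complex`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(cx, file) {
  stopifnot(inherits(cx, "complex"))
  a <- cx$atoms
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(coords(a))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   chain = a$chain, o = a$occupancy, b = rep(0, nrow(a)),
                   elesy = a$element)
  body <- readLines(tmp); unlink(tmp)
  header <- character()
  if (!is.na(cx$method))
    header <- c(header, sprintf("EXPDTA    %s", cx$method))
  if (!is.na(cx$resolution))
    header <- c(header,
                sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                        cx$resolution))
  writeLines(c(header, body), file)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Watson-Crick duplex detection
# ---------------------------------------------------------------------------

#' Detect the Watson-Crick duplex in a complex
#'
#' Pairs DNA residues that are Watson-Crick complementary (A-T, G-C) and
#' whose purine N1 to pyrimidine N3 distance is at most `max_n1n3` (a pure
#' distance criterion, adequate for near-ideal duplexes; no angle test).
#' Pairing is greedy by increasing N1-N3 distance with each residue used at
#' most once.
#'
#' @param cx a `complex` with at least one DNA chain.
#' @param reference_strand chain id of the strand whose 5'→3' direction
#'   orders the positions; default: lexicographically first DNA chain.
#' @param max_n1n3 distance cutoff in Angstrom (default 3.5).
#' @return Object of class `duplex_info`: `pairs` (data frame, one row per
#'   base pair ordered along the reference strand), `n_paired`,
#'   `n_unpaired`, `reference_strand`.
#' @export
detect_duplex <- function(cx, reference_strand = NULL, max_n1n3 = 3.5) {
  stopifnot(inherits(cx, "complex"))
  dna_chains <- chain_ids(cx, "dna")
  if (!length(dna_chains)) stop("complex contains no DNA chain")
  if (is.null(reference_strand)) reference_strand <- sort(dna_chains)[1]
  if (!reference_strand %in% dna_chains)
    stop("reference_strand ", reference_strand, " is not a DNA chain")
  da <- atoms_of_kind(cx, "dna")
  res <- unique(da[, c("chain", "resno", "resname")])
  res$key <- paste(res$chain, res$resno)
  glyc_n <- function(rows, name) {
    sel <- da[paste(da$chain, da$resno) %in% rows$key & da$atom == name, ,
              drop = FALSE]
    sel <- sel[match(rows$key, paste(sel$chain, sel$resno)), , drop = FALSE]
    coords(sel)
  }
  pu <- res[is_purine_residue(res$resname), , drop = FALSE]
  py <- res[res$resname %in% c("DC", "DT"), , drop = FALSE]
  pairs <- data.frame()
  if (nrow(pu) && nrow(py)) {
    d2 <- cross_dist2(glyc_n(pu, "N1"), glyc_n(py, "N3"))
    comp <- outer(pu$resname, py$resname,
                  function(a, b) wc_complement(a) == b)
    cand <- which(comp & !is.na(d2) & d2 <= max_n1n3^2, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d2[cand]), , drop = FALSE]
      used_pu <- used_py <- logical(0)
      keep <- logical(nrow(cand))
      taken_pu <- rep(FALSE, nrow(pu)); taken_py <- rep(FALSE, nrow(py))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!taken_pu[i] && !taken_py[j]) {
          taken_pu[i] <- taken_py[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(
        chain1 = pu$chain[cand[, 1]], resno1 = pu$resno[cand[, 1]],
        resname1 = pu$resname[cand[, 1]],
        chain2 = py$chain[cand[, 2]], resno2 = py$resno[cand[, 2]],
        resname2 = py$resname[cand[, 2]], stringsAsFactors = FALSE)
      # put the reference-strand residue in slot 1 where possible
      swap <- pairs$chain1 != reference_strand &
              pairs$chain2 == reference_strand
      if (any(swap)) {
        tmp <- pairs[swap, c("chain1", "resno1", "resname1")]
        pairs[swap, c("chain1", "resno1", "resname1")] <-
          pairs[swap, c("chain2", "resno2", "resname2")]
        pairs[swap, c("chain2", "resno2", "resname2")] <- tmp
      }
      on_ref <- pairs$chain1 == reference_strand
      pairs <- rbind(pairs[on_ref, ][order(pairs$resno1[on_ref]), ],
                     pairs[!on_ref, ])
      rownames(pairs) <- NULL
    }
  }
  n_paired <- nrow(pairs)
  structure(
    list(pairs = pairs, n_paired = n_paired,
         n_unpaired = nrow(res) - 2L * n_paired,
         reference_strand = reference_strand),
    class = "duplex_info")
}

#' @export
print.duplex_info <- function(x, ...) {
  cat(sprintf("<duplex_info> %d paired, %d unpaired (reference strand %s)\n",
              x$n_paired, x$n_unpaired, x$reference_strand))
  if (x$n_paired) {
    seq1 <- paste(substring(x$pairs$resname1, 2), collapse = "")
    cat("  reference-strand sequence: ", seq1, "\n", sep = "")
  }
  invisible(x)
}

# Distinct duplex segments: unordered chain pairs carrying >= 2 base pairs.
# Used to operationalize the "exactly one double-stranded DNA" filter.
duplex_segments <- function(duplex) {
  if (!duplex$n_paired) return(character(0))
  key <- apply(duplex$pairs[, c("chain1", "chain2")], 1,
               function(r) paste(sort(r), collapse = "~"))
  names(which(table(key) >= 2))
}

# ---------------------------------------------------------------------------
# Contacts and selection filters
# ---------------------------------------------------------------------------

#' Protein residues in contact with DNA
#'
#' A protein residue is a contact residue when any of its heavy atoms lies
#' within `cutoff` of any DNA heavy atom.
#'
#' @param cx a `complex`.
#' @param cutoff distance in Angstrom (default 4.5).
#' @return Data frame `chain`, `resno`, `resname`, one row per contact
#'   residue (possibly empty).
#' @export
contact_residues <- function(cx, cutoff = 4.5) {
  stopifnot(inherits(cx, "complex"), cutoff > 0)
  pa <- atoms_of_kind(cx, "protein")
  da <- atoms_of_kind(cx, "dna")
  empty <- data.frame(chain = character(), resno = integer(),
                      resname = character(), stringsAsFactors = FALSE)
  if (!nrow(pa) || !nrow(da)) return(empty)
  d2 <- cross_dist2(coords(pa), coords(da))
  near <- apply(d2 <= cutoff^2, 1, any)
  if (!any(near)) return(empty)
  out <- unique(pa[near, c("chain", "resno", "resname")])
  rownames(out) <- NULL
  out
}

#' Complex-selection filter profiles
#'
#' Two presets mirror the structure-selection rules used when (a) building
#' the contact knowledgebase and (b) qualifying a template complex:
#' X-ray structure with resolution better than 3.0 A, at least 6 paired
#' bases with under 30% of DNA residues unpaired, a protein chain with at
#' least 5 contact residues (4.5 A), and a protein chain of at least 40
#' residues.  The knowledgebase profile additionally requires exactly one
#' double-stranded DNA.
#'
#' @param name `"knowledgebase"` or `"template"`.
#' @return A `filter_profile` list of thresholds.
#' @export
filter_profile <- function(name = c("knowledgebase", "template")) {
  name <- match.arg(name)
  structure(
    list(name = name,
         max_resolution = 3.0,
         require_xray = TRUE,
         require_single_dsdna = (name == "knowledgebase"),
         min_paired_bases = 6L,
         max_unpaired_fraction = 0.30,
         min_contact_residues = 5L,
         contact_cutoff = 4.5,
         min_chain_length = 40L),
    class = "filter_profile")
}

#' Apply a selection filter profile to a complex
#'
#' Evaluates every criterion of the profile and reports all failures.
#' The X-ray requirement is checked against header metadata; structures
#' with no recorded method are rejected when `profile$require_xray` is set.
#'
#' @param cx a `complex`.
#' @param profile a [filter_profile()].
#' @return List with `pass` (logical) and `failures` (character vector of
#'   criterion names that failed).
#' @export
passes_filters <- function(cx, profile = filter_profile("knowledgebase")) {
  stopifnot(inherits(cx, "complex"))
  fail <- character()
  is_xray <- !is.na(cx$method) && grepl("X-?RAY", toupper(cx$method))
  if (profile$require_xray && !is_xray) fail <- c(fail, "method")
  if (is.na(cx$resolution) || cx$resolution >= profile$max_resolution)
    fail <- c(fail, "resolution")
  dna_chains <- chain_ids(cx, "dna")
  if (!length(dna_chains)) {
    fail <- c(fail, "no_dna")
  } else {
    duplex <- detect_duplex(cx)
    if (profile$require_single_dsdna &&
        length(duplex_segments(duplex)) != 1)
      fail <- c(fail, "single_dsdna")
    if (duplex$n_paired < profile$min_paired_bases)
      fail <- c(fail, "min_paired_bases")
    n_dna_res <- 2L * duplex$n_paired + duplex$n_unpaired
    if (n_dna_res == 0 ||
        duplex$n_unpaired / n_dna_res >= profile$max_unpaired_fraction)
      fail <- c(fail, "max_unpaired_fraction")
  }
  prot_chains <- chain_ids(cx, "protein")
  if (!length(prot_chains)) {
    fail <- c(fail, "no_protein")
  } else {
    cr <- contact_residues(cx, profile$contact_cutoff)
    per_chain <- table(factor(cr$chain, levels = prot_chains))
    if (!any(per_chain >= profile$min_contact_residues))
      fail <- c(fail, "min_contact_residues")
    pa <- atoms_of_kind(cx, "protein")
    lens <- vapply(split(pa$resno, pa$chain),
                   function(r) length(unique(r)), integer(1))
    if (!any(lens >= profile$min_chain_length))
      fail <- c(fail, "min_chain_length")
  }
  list(pass = length(fail) == 0L, failures = fail)
}
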