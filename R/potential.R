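# ---------------------------------------------------------------------------
# Knowledge-based pair potential (inverse-Boltzmann, r^alpha reference state)
# ---------------------------------------------------------------------------

#' Parameters of the pair potential and PWM emission
#'
#' @param alpha exponent of the `r^alpha` reference state (default 1.61).
#' @param r_cut interaction cutoff in Angstrom; fixed at 10, the upper edge
#'   of the last distance bin.
#' @param pseudocount additive per-bin count `delta` applied before
#'   normalizing observed distributions (default 0.1; 0 allowed, in which
#'   case all-zero pairs are uninformative and score 0).
#' @param weighting distance weighting of the observed counts: `"none"`
#'   (plain log-ratio potential) or `"power"` with exponent `gamma`, i.e.
#'   `w(r) = (r / r_cut)^gamma` applied to the bin counts before
#'   normalization.
#' @param gamma exponent of the power weighting (ignored for `"none"`).
#' @param beta temperature-like divisor converting per-base free energies
#'   to PWM column probabilities (default 15).
#' @return A `potential_params` list.
#' @export
potential_params <- function(alpha = 1.61, r_cut = 10, pseudocount = 0.1,
                             weighting = c("none", "power"), gamma = 1,
                             beta = 15) {
  weighting <- match.arg(weighting)
  stopifnot(alpha >= 0, identical(as.numeric(r_cut), 10), pseudocount >= 0,
            beta > 0)
  structure(list(alpha = alpha, r_cut = r_cut, pseudocount = pseudocount,
                 weighting = weighting, gamma = gamma, beta = beta),
            class = "potential_params")
}

#' Reference-state probability of a distance bin
#'
#' `P_ref(r) = r^alpha * dr(r) / sum_r' r'^alpha * dr(r')` over the eight
#' bins `r = 3..10` with widths 3, 1, 1, ..., 1.
#'
#' @param r bin label(s) in `3:10`.
#' @param params a [potential_params()].
#' @return Probabilities; they sum to 1 over all bins.
#' @export
reference_probability <- function(r, params = potential_params()) {
  if (!all(r %in% .kb_bins)) stop("invalid distance bin: ",
                                  paste(setdiff(r, .kb_bins), collapse = ","))
  w <- .kb_bins^params$alpha * .kb_bin_width
  (r^params$alpha * .kb_bin_width[match(r, .kb_bins)]) / sum(w)
}

# Observed bin distribution for one (i, j) pair given its 8 raw counts.
# Returns NULL for an uninformative pair (all-zero counts with delta = 0).
observed_distribution <- function(counts, params) {
  stopifnot(length(counts) == length(.kb_bins))
  n <- counts + params$pseudocount
  if (params$weighting == "power")
    n <- n * (.kb_bins / .kb_rcut)^params$gamma
  tot <- sum(n)
  if (tot <= 0) return(NULL)
  n / tot
}

#' Observed contact probability of a type pair in a distance bin
#'
#' `P(i, j, r)` is the pseudocounted, optionally distance-weighted fraction
#' of the pair's contacts falling in bin `r` (normalized over bins so the
#' eight probabilities sum to 1).
#'
#' @param kb a `knowledgebase`.
#' @param i protein atom type (e.g. `"ARG.NH1"`).
#' @param j DNA atom type (e.g. `"DG.N7"`).
#' @param r bin label in `3:10`.
#' @param params a [potential_params()].
#' @return Probability, or `NA` for an uninformative pair (no counts and
#'   `pseudocount = 0`).
#' @export
observed_probability <- function(kb, i, j, r, params = potential_params()) {
  stopifnot(inherits(kb, "knowledgebase"), r %in% .kb_bins)
  p <- observed_distribution(kb$counts[i, j, ], params)
  if (is.null(p)) return(NA_real_)
  unname(p[as.character(r)])
}

#' Pair potential for one type pair and bin
#'
#' `u(i, j, r) = -ln(P(i, j, r) / P_ref(r))` for `r <= r_cut`; pairs whose
#' total observed count is zero (with `pseudocount = 0`) are uninformative
#' and score 0, as do separations beyond the cutoff.
#'
#' @inheritParams observed_probability
#' @return Dimensionless energy.
#' @export
pair_potential <- function(kb, i, j, r, params = potential_params()) {
  stopifnot(inherits(kb, "knowledgebase"), r %in% .kb_bins)
  counts <- kb$counts[i, j, ]
  if (sum(counts) == 0 && params$pseudocount == 0) return(0)
  p <- observed_distribution(counts, params)
  u <- -log(p / reference_probability(.kb_bins, params))
  unname(u[as.character(r)])
}

#' Derive the full potential table from a knowledgebase
#'
#' Vectorized evaluation of [pair_potential()] over the whole
#' `(protein type, DNA type, bin)` grid.  Pairs with zero total counts are
#' identically zero when `pseudocount = 0`; with a positive pseudocount
#' they follow the pseudocount-only (flat) distribution.
#'
#' @param kb a `knowledgebase`.
#' @param params a [potential_params()].
#' @return Object of class `pair_potential_table`: `u` (167 x 82 x 8 array),
#'   `params`, `source` (knowledgebase provenance summary).
#' @export
derive_potential <- function(kb, params = potential_params()) {
  stopifnot(inherits(kb, "knowledgebase"))
  counts <- kb$counts
  n <- counts + params$pseudocount
  if (params$weighting == "power") {
    wr <- (.kb_bins / .kb_rcut)^params$gamma
    n <- sweep(n, 3, wr, "*")
  }
  tot <- rowSums(n, dims = 2)
  pref <- reference_probability(.kb_bins, params)
  u <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  informative <- tot > 0
  for (k in seq_along(.kb_bins)) {
    uk <- -log((n[, , k] / tot) / pref[k])
    uk[!informative] <- 0
    u[, , k] <- uk
  }
  if (params$pseudocount == 0 && any(is.infinite(u))) {
    # with no pseudocount an empty bin of an informative pair is -ln(0);
    # clamp to the strongest finite repulsion so energies stay usable
    finite_max <- max(u[is.finite(u)], 0)
    u[is.infinite(u)] <- finite_max
  }
  structure(
    list(u = u, params = params,
         source = sprintf("%d complexes / %d chains (%s profile)",
                          kb$n_complexes, kb$n_protein_chains,
                          kb$profile$name)),
    class = "pair_potential_table")
}

#' @export
print.pair_potential_table <- function(x, ...) {
  cat(sprintf(
    "<pair_potential_table> alpha=%.2f, pseudocount=%g, weighting=%s; %s\n",
    x$params$alpha, x$params$pseudocount, x$params$weighting, x$source))
  invisible(x)
}

#' Export / import a potential table as TSV
#'
#' Rows are `protein_type TAB dna_type TAB bin TAB u` with 9 significant
#' digits; the parameter block is serialized in `#`-prefixed headers.
#'
#' @param pot a `pair_potential_table`.
#' @param file path.
#' @export
save_potential <- function(pot, file) {
  stopifnot(inherits(pot, "pair_potential_table"))
  nz <- which(pot$u != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2], nz[, 3]), , drop = FALSE]
  dn <- dimnames(pot$u)
  p <- pot$params
  header <- c(
    "#format\tpwmthread-potential 1",
    sprintf("#alpha\t%g", p$alpha),
    sprintf("#pseudocount\t%g", p$pseudocount),
    sprintf("#weighting\t%s", p$weighting),
    sprintf("#gamma\t%g", p$gamma),
    sprintf("#beta\t%g", p$beta),
    paste0("#source\t", pot$source))
  rows <- sprintf("%s\t%s\t%s\t%.9g", dn[[1]][nz[, 1]], dn[[2]][nz[, 2]],
                  dn[[3]][nz[, 3]], pot$u[nz])
  writeLines(c(header, rows), file)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Binding free energy of a complex (sum over contacting atom pairs)
# ---------------------------------------------------------------------------

#' Binding free energy of a protein-DNA complex
#'
#' Sums the pair potential over every typed protein/DNA heavy-atom pair
#' within the 10 A cutoff (the whole-complex analogue of the per-position
#' energies used for threading).
#'
#' @param cx a `complex`.
#' @param pot a [derive_potential()] table.
#' @return Scalar dimensionless energy (0 when no pair is within range).
#' @export
binding_free_energy <- function(cx, pot) {
  stopifnot(inherits(cx, "complex"), inherits(pot, "pair_potential_table"))
  pa <- atoms_of_kind(cx, "protein")
  da <- atoms_of_kind(cx, "dna")
  if (!nrow(pa) || !nrow(da)) return(0)
  pair_energy_kernel(pa, da, pot)$energy
}

# Shared kernel: energy sum (and in-range pair count) between two typed
# atom tables.
pair_energy_kernel <- function(pa, da, pot) {
  none <- list(energy = 0, n_pairs = 0L)
  pt <- assign_type(pa$resname, pa$atom)
  dt <- assign_type(da$resname, da$atom)
  pa <- pa[!is.na(pt), , drop = FALSE]; pt <- pt[!is.na(pt)]
  da <- da[!is.na(dt), , drop = FALSE]; dt <- dt[!is.na(dt)]
  if (!nrow(pa) || !nrow(da)) return(none)
  d2 <- cross_dist2(coords(pa), coords(da))
  hit <- which(d2 <= .kb_rcut^2, arr.ind = TRUE)
  if (!nrow(hit)) return(none)
  bin <- distance_bin(sqrt(d2[hit]))
  ok <- !is.na(bin)
  if (!any(ok)) return(none)
  dn <- dimnames(pot$u)
  idx <- cbind(match(pt[hit[ok, 1]], dn[[1]]),
               match(dt[hit[ok, 2]], dn[[2]]),
               match(as.character(bin[ok]), dn[[3]]))
  list(energy = sum(pot$u[idx]), n_pairs = sum(ok))
}
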