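# ---------------------------------------------------------------------------
# Distance bins
# ---------------------------------------------------------------------------

# Bin labels r = 3..10 A with widths Delta r = 3 for r = 3 and 1 otherwise;
# a distance d falls in the unique bin (r - Delta r, r].
.kb_bins <- 3:10
.kb_bin_width <- c(3, rep(1, 7))
.kb_rcut <- 10

#' Distance bin of an atom-pair separation
#'
#' Bins are labelled by their upper edge `r` in `3:10` Angstrom, with width
#' 3 for the first bin and 1 for the rest, interval convention
#' `(r - dr, r]`.  Distances beyond 10 A (and non-positive values) map to
#' `NA`.
#'
#' @param d numeric vector of distances in Angstrom.
#' @return Integer vector of bin labels in `3:10`, or `NA`.
#' @examples
#' distance_bin(c(3, 3.5, 4, 10, 10.5))  # 3 4 4 10 NA
#' @export
distance_bin <- function(d) {
  r <- pmax(3, ceiling(d))
  r[d > .kb_rcut | d <= 0] <- NA_integer_
  as.integer(r)
}

# ---------------------------------------------------------------------------
# Pair counting
# ---------------------------------------------------------------------------

#' Count typed protein-DNA atom pairs of a complex
#'
#' Every (protein heavy atom, DNA heavy atom) pair with separation at most
#' 10 A is counted exactly once in its distance bin; intra-protein and
#' intra-DNA pairs never contribute.  Atoms outside the 167+82 type
#' vocabulary are skipped and tallied in the `skipped` attribute.
#'
#' @param cx a `complex` with at least one protein and one DNA chain.
#' @return Data frame `protein_type`, `dna_type`, `bin`, `count` (sparse:
#'   only observed combinations), with attribute `skipped` giving the
#'   number of untyped protein/DNA atoms.
#' @export
count_pairs <- function(cx) {
  stopifnot(inherits(cx, "complex"))
  pa <- atoms_of_kind(cx, "protein")
  da <- atoms_of_kind(cx, "dna")
  if (!nrow(pa) || !nrow(da))
    stop("count_pairs needs both protein and DNA chains")
  pt <- assign_type(pa$resname, pa$atom)
  dt <- assign_type(da$resname, da$atom)
  skipped <- c(protein = sum(is.na(pt)), dna = sum(is.na(dt)))
  pa <- pa[!is.na(pt), , drop = FALSE]; pt <- pt[!is.na(pt)]
  da <- da[!is.na(dt), , drop = FALSE]; dt <- dt[!is.na(dt)]
  out <- data.frame(protein_type = character(), dna_type = character(),
                    bin = integer(), count = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(pa) && nrow(da)) {
    d2 <- cross_dist2(coords(pa), coords(da))
    hit <- which(d2 <= .kb_rcut^2, arr.ind = TRUE)
    if (nrow(hit)) {
      bin <- distance_bin(sqrt(d2[hit]))
      ok <- !is.na(bin)
      key <- paste(pt[hit[ok, 1]], dt[hit[ok, 2]], bin[ok], sep = "\r")
      tab <- table(key)
      parts <- strsplit(names(tab), "\r", fixed = TRUE)
      out <- data.frame(
        protein_type = vapply(parts, `[`, "", 1),
        dna_type = vapply(parts, `[`, "", 2),
        bin = as.integer(vapply(parts, `[`, "", 3)),
        count = as.integer(tab), stringsAsFactors = FALSE)
      out <- out[order(out$protein_type, out$dna_type, out$bin), ]
      rownames(out) <- NULL
    }
  }
  attr(out, "skipped") <- skipped
  out
}

# ---------------------------------------------------------------------------
# Knowledgebase
# ---------------------------------------------------------------------------

empty_kb_counts <- function() {
  array(0L,
        dim = c(167L, 82L, length(.kb_bins)),
        dimnames = list(atom_type_vocabulary("protein"),
                        atom_type_vocabulary("dna"),
                        as.character(.kb_bins)))
}

#' Accumulate a contact knowledgebase from filtered complexes
#'
#' Applies the selection profile to every input complex (rejections are
#' reported with their failure reasons), then accumulates the distance-
#' binned pair counts of the survivors into the `N_obs(i, j, r)` tensor.
#' All chains of a surviving complex contribute pairs.
#'
#' @param complexes list of `complex` objects.
#' @param profile a [filter_profile()]; use
#'   `filter_profile("knowledgebase")` (default) to reproduce the standard
#'   selection rules.
#' @param provenance free-text note stored with the counts.
#' @return Object of class `knowledgebase`: `counts` (167 x 82 x 8 integer
#'   array), `n_complexes`, `n_protein_chains`, `profile`, `provenance`,
#'   `rejections`.
#' @export
build_knowledgebase <- function(complexes,
                                profile = filter_profile("knowledgebase"),
                                provenance = "") {
  stopifnot(is.list(complexes))
  counts <- empty_kb_counts()
  n_complexes <- 0L; n_chains <- 0L
  rejections <- list()
  for (k in seq_along(complexes)) {
    cx <- complexes[[k]]
    verdict <- passes_filters(cx, profile)
    if (!verdict$pass) {
      rejections[[length(rejections) + 1L]] <-
        list(index = k, failures = verdict$failures)
      next
    }
    inc <- count_pairs(cx)
    if (nrow(inc)) {
      idx <- cbind(match(inc$protein_type, dimnames(counts)[[1]]),
                   match(inc$dna_type, dimnames(counts)[[2]]),
                   match(as.character(inc$bin), dimnames(counts)[[3]]))
      counts[idx] <- counts[idx] + inc$count
    }
    n_complexes <- n_complexes + 1L
    n_chains <- n_chains + length(chain_ids(cx, "protein"))
  }
  if (length(rejections))
    message(length(rejections), " complex(es) rejected by the '",
            profile$name, "' profile")
  if (n_complexes == 0L)
    stop("no complex passed the selection filters; refusing to build an ",
         "empty knowledgebase")
  structure(
    list(counts = counts, n_complexes = n_complexes,
         n_protein_chains = n_chains, profile = profile,
         provenance = provenance, rejections = rejections),
    class = "knowledgebase")
}

#' @export
print.knowledgebase <- function(x, ...) {
  cat(sprintf(
    "<knowledgebase> %s pairs from %d complexes (%d protein chains)\n",
    format(sum(x$counts), big.mark = ","), x$n_complexes,
    x$n_protein_chains))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization (plain TSV, bit-exact integer counts)
# ---------------------------------------------------------------------------

.kb_format <- "pwmthread-kb 1"

#' Save / load a knowledgebase as TSV
#'
#' The file carries `#`-prefixed header lines (format version, complex and
#' chain counts, profile name, a simple checksum) followed by one
#' `protein_type TAB dna_type TAB bin TAB count` row per nonzero cell.
#' `load_kb()` refuses files with an unknown format version, a failing
#' checksum (e.g. truncation), or atom-type labels outside the vocabulary.
#'
#' @param kb a `knowledgebase`.
#' @param file path.
#' @return `save_kb` returns `file` invisibly; `load_kb` returns the
#'   reconstructed `knowledgebase`.
#' @export
save_kb <- function(kb, file) {
  stopifnot(inherits(kb, "knowledgebase"))
  nz <- which(kb$counts != 0, arr.ind = TRUE)
  dn <- dimnames(kb$counts)
  rows <- if (nrow(nz)) {
    nz <- nz[order(nz[, 1], nz[, 2], nz[, 3]), , drop = FALSE]
    sprintf("%s\t%s\t%s\t%d", dn[[1]][nz[, 1]], dn[[2]][nz[, 2]],
            dn[[3]][nz[, 3]], kb$counts[nz])
  } else character()
  header <- c(
    paste0("#format\t", .kb_format),
    paste0("#n_complexes\t", kb$n_complexes),
    paste0("#n_protein_chains\t", kb$n_protein_chains),
    paste0("#profile\t", kb$profile$name),
    paste0("#provenance\t", gsub("[\t\n]", " ", kb$provenance)),
    paste0("#checksum\t", sum(kb$counts), "\t", nrow(nz)))
  writeLines(c(header, rows), file)
  invisible(file)
}

#' @rdname save_kb
#' @export
load_kb <- function(file) {
  lines <- readLines(file)
  is_head <- startsWith(lines, "#")
  head_kv <- strsplit(lines[is_head], "\t")
  hv <- function(key) {
    hit <- which(vapply(head_kv, `[`, "", 1) == paste0("#", key))
    if (!length(hit)) stop("knowledgebase file lacks header '", key, "'")
    head_kv[[hit[1]]][-1]
  }
  if (!identical(hv("format")[1], .kb_format))
    stop("unsupported knowledgebase format: ", hv("format")[1])
  counts <- empty_kb_counts()
  body <- lines[!is_head & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t")
    bad <- which(lengths(parts) != 4)
    if (length(bad)) stop("malformed knowledgebase row: ", body[bad[1]])
    m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
    i <- match(m[, 1], dimnames(counts)[[1]])
    j <- match(m[, 2], dimnames(counts)[[2]])
    r <- match(m[, 3], dimnames(counts)[[3]])
    if (anyNA(i)) stop("unknown protein atom type: ", m[which(is.na(i))[1], 1])
    if (anyNA(j)) stop("unknown DNA atom type: ", m[which(is.na(j))[1], 2])
    if (anyNA(r)) stop("unknown distance bin: ", m[which(is.na(r))[1], 3])
    counts[cbind(i, j, r)] <- as.integer(m[, 4])
  }
  chk <- as.numeric(hv("checksum"))
  if (sum(counts) != chk[1] || length(body) != chk[2])
    stop("knowledgebase checksum failure (truncated or edited file?)")
  structure(
    list(counts = counts,
         n_complexes = as.integer(hv("n_complexes")[1]),
         n_protein_chains = as.integer(hv("n_protein_chains")[1]),
         profile = filter_profile(hv("profile")[1]),
         provenance = paste(hv("provenance"), collapse = " "),
         rejections = list()),
    class = "knowledgebase")
}
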