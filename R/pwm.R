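# ---------------------------------------------------------------------------
# Position weight matrices
# ---------------------------------------------------------------------------

#' Construct a position weight matrix
#'
#' An `L x 4` column-stochastic matrix over bases A, C, G, T (one row per
#' position, 5'→3' on the reference strand).  Rows are renormalized; small
#' negative rounding noise is clipped.
#'
#' @param mat numeric `L x 4` matrix (columns A, C, G, T in that order, or
#'   named).
#' @param contacted optional logical vector of per-position contact flags.
#' @param reference_strand optional chain id the orientation refers to.
#' @param beta emission temperature used to produce the matrix, if any.
#' @param name motif identifier used when writing.
#' @return Object of class `pwm` (a matrix with attributes).
#' @export
pwm <- function(mat, contacted = NULL, reference_strand = NA_character_,
                beta = NA_real_, name = "motif") {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("a PWM needs 4 base columns (A, C, G, T)")
  if (!is.null(colnames(mat))) {
    if (!setequal(colnames(mat), c("A", "C", "G", "T")))
      stop("PWM columns must be named A, C, G, T")
    mat <- mat[, c("A", "C", "G", "T"), drop = FALSE]
  } else colnames(mat) <- c("A", "C", "G", "T")
  if (any(mat < -1e-9) || any(!is.finite(mat)))
    stop("PWM entries must be finite and nonnegative")
  mat[mat < 0] <- 0
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("PWM has an all-zero position")
  mat <- mat / rs
  if (is.null(contacted)) contacted <- rep(NA, nrow(mat))
  stopifnot(length(contacted) == nrow(mat))
  structure(mat, class = c("pwm", "matrix"),
            contacted = contacted, reference_strand = reference_strand,
            beta = beta, name = name)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d positions, consensus %s\n", nrow(x), consensus(x)))
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  rownames(m) <- ifelse(is.na(attr(x, "contacted")), seq_len(nrow(x)),
                        ifelse(attr(x, "contacted"),
                               paste0(seq_len(nrow(x)), "*"),
                               as.character(seq_len(nrow(x)))))
  print(round(m, 3))
  if (any(!is.na(attr(x, "contacted"))))
    cat("  (* = position contacted by protein)\n")
  invisible(x)
}

pwm_length <- function(x) nrow(x)

#' Reverse complement of a PWM
#'
#' Reverses the position order and swaps the A/T and C/G columns.
#'
#' @param x a [pwm()].
#' @return The reverse-complement `pwm`.
#' @export
revcomp_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  m <- unclass(x)[rev(seq_len(nrow(x))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  pwm(m, contacted = rev(attr(x, "contacted")),
      reference_strand = attr(x, "reference_strand"),
      beta = attr(x, "beta"), name = attr(x, "name"))
}

.iupac_codes <- c(A = "A", C = "C", G = "G", T = "T",
                  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y",
                  GT = "K", ACG = "V", ACT = "H", AGT = "D", CGT = "B",
                  ACGT = "N")

#' Consensus sequence of a PWM
#'
#' Per-column argmax; ties (within `tol`) produce IUPAC degenerate codes.
#'
#' @param x a [pwm()].
#' @param tol probabilities within `tol` of the maximum count as tied.
#' @return Single consensus string.
#' @export
consensus <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "pwm"))
  paste(apply(unclass(x), 1, function(p) {
    best <- colnames(x)[p >= max(p) - tol]
    .iupac_codes[paste(sort(best), collapse = "")]
  }), collapse = "")
}

# ---------------------------------------------------------------------------
# PWM file formats: plain TSV, TRANSFAC-style block, JASPAR-style PFM
# ---------------------------------------------------------------------------

#' Write a PWM file
#'
#' Formats: `"tsv"` (header `A C G T`, one tab-separated row per position,
#' 6 decimals), `"transfac"` (matrix block with `P0` header, `XX`/`//`
#' terminators), `"jaspar"` (`>name` then one `BASE [ ... ]` row per base).
#'
#' @param x a [pwm()].
#' @param file path.
#' @param format one of `"tsv"`, `"transfac"`, `"jaspar"`.
#' @export
write_pwm <- function(x, file, format = c("tsv", "transfac", "jaspar")) {
  stopifnot(inherits(x, "pwm"))
  format <- match.arg(format)
  m <- unclass(x)
  lines <- switch(format,
    tsv = c(paste(c("A", "C", "G", "T"), collapse = "\t"),
            apply(m, 1, function(p)
              paste(sprintf("%.6f", p), collapse = "\t"))),
    transfac = c(paste0("ID ", attr(x, "name")),
                 paste0("BF ", attr(x, "name")),
                 sprintf("P0%7s%7s%7s%7s", "A", "C", "G", "T"),
                 vapply(seq_len(nrow(m)), function(i)
                   sprintf("%02d %6.4f %6.4f %6.4f %6.4f", i,
                           m[i, 1], m[i, 2], m[i, 3], m[i, 4]),
                   character(1)),
                 "XX", "//"),
    jaspar = c(paste0(">", attr(x, "name")),
               vapply(c("A", "C", "G", "T"), function(b)
                 sprintf("%s  [ %s ]", b,
                         paste(sprintf("%.6f", m[, b]), collapse = "  ")),
                 character(1))))
  writeLines(lines, file)
  invisible(file)
}

#' Read a PWM file
#'
#' Auto-detects the three supported formats (TSV with `A C G T` header,
#' TRANSFAC-style block, JASPAR-style PFM).  Count matrices are normalized
#' to column-stochastic form.
#'
#' @param file path, or the file's text content.
#' @param format `"auto"` (default) or one of `"tsv"`, `"transfac"`,
#'   `"jaspar"`.
#' @return A [pwm()].
#' @export
read_pwm <- function(file, format = c("auto", "tsv", "transfac", "jaspar")) {
  format <- match.arg(format)
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file))
    readLines(file)
  else if (length(file) == 1) strsplit(file, "\n")[[1]]
  else file
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PWM file")
  if (format == "auto") {
    format <- if (any(grepl("^P0", lines))) "transfac"
    else if (startsWith(trimws(lines[1]), ">")) "jaspar"
    else "tsv"
  }
  name <- "motif"
  m <- switch(format,
    tsv = {
      first <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
      body <- if (setequal(toupper(first), c("A", "C", "G", "T")))
        lines[-1] else lines
      vals <- lapply(body, function(l)
        suppressWarnings(as.numeric(strsplit(trimws(l), "[\t ]+")[[1]])))
      if (any(lengths(vals) != 4)) stop("TSV PWM rows must have 4 values")
      mm <- do.call(rbind, vals)
      colnames(mm) <- if (length(first) == 4 &&
                          setequal(toupper(first), c("A", "C", "G", "T")))
        toupper(first) else c("A", "C", "G", "T")
      mm
    },
    transfac = {
      id <- grep("^ID\\s+", lines, value = TRUE)
      if (length(id)) name <- sub("^ID\\s+", "", id[1])
      p0 <- grep("^P0", lines)
      if (!length(p0)) stop("TRANSFAC block lacks a P0 header")
      order_bases <- strsplit(trimws(sub("^P0", "", lines[p0[1]])),
                              "\\s+")[[1]]
      rows <- lines[seq(p0[1] + 1, length(lines))]
      rows <- rows[grepl("^\\s*[0-9]+\\s", rows)]
      mm <- do.call(rbind, lapply(rows, function(l) {
        v <- strsplit(trimws(l), "\\s+")[[1]]
        as.numeric(v[2:5])
      }))
      colnames(mm) <- toupper(substring(order_bases[1:4], 1, 1))
      mm
    },
    jaspar = {
      hdr <- which(startsWith(trimws(lines), ">"))
      if (length(hdr)) name <- sub("^>\\s*", "", trimws(lines[hdr[1]]))
      rows <- grep("^\\s*[ACGT]\\s*\\[", lines, value = TRUE)
      if (length(rows) != 4) stop("JASPAR PFM needs 4 base rows")
      bases <- toupper(substring(trimws(rows), 1, 1))
      vals <- lapply(rows, function(l) {
        inner <- sub("^[^\\[]*\\[", "", sub("\\].*$", "", l))
        as.numeric(strsplit(trimws(inner), "\\s+")[[1]])
      })
      if (length(unique(lengths(vals))) != 1)
        stop("JASPAR PFM rows have unequal lengths")
      mm <- do.call(cbind, vals)
      colnames(mm) <- bases
      mm
    })
  if (anyNA(m)) stop("non-numeric value in PWM file")
  pwm(m, name = name)
}
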