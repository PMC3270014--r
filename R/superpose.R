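# ---------------------------------------------------------------------------
# Rigid transforms and synthetic (superimposed) complex construction
# ---------------------------------------------------------------------------

#' Construct a rigid transform
#'
#' The transform acts as `x' = t + U x` with `U` a proper rotation.
#'
#' @param U 3x3 rotation matrix (orthogonal, det +1, checked to `tol`).
#' @param t length-3 translation in Angstrom.
#' @param tol orthogonality / determinant tolerance (default 1e-6).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(U = diag(3), t = c(0, 0, 0), tol = 1e-6) {
  U <- unname(as.matrix(U)); t <- unname(as.numeric(t))
  stopifnot(all(dim(U) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(U) - diag(3))) > tol)
    stop("U is not orthogonal within tolerance ", tol)
  if (abs(det(U) - 1) > tol)
    stop("U is not a proper rotation (det = ", format(det(U)),
         "); reflections are rejected")
  structure(list(U = U, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> x' = t + U x\n")
  m <- cbind(x$t, x$U)
  dimnames(m) <- list(paste0("  row", 1:3), c("t", "u1", "u2", "u3"))
  print(round(m, 6))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a complex
#'
#' @param x an n x 3 coordinate matrix or a `complex`.
#' @param tf a [rigid_transform()].
#' @param chains for a complex: restrict to these chain ids (default all).
#' @return Transformed object of the same shape/class.
#' @export
apply_transform <- function(x, tf, chains = NULL) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "complex")) {
    sel <- if (is.null(chains)) rep(TRUE, nrow(x$atoms))
           else x$atoms$chain %in% chains
    xyz <- apply_transform(coords(x$atoms[sel, , drop = FALSE]), tf)
    x$atoms[sel, c("x", "y", "z")] <- xyz
    return(x)
  }
  sweep(x %*% t(tf$U), 2, tf$t, "+")
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$U), -as.numeric(t(tf$U) %*% tf$t))
}

# ---------------------------------------------------------------------------
# Rotation-matrix file dialect (as printed by structure-alignment tools)
# ---------------------------------------------------------------------------

#' Parse a structure-alignment rotation-matrix file
#'
#' Accepts the plain-text dialect printed by structure-alignment tools:
#' three data rows `i  t(i)  u(i,1)  u(i,2)  u(i,3)` (any banner or header
#' lines are ignored).  Row `i` supplies `t[i]` and row `i` of `U`, with
#' the convention `x' = t + U x`.
#'
#' @param text file path, single string, or character vector of lines.
#' @return A [rigid_transform()]; non-orthogonal or reflective matrices are
#'   rejected.
#' @export
parse_matrix_file <- function(text) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text)
  else if (length(text) == 1) strsplit(text, "\n")[[1]]
  else text
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  pat <- sprintf("^\\s*([123])\\s+(%s)\\s+(%s)\\s+(%s)\\s+(%s)\\s*$",
                 num, num, num, num)
  hits <- regmatches(lines, regexec(pat, lines))
  hits <- hits[lengths(hits) == 6]
  if (length(hits) != 3)
    stop("expected exactly 3 data rows 'i t u1 u2 u3'; found ",
         length(hits))
  m <- do.call(rbind, lapply(hits, function(h) as.numeric(h[-1])))
  if (!identical(as.integer(m[, 1]), 1:3))
    stop("matrix-file rows must be indexed 1, 2, 3 in order")
  rigid_transform(U = m[, 3:5], t = m[, 2])
}

#' Write a rigid transform in the rotation-matrix file dialect
#'
#' @param tf a [rigid_transform()].
#' @param file path.
#' @export
write_matrix_file <- function(tf, file) {
  stopifnot(inherits(tf, "rigid_transform"))
  lines <- c(
    " -------- rotation matrix to superimpose the query (x' = t + U x) ----",
    " i          t(i)         u(i,1)         u(i,2)         u(i,3)",
    sprintf(" %d %17.10f %14.10f %14.10f %14.10f",
            1:3, tf$t, tf$U[, 1], tf$U[, 2], tf$U[, 3]))
  writeLines(lines, file)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Kabsch least-squares superposition
# ---------------------------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimizing the RMSD of
#' `moving` onto `fixed`, for use when only a residue correspondence (not a
#' precomputed alignment matrix) is available.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, matched rows.
#' @return List with `transform` (a [rigid_transform()]) and `rmsd`.
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3)
    stop("moving and fixed must be matched n x 3 matrices")
  if (nrow(moving) < 3)
    stop("at least 3 point pairs are required (got ", nrow(moving), ")")
  mc <- colMeans(moving); fc <- colMeans(fixed)
  m <- sweep(moving, 2, mc); f <- sweep(fixed, 2, fc)
  if (min(svd(m)$d[2], svd(f)$d[2]) < 1e-8)
    stop("degenerate (collinear) point set")
  sv <- svd(crossprod(m, f))
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tf <- rigid_transform(U, fc - as.numeric(U %*% mc))
  moved <- apply_transform(moving, tf)
  list(transform = tf,
       rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

# ---------------------------------------------------------------------------
# Synthetic complex construction
# ---------------------------------------------------------------------------

#' Build a superimposed (synthetic) protein-DNA complex
#'
#' Removes the template's protein chains, applies the rigid transform to
#' the query, and appends the transformed query protein chains to the
#' template's untouched DNA (and other) chains.  Query chain ids colliding
#' with retained template chains are renamed to unused ids and the mapping
#' is reported in the `chain_map` attribute.
#'
#' @param query a `complex` with at least one protein chain (its
#'   non-protein chains are dropped).
#' @param template a `complex` with at least one DNA chain.
#' @param tf a [rigid_transform()] mapping query coordinates into the
#'   template frame (identity by default).
#' @return The synthetic `complex`; template DNA coordinates are bitwise
#'   those of the template.  A warning is issued when no transformed
#'   protein atom lies within 10 A of the DNA (the prediction would be
#'   uninformative).
#' @export
build_superimposed_complex <- function(query, template,
                                       tf = rigid_transform()) {
  stopifnot(inherits(query, "complex"), inherits(template, "complex"))
  if (!length(chain_ids(template, "dna")))
    stop("template has no DNA chain")
  if (!length(chain_ids(query, "protein")))
    stop("query has no protein chain")
  keep <- template$atoms[!(template$atoms$chain %in%
                           chain_ids(template, "protein")), , drop = FALSE]
  qa <- atoms_of_kind(query, "protein")
  qa[, c("x", "y", "z")] <- apply_transform(coords(qa), tf)
  # resolve chain-id collisions against retained template chains
  free_ids <- setdiff(c(LETTERS, letters, as.character(0:9)),
                      unique(keep$chain))
  chain_map <- list()
  for (ch in unique(qa$chain)) {
    new_id <- if (ch %in% keep$chain) {
      if (!length(free_ids)) stop("no free chain ids left for renaming")
      id <- free_ids[1]; free_ids <- free_ids[-1]; id
    } else ch
    free_ids <- setdiff(free_ids, new_id)
    chain_map[[ch]] <- new_id
  }
  qa$chain <- unlist(chain_map)[qa$chain]
  out <- as_complex(rbind(keep, qa),
                    resolution = template$resolution,
                    method = template$method,
                    model_index = template$model_index)
  dmin2 <- min(cross_dist2(coords(atoms_of_kind(out, "protein")),
                           coords(atoms_of_kind(out, "dna"))))
  if (dmin2 > .kb_rcut^2)
    warning("no query protein atom within ", .kb_rcut,
            " A of the template DNA; the prediction will be uninformative")
  attr(out, "chain_map") <- chain_map
  out
}
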