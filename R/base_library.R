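#' Idealized nucleotide geometry library
#'
#' Heavy-atom coordinates for one idealized conformer of each standard
#' deoxyribonucleotide (DA, DC, DG, DT), shipped as a plain-text table.
#' The library provides the base moieties planted during in-silico base
#' substitution and the rigid building blocks for the idealized B-DNA
#' generator.  Coordinates are synthetic reference geometry, not taken from
#' any crystal structure.
#'
#' @return Named list (`DA`,`DC`,`DG`,`DT`); each element is a data frame
#'   with columns `atom`, `element`, `x`, `y`, `z`.
#' @export
base_library <- function() {
  cached <- .pwmthread_cache$base_library
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "nucleotide_geometry.tsv",
                      package = "pwmthread", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  lib <- split(tab[, c("atom", "element", "x", "y", "z")], tab$resname)
  lib <- lapply(lib, function(d) { rownames(d) <- d$atom; d })
  .pwmthread_cache$base_library <- lib
  lib
}

.pwmthread_cache <- new.env(parent = emptyenv())

# Coordinate matrix (rows named by atom) for one library residue.
lib_coords <- function(resname, atoms = NULL) {
  d <- base_library()[[resname]]
  if (is.null(d)) stop("no library geometry for residue ", resname)
  if (!is.null(atoms)) {
    missing <- setdiff(atoms, d$atom)
    if (length(missing))
      stop("library residue ", resname, " lacks atoms: ",
           paste(missing, collapse = ", "))
    d <- d[atoms, , drop = FALSE]
  }
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$atom
  m
}

base_moiety_atoms <- function(resname) .dna_base_atom_table[[resname]]

# Geometry helpers -----------------------------------------------------------

# Least-squares plane through points (rows); returns unit normal and center.
fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {     # antiparallel: rotate pi about any orthogonal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# In-plane (about z) least-squares rigid fit of 2D point sets.
fit_rigid_xy <- function(moving, target) {
  mc <- colMeans(moving); tc <- colMeans(target)
  m <- sweep(moving, 2, mc); t <- sweep(target, 2, tc)
  # 2D Kabsch via the cross/dot sums; proper rotation only.
  a <- sum(m[, 1] * t[, 1] + m[, 2] * t[, 2])
  b <- sum(m[, 1] * t[, 2] - m[, 2] * t[, 1])
  theta <- atan2(b, a)
  list(theta = theta, moving_center = mc, target_center = tc)
}

apply_rigid_xy <- function(xyz, fit) {
  shifted <- sweep(xyz, 2, c(fit$moving_center, 0))
  rotated <- shifted %*% t(rot_z(fit$theta))
  sweep(rotated, 2, c(fit$target_center, 0), "+")
}

# Watson-Crick pair templates ------------------------------------------------

# Hydrogen-bond atom pairs (purine atom, pyrimidine atom, distance in A)
# used to position the pyrimidine against the fixed purine.
.wc_hbonds <- list(
  DA = data.frame(pu = c("N1", "N6"), py = c("N3", "O4"),
                  d = c(2.82, 2.95)),
  DG = data.frame(pu = c("N1", "O6", "N2"), py = c("N3", "N4", "O2"),
                  d = c(2.88, 2.91, 2.86))
)

# Canonicalize a library nucleotide: base plane -> z = 0, glycosidic N at
# the origin, WC-edge direction (glycosidic N -> N1/N3) along +x, handedness
# fixed so the C8 (purine) or C6 (pyrimidine) side has y of one sign.
canonical_nucleotide <- function(resname) {
  xyz <- lib_coords(resname)
  base_atoms <- base_moiety_atoms(resname)
  pl <- fit_plane(xyz[base_atoms, , drop = FALSE])
  R1 <- rotation_between(pl$normal, c(0, 0, 1))
  xyz <- sweep(xyz, 2, pl$center) %*% t(R1)
  glyc <- if (is_purine_residue(resname)) "N9" else "N1"
  edge <- if (is_purine_residue(resname)) "N1" else "N3"
  ref <- if (is_purine_residue(resname)) "C8" else "C6"
  xyz <- sweep(xyz, 2, xyz[glyc, ])
  v <- xyz[edge, c(1, 2)]
  xyz <- xyz %*% t(rot_z(-atan2(v[2], v[1])))
  if (xyz[ref, 2] < 0) xyz[, 2:3] <- -xyz[, 2:3]   # fix handedness
  xyz
}

# Rotate points about the axis through `point` along unit `dir` by theta.
rotate_about_axis <- function(xyz, point, dir, theta) {
  dir <- dir / sqrt(sum(dir^2))
  K <- matrix(c(0, dir[3], -dir[2], -dir[3], 0, dir[1], dir[2], -dir[1], 0),
              3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(sweep(xyz, 2, point) %*% t(R), 2, point, "+")
}

# Spin of the standardized backbone about the glycosidic axis, chosen so
# that stacked nucleotides of the idealized helix are clash-free (grid
# search over the spin against the minimal non-bonded separation).
.bdna_backbone_spin <- 200 * pi / 180

# Common half-separation of the two C1' anchors in the pair frame (A).
.bdna_c1_half <- 5.2

# Build the four base-pair templates in a common pair frame: origin at the
# C1'-C1' midpoint, pair plane z = 0, strand-1 C1' at -x.  Template for a
# pyrimidine reference base is the dyad image (180 deg about y) of its
# purine partner's template with strand roles swapped.  All strand-1
# nucleotides share one standardized backbone pose (strand-2 poses are its
# dyad image), so the generated helix is exactly screw-symmetric.
wc_pair_templates <- function() {
  cached <- .pwmthread_cache$pair_templates
  if (!is.null(cached)) return(cached)
  raw <- list()
  for (pu in c("DA", "DG")) {
    py <- wc_complement(pu)
    pu_xyz <- canonical_nucleotide(pu)
    py_xyz <- canonical_nucleotide(py)
    py_xyz[, 3] <- -py_xyz[, 3]          # antiparallel strand faces down
    py_xyz[, 2] <- -py_xyz[, 2]          # keep base handedness after flip
    hb <- .wc_hbonds[[pu]]
    ring6 <- intersect(c("N1", "C2", "N3", "C4", "C5", "C6"),
                       base_moiety_atoms(pu))
    ctr <- colMeans(pu_xyz[ring6, , drop = FALSE])
    # The WC hydrogen bonds are nearly parallel; use one common in-plane
    # direction (mean radial direction of the edge atoms) for all of them.
    dirs <- vapply(hb$pu, function(a) {
      d <- pu_xyz[a, ] - ctr; d[3] <- 0; d / sqrt(sum(d^2))
    }, numeric(3))
    u <- rowMeans(dirs); u <- u / sqrt(sum(u^2))
    target <- t(vapply(seq_len(nrow(hb)), function(k) {
      (pu_xyz[hb$pu[k], ] + hb$d[k] * u)[1:2]
    }, numeric(2)))
    fit <- fit_rigid_xy(py_xyz[hb$py, 1:2, drop = FALSE], target)
    py_xyz <- apply_rigid_xy(py_xyz, fit)
    # shared pair frame
    c1 <- pu_xyz["C1'", ]; c2 <- py_xyz["C1'", ]
    mid <- (c1 + c2) / 2
    ax <- c2 - c1; ax[3] <- 0; ax <- ax / sqrt(sum(ax^2))
    R <- t(cbind(ax, c(-ax[2], ax[1], 0), c(0, 0, 1)))
    pu_xyz <- sweep(pu_xyz, 2, mid) %*% t(R)
    py_xyz <- sweep(py_xyz, 2, mid) %*% t(R)
    # harmonize the glycosidic anchors across templates: every strand-1
    # C1' at exactly (-h, 0, 0), every strand-2 C1' at (+h, 0, 0), so the
    # generated helix is exactly screw-symmetric in C1'
    pu_xyz[, 1] <- pu_xyz[, 1] - (.bdna_c1_half + pu_xyz["C1'", 1])
    py_xyz[, 1] <- py_xyz[, 1] + (.bdna_c1_half - py_xyz["C1'", 1])
    # spin each nucleotide's backbone about its own glycosidic axis to the
    # clash-free pose (C1' lies on the axis and stays put)
    spin_bb <- function(xyz, glyc, angle) {
      xyz[.dna_backbone_atoms, ] <- rotate_about_axis(
        xyz[.dna_backbone_atoms, , drop = FALSE],
        xyz["C1'", ], xyz[glyc, ] - xyz["C1'", ], angle)
      xyz
    }
    # the flipped strand spins in the mirrored sense
    pu_xyz <- spin_bb(pu_xyz, "N9", .bdna_backbone_spin)
    py_xyz <- spin_bb(py_xyz, "N1", -.bdna_backbone_spin)
    raw[[pu]] <- list(ref = pu_xyz, partner = py_xyz,
                      ref_name = pu, partner_name = py)
  }
  dy <- function(m) { m[, c(1, 3)] <- -m[, c(1, 3)]; m }
  templates <- list()
  for (pu in c("DA", "DG")) {
    py <- raw[[pu]]$partner_name
    templates[[pu]] <- raw[[pu]]
    templates[[py]] <- list(ref = dy(raw[[pu]]$partner),
                            partner = dy(raw[[pu]]$ref),
                            ref_name = py, partner_name = pu)
  }
  .pwmthread_cache$pair_templates <- templates
  templates
}
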