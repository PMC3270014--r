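# Shared fixtures and independent oracles used across the suite.

# Minimal handcrafted PDB text (fixed-width ATOM records).
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, element = substring(name, 1, 1),
                          altloc = " ", record = "ATOM") {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name), altloc,
          resname, chain, resno, x, y, z, occ, 0, element)
}

# A complex of free-floating atoms with chosen types: protein atoms on
# chain P (one residue per atom), DNA atoms on chain D likewise.
cloud_complex <- function(protein_types, dna_types, protein_xyz, dna_xyz) {
  split2 <- function(tt) do.call(rbind, strsplit(tt, ".", fixed = TRUE))
  p <- split2(protein_types); d <- split2(dna_types)
  atoms <- rbind(
    data.frame(chain = "P", resno = seq_along(protein_types),
               resname = p[, 1], atom = p[, 2],
               element = substring(gsub("[0-9']", "", p[, 2]), 1, 1),
               x = protein_xyz[, 1], y = protein_xyz[, 2],
               z = protein_xyz[, 3], occupancy = 1,
               stringsAsFactors = FALSE),
    data.frame(chain = "D", resno = seq_along(dna_types),
               resname = d[, 1], atom = d[, 2],
               element = substring(gsub("[0-9']", "", d[, 2]), 1, 1),
               x = dna_xyz[, 1], y = dna_xyz[, 2], z = dna_xyz[, 3],
               occupancy = 1, stringsAsFactors = FALSE))
  as_complex(atoms)
}

# Exhaustive O(n^2) pair-count oracle, written independently of the
# package's vectorized counter: explicit loops and explicit interval tests.
oracle_count_pairs <- function(cx) {
  pa <- cx$atoms[cx$atoms$chain %in%
                 names(which(cx$chain_kind == "protein")), ]
  da <- cx$atoms[cx$atoms$chain %in%
                 names(which(cx$chain_kind == "dna")), ]
  pt <- assign_type(pa$resname, pa$atom)
  dt <- assign_type(da$resname, da$atom)
  out <- list()
  for (i in seq_len(nrow(pa))) {
    if (is.na(pt[i])) next
    for (j in seq_len(nrow(da))) {
      if (is.na(dt[j])) next
      dd <- sqrt((pa$x[i] - da$x[j])^2 + (pa$y[i] - da$y[j])^2 +
                 (pa$z[i] - da$z[j])^2)
      bin <- NA
      if (dd > 0 && dd <= 3) bin <- 3
      else for (r in 4:10) if (dd > r - 1 && dd <= r) { bin <- r; break }
      if (is.na(bin)) next
      key <- paste(pt[i], dt[j], bin)
      out[[key]] <- (if (is.null(out[[key]])) 0L else out[[key]]) + 1L
    }
  }
  out[order(names(out))]
}

count_df_to_list <- function(df) {
  out <- as.list(df$count)
  names(out) <- paste(df$protein_type, df$dna_type, df$bin)
  out[order(names(out))]
}

# Uniform random rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_transform <- function() {
  rigid_transform(random_rotation(), stats::runif(3, -20, 20))
}

# Brute-force PWM alignment oracle: enumerate every placement and strand
# with an independently coded mean-KL score.
oracle_align <- function(pred, ann, epsilon = 1e-3) {
  flo <- function(m) { m <- pmax(unclass(m), epsilon); m / rowSums(m) }
  kl1 <- function(q, p) sum(q * log(q / p))
  rc <- function(m) {
    m2 <- unclass(m)[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
    colnames(m2) <- c("A", "C", "G", "T"); m2
  }
  best <- NULL
  for (strand in c("forward", "revcomp")) {
    pm <- if (strand == "forward") unclass(pred) else rc(pred)
    Lp <- nrow(pm); La <- nrow(ann)
    for (off in 0:abs(La - Lp)) {
      if (Lp <= La) { q <- flo(unclass(ann)[off + 1:Lp, , drop = FALSE])
                      p <- flo(pm); L <- Lp }
      else { q <- flo(unclass(ann)); p <- flo(pm[off + 1:La, , drop = FALSE])
             L <- La }
      psi <- sum(vapply(seq_len(L), function(j) kl1(q[j, ], p[j, ]),
                        numeric(1))) / L
      if (is.null(best) || psi < best$psi - 1e-15)
        best <- list(psi = psi, offset = off, strand = strand)
    }
  }
  best
}

# Random column-stochastic PWM.
random_pwm <- function(L) {
  m <- matrix(stats::rexp(L * 4), L, 4)
  pwm(m / rowSums(m))
}

revcomp_seq <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# One complex both tests and acceptance reuse: built to pass every
# knowledgebase filter (45-residue protein, 6 contact residues).
passing_fixture <- function(seed = 11) {
  contacts <- c(pwmthread:::default_backbone_contacts(5, 8),
                list(list(residue = 12L, atom = "CB", position = 4,
                          strand = "ref", distance = 3.4,
                          mode = "groove")))
  make_toy_complex("GATTACCA", protein_size = 45,
                   planted_contacts = contacts, seed = seed)
}
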