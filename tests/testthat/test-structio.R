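test_that("a handcrafted PDB parses to the atoms it contains", {
  txt <- paste(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.0, 1.2, 0),
    "END", sep = "\n")
  cx <- read_structure(txt)
  expect_equal(nrow(cx$atoms), 3)
  expect_equal(length(cx$chain_kind), 1)
  expect_equal(unname(cx$chain_kind), "protein")
  expect_equal(cx$atoms$atom, c("N", "CA", "C"))
})

test_that("hydrogens are stripped and altlocs resolve to highest occupancy", {
  txt <- paste(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 5, 5, 5, occ = 0.6, altloc = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 1.5, 0, 0),
    pdb_atom_line(4, "HB1", "ALA", "A", 1, 2.0, 0.5, 0, element = "H"),
    "END", sep = "\n")
  cx <- read_structure(txt)
  expect_equal(nrow(cx$atoms), 2)           # H gone, one CA kept
  ca <- cx$atoms[cx$atoms$atom == "CA", ]
  expect_equal(ca$x, 5)                     # the 0.6-occupancy altloc
})

test_that("header resolution and method are read and stamped", {
  txt <- paste(
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.75 ANGSTROMS.",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    sep = "\n")
  cx <- read_structure(txt)
  expect_equal(cx$resolution, 1.75)
  expect_match(cx$method, "X-RAY")
  expect_error(read_structure("HEADER only\nEND\n"), "parse|empty|ATOM")
})

test_that("fixture structures round-trip through PDB write/read", {
  cx <- passing_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cx, f)
  cx2 <- read_structure(f)
  expect_equal(nrow(cx2$atoms), nrow(cx$atoms))
  expect_lt(max(abs(pwmthread:::coords(cx2$atoms) -
                    pwmthread:::coords(cx$atoms))), 1e-3)
  expect_equal(cx2$resolution, cx$resolution)
  expect_equal(sort(unname(cx2$chain_kind)), sort(unname(cx$chain_kind)))
})

test_that("duplex detection pairs complementary bases within reach", {
  d <- make_bdna("GATTACCA")
  dup <- detect_duplex(d)
  expect_equal(dup$n_paired, 8)
  expect_equal(dup$n_unpaired, 0)
  expect_equal(paste(substring(dup$pairs$resname1, 2), collapse = ""),
               "GATTACCA")
  # all pairs are WC complementary by construction of the detector
  expect_true(all(wc_complement(dup$pairs$resname1) == dup$pairs$resname2))

  # delete the partner of the last reference position
  last <- dup$pairs[8, ]
  a <- d$atoms
  d1 <- as_complex(a[!(a$chain == last$chain2 & a$resno == last$resno2), ])
  dup1 <- detect_duplex(d1)
  expect_equal(dup1$n_paired, 7)
  expect_equal(dup1$n_unpaired, 1)

  # translate one strand far away: nothing pairs
  a2 <- d$atoms
  sel <- a2$chain == "B"
  a2$x[sel] <- a2$x[sel] + 10
  dup2 <- detect_duplex(as_complex(a2))
  expect_equal(dup2$n_paired, 0)

  expect_error(detect_duplex(as_complex(
    data.frame(chain = "A", resno = 1, resname = "ALA", atom = "CA",
               element = "C", x = 0, y = 0, z = 0))), "DNA")
})

test_that("duplex detection is invariant under rigid motion", {
  d <- make_bdna("ACGTAC")
  dup <- detect_duplex(d)
  set.seed(5)
  for (k in 1:5) {
    d2 <- apply_transform(d, random_transform())
    dup2 <- detect_duplex(d2)
    expect_equal(dup2$n_paired, dup$n_paired)
    expect_equal(dup2$pairs, dup$pairs)
  }
})

test_that("contact residues follow the any-heavy-atom rule", {
  # one DNA atom at the origin; one protein residue with CA far away and
  # CB at a controlled separation
  mk <- function(dist, ca_dist = 30) {
    cloud_complex(c("ALA.CA", "ALA.CB"), "DG.N7",
                  rbind(c(ca_dist, 0, 0), c(dist, 0, 0)),
                  matrix(c(0, 0, 0), 1))
  }
  cx <- mk(4.4)
  cx$atoms$resno[cx$atoms$chain == "P"] <- 1L   # one residue, two atoms
  cx44 <- as_complex(cx$atoms)
  expect_equal(nrow(contact_residues(cx44)), 1)

  cx$atoms$x[cx$atoms$atom == "CB"] <- 4.6
  expect_equal(nrow(contact_residues(as_complex(cx$atoms))), 0)

  # any-atom rule: CA at 6.0 A, CB at 3.0 A -> residue counts once
  cx$atoms$x[cx$atoms$atom == "CA"] <- 6.0
  cx$atoms$x[cx$atoms$atom == "CB"] <- 3.0
  expect_equal(nrow(contact_residues(as_complex(cx$atoms))), 1)
})

test_that("contact sets grow monotonically with the cutoff", {
  cx <- passing_fixture()
  cuts <- sort(runif(6, 2, 12))
  sets <- lapply(cuts, function(cc) {
    cr <- contact_residues(cx, cc)
    paste(cr$chain, cr$resno)
  })
  for (k in seq_len(length(sets) - 1))
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
})

test_that("selection filters report every failed criterion", {
  cx <- passing_fixture()
  expect_true(passes_filters(cx, filter_profile("knowledgebase"))$pass)

  worse <- cx; worse$resolution <- 3.2
  v <- passes_filters(worse, filter_profile("knowledgebase"))
  expect_false(v$pass)
  expect_equal(v$failures, "resolution")

  # 5-bp duplex fails the paired-bases floor (and nothing else)
  short <- make_toy_complex("GATTA", protein_size = 45,
                            planted_contacts =
                              pwmthread:::default_backbone_contacts(5, 5),
                            seed = 2)
  v2 <- passes_filters(short, filter_profile("knowledgebase"))
  expect_false(v2$pass)
  expect_true("min_paired_bases" %in% v2$failures)

  # resolution at exactly 3.0 is not better than 3.0
  border <- cx; border$resolution <- 3.0
  expect_false(passes_filters(border)$pass)
})

test_that("the knowledgebase profile is stricter than the template profile", {
  cases <- list(passing_fixture(1), passing_fixture(2),
                make_toy_complex("ACGTACGT", 45,
                                 pwmthread:::default_backbone_contacts(5, 8),
                                 seed = 3))
  for (cx in cases) {
    if (passes_filters(cx, filter_profile("knowledgebase"))$pass)
      expect_true(passes_filters(cx, filter_profile("template"))$pass)
  }
})
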