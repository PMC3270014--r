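test_that("idealized duplexes are fully paired with regular geometry", {
  d <- make_bdna("GATTACCA")
  dup <- detect_duplex(d)
  expect_equal(dup$n_paired, 8)
  expect_equal(dup$n_unpaired, 0)

  a <- d$atoms
  c1 <- a[a$chain == "A" & a$atom == "C1'", ]
  c1 <- c1[order(c1$resno), ]
  steps <- sqrt(rowSums(diff(as.matrix(c1[, c("x", "y", "z")]))^2))
  expect_lt(diff(range(steps)), 0.1)

  # base rings are coplanar to 0.05 A
  for (rn in unique(paste(a$chain, a$resno))[1:4] ) {
    parts <- strsplit(rn, " ")[[1]]
    res <- a[a$chain == parts[1] & a$resno == as.integer(parts[2]), ]
    base <- res[res$atom %in%
                pwmthread:::base_moiety_atoms(res$resname[1]), ]
    pl <- pwmthread:::fit_plane(pwmthread:::coords(base))
    dev <- abs(sweep(pwmthread:::coords(base), 2, pl$center) %*% pl$normal)
    expect_lt(max(dev), 0.05)
  }

  expect_error(make_bdna("GAXT"), "alphabet")
  expect_error(make_bdna("G"), "length")
})

test_that("the second strand reads as the reverse complement", {
  s <- "GATTACCA"
  d <- make_bdna(revcomp_seq(s))
  a <- d$atoms
  resB <- unique(a[a$chain == "B", c("resno", "resname")])
  resB <- resB[order(resB$resno), ]
  expect_equal(paste(substring(resB$resname, 2), collapse = ""), s)
})

test_that("toy complexes plant contacts where requested, deterministically", {
  cx <- make_toy_complex("GATTACCA", protein_size = 45,
                         planted_contacts = list(
                           list(residue = 3L, atom = "CB", position = 2,
                                dna_atom = "P", strand = "ref",
                                distance = 4.4, mode = "radial")),
                         seed = 9)
  cr <- contact_residues(cx)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$resno, 3)

  # 4.6 A stays out of the 4.5 A contact shell
  cx2 <- make_toy_complex("GATTACCA", 45, planted_contacts = list(
    list(residue = 3L, atom = "CB", position = 2, dna_atom = "P",
         strand = "ref", distance = 4.6, mode = "radial")), seed = 9)
  expect_equal(nrow(contact_residues(cx2)), 0)

  # determinism: same seed gives bitwise-identical PDB output
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(make_toy_complex("ACGT", 40, seed = 4), f1)
  write_structure(make_toy_complex("ACGT", 40, seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))

  # infeasible planting is refused
  expect_error(make_toy_complex("GATTACCA", 45, planted_contacts = list(
    list(residue = 3L, atom = "CB", position = 2, dna_atom = "P",
         strand = "ref", distance = 0.5, mode = "radial")), seed = 9),
    "infeasible")
})

test_that("short protein chains fail the chain-length filter", {
  cx <- make_toy_complex("GATTACCA", protein_size = 39,
                         planted_contacts =
                           pwmthread:::default_backbone_contacts(5, 8),
                         seed = 10)
  v <- passes_filters(cx, filter_profile("knowledgebase"))
  expect_false(v$pass)
  expect_true("min_chain_length" %in% v$failures)
})

test_that("planted corpora concentrate probe contacts on the planted base", {
  corpus <- make_planted_kb_corpus(12, "G", seed = 13)
  expect_length(corpus, 12)
  kb <- suppressMessages(build_knowledgebase(corpus))
  # probe CB short-range counts against guanine groove atoms
  short_g <- sum(kb$counts["ALA.CB", c("DG.N7", "DG.O6"), c("3", "4", "5")])
  short_a <- sum(kb$counts["ALA.CB", c("DA.N7", "DA.N6"), c("3", "4", "5")])
  expect_gt(short_g, 0)
  expect_gt(short_g, 3 * short_a)

  # permutation leaves the accumulated counts identical
  kb_perm <- suppressMessages(build_knowledgebase(corpus[c(5:12, 1:4)]))
  expect_identical(kb_perm$counts, kb$counts)

  # corpora are reproducible under their seed
  corpus2 <- make_planted_kb_corpus(12, "G", seed = 13)
  expect_identical(corpus2[[7]]$atoms, corpus[[7]]$atoms)
})

test_that("opposite planted preferences flip the threading prediction", {
  modal_base <- function(preference, seed) {
    corpus <- make_planted_kb_corpus(10, preference, seed = seed)
    pot <- derive_potential(
      suppressMessages(build_knowledgebase(corpus)))
    held <- make_planted_complex(preference, seed = seed + 5000)
    pw <- predict_pwm(held, detect_duplex(held), pot)
    colnames(pw)[which.max(unclass(pw)[4, ])]
  }
  expect_equal(modal_base("G", 17), "G")
  expect_equal(modal_base("A", 17), "A")
})
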