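backbone_coords <- function(cx, chain, resno) {
  a <- cx$atoms
  sel <- a[a$chain == chain & a$resno == resno &
           a$atom %in% pwmthread:::.dna_backbone_atoms, ]
  m <- pwmthread:::coords(sel[order(sel$atom), ])
  rownames(m) <- sel$atom[order(sel$atom)]
  m
}

bare <- function(m) { rownames(m) <- NULL; m }

test_that("base substitution rebuilds the pair and nothing else", {
  cx <- passing_fixture(51)
  dup <- detect_duplex(cx)
  i <- 3                                   # a T position in GATTACCA
  pair <- dup$pairs[i, ]
  expect_equal(pair$resname1, "DT")

  sub <- substitute_base_pair(cx, dup, i, "A")
  dup2 <- detect_duplex(sub)
  expect_equal(dup2$pairs$resname1[i], "DA")
  expect_equal(dup2$pairs$resname2[i], "DT")   # complement updated

  # backbone bitwise unchanged on both strands
  expect_identical(backbone_coords(sub, pair$chain1, pair$resno1),
                   backbone_coords(cx, pair$chain1, pair$resno1))
  expect_identical(backbone_coords(sub, pair$chain2, pair$resno2),
                   backbone_coords(cx, pair$chain2, pair$resno2))
  # every other residue bitwise unchanged
  others <- cx$atoms[!(cx$atoms$chain %in% c(pair$chain1, pair$chain2) &
                       cx$atoms$resno %in% c(pair$resno1, pair$resno2)), ]
  others2 <- sub$atoms[!(sub$atoms$chain %in% c(pair$chain1, pair$chain2) &
                         sub$atoms$resno %in% c(pair$resno1, pair$resno2)), ]
  expect_identical(bare(pwmthread:::coords(others2)),
                   bare(pwmthread:::coords(others)))

  expect_error(substitute_base_pair(cx, dup, 99, "A"), "not a paired")
})

test_that("self-substitution is idempotent and matches library geometry", {
  cx <- passing_fixture(52)
  dup <- detect_duplex(cx)
  s1 <- substitute_base_pair(cx, dup, 1, "G")  # position 1 is already G
  s2 <- substitute_base_pair(s1, detect_duplex(s1), 1, "G")
  expect_equal(pwmthread:::coords(s2$atoms), pwmthread:::coords(s1$atoms),
               tolerance = 1e-9)

  # G -> A: C1'-N9 bond length matches the library value to 0.05 A
  sA <- substitute_base_pair(cx, dup, 1, "A")
  a <- sA$atoms
  res <- a[a$chain == dup$pairs$chain1[1] & a$resno == dup$pairs$resno1[1], ]
  c1 <- as.numeric(res[res$atom == "C1'", c("x", "y", "z")])
  n9 <- as.numeric(res[res$atom == "N9", c("x", "y", "z")])
  lib <- pwmthread:::lib_coords("DA", c("C1'", "N9"))
  lib_bond <- sqrt(sum((lib[1, ] - lib[2, ])^2))
  expect_equal(sqrt(sum((c1 - n9)^2)), lib_bond, tolerance = 0.05)
})

# A potential whose only nonzero entry links one protein type to one
# DNA type, for single-lookup constructions.
delta_potential <- function(protein_type, dna_type, value = -1) {
  kb <- suppressMessages(build_knowledgebase(list(passing_fixture(5))))
  pot <- derive_potential(kb)
  pot$u[] <- 0
  pot$u[protein_type, dna_type, ] <- value
  pot
}

test_that("position energies respond only to the substituted identity", {
  # duplex plus a single probe atom placed 3.5 A off guanine's N7 at
  # position 4; the potential is nonzero only for (ALA.CB, DG.N7) in bins
  # 3-4, so only a reference-strand guanine can score (the partner
  # guanine's N7, present when the reference base is C, points to the far
  # end of the major groove)
  dna <- make_bdna("GATGACCA")
  dup <- detect_duplex(dna)
  pos4 <- dna$atoms[dna$atoms$chain == "A" & dna$atoms$resno == 4, ]
  n7 <- as.numeric(pos4[pos4$atom == "N7", c("x", "y", "z")])
  ctr <- colMeans(pwmthread:::coords(
    pos4[pos4$atom %in% pwmthread:::base_moiety_atoms("DG"), ]))
  u <- n7 - ctr; u <- u / sqrt(sum(u^2))
  probe <- n7 + 3.5 * u
  prot <- data.frame(chain = "P", resno = 1, resname = "ALA", atom = "CB",
                     element = "C", x = probe[1], y = probe[2],
                     z = probe[3], occupancy = 1)
  cx <- as_complex(rbind(dna$atoms, prot))

  # geometric precondition: the partner guanine's N7 stays outside bin 4
  cxC <- substitute_base_pair(cx, dup, 4, "C")
  partner <- cxC$atoms[cxC$atoms$chain == "B" &
                       cxC$atoms$resno == dup$pairs$resno2[4], ]
  n7p <- as.numeric(partner[partner$atom == "N7", c("x", "y", "z")])
  expect_gt(sqrt(sum((probe - n7p)^2)), 4)

  pot <- delta_potential("ALA.CB", "DG.N7")
  pot$u["ALA.CB", "DG.N7", c("5", "6", "7", "8", "9", "10")] <- 0
  pe <- position_energies(cx, dup, 4, pot)
  expect_true(pe$contacted)
  expect_equal(unname(pe$energies["G"]), -1)
  expect_equal(unname(pe$energies["A"]), 0)
  expect_equal(unname(pe$energies["C"]), 0)
  expect_equal(unname(pe$energies["T"]), 0)
})

test_that("uncontacted positions have four equal energies", {
  # protein arc only, no planted contacts: everything is far from the DNA
  cx <- make_toy_complex("GATTACCA", protein_size = 45, seed = 54)
  dup <- detect_duplex(cx)
  kb <- suppressMessages(build_knowledgebase(list(passing_fixture(5))))
  pot <- derive_potential(kb)
  pe <- position_energies(cx, dup, 4, pot)
  expect_false(pe$contacted)
  expect_true(all(pe$energies == pe$energies[1]))
})

test_that("position energies are rigid-invariant", {
  cx <- passing_fixture(55)
  dup <- detect_duplex(cx)
  kb <- suppressMessages(build_knowledgebase(list(cx)))
  pot <- derive_potential(kb)
  e0 <- position_energies(cx, dup, 4, pot)$energies
  set.seed(56)
  for (k in 1:3) {
    cx2 <- apply_transform(cx, random_transform())
    e1 <- position_energies(cx2, detect_duplex(cx2), 4, pot)$energies
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("Boltzmann columns honor closed forms, shifts and beta limits", {
  bc <- pwmthread:::boltzmann_column
  expect_equal(bc(c(1, 1, 1, 1), 15), rep(0.25, 4))
  # dG difference of beta * ln 3 gives a 3:1 probability ratio
  beta <- 15
  p <- bc(c(0, beta * log(3), 50, 60), beta)
  expect_equal(p[1] / p[2], 3, tolerance = 1e-12)
  # shift invariance
  e <- c(0.3, -1.2, 4, 2)
  expect_equal(bc(e + 7.5, 15), bc(e, 15), tolerance = 1e-12)
  # monotone: lower energy, higher probability
  expect_true(all(diff(bc(sort(rnorm(4)), 15)) < 0))
  # beta limits
  expect_lt(max(abs(bc(e, 1e6) - 0.25)), 1e-3)
  expect_equal(which.max(bc(e, 1e-3)), which.min(e))
})

test_that("predicted PWMs are column-stochastic and flag contacts", {
  cx <- passing_fixture(57)
  kb <- suppressMessages(build_knowledgebase(
    make_planted_kb_corpus(8, "G", seed = 58)))
  pot <- derive_potential(kb)
  pw <- predict_pwm(cx, detect_duplex(cx), pot)
  expect_s3_class(pw, "pwm")
  expect_equal(nrow(pw), 8)
  expect_equal(unname(rowSums(unclass(pw))), rep(1, 8), tolerance = 1e-9)
  # energy ordering matches probability ordering at every position
  e <- attr(pw, "energies")
  for (i in 1:8)
    expect_equal(order(e[i, ]), order(-unclass(pw)[i, ]))
})

test_that("threading is independent of the template's native sequence", {
  cx <- passing_fixture(59)
  dup <- detect_duplex(cx)
  kb <- suppressMessages(build_knowledgebase(
    make_planted_kb_corpus(8, "G", seed = 60)))
  pot <- derive_potential(kb)
  pw0 <- predict_pwm(cx, dup, pot)
  # rewrite the template duplex to a different sequence, then re-thread
  cx2 <- cx
  for (i in c(2, 5, 7)) cx2 <- substitute_base_pair(cx2, dup, i, "G")
  pw1 <- predict_pwm(cx2, detect_duplex(cx2), pot)
  # unsubstituted positions: exactly invariant
  for (i in c(1, 3, 4, 6, 8))
    expect_identical(unclass(pw0)[i, ], unclass(pw1)[i, ])
  # substituted positions: invariant up to the tiny glycosidic-frame
  # difference between purine and pyrimidine re-anchoring
  expect_lt(max(abs(unclass(pw1) - unclass(pw0))), 0.02)
})
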