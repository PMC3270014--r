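test_that("the reference state normalizes and matches closed forms", {
  for (a in c(0, 1.61, 3)) {
    p <- reference_probability(3:10, potential_params(alpha = a))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  p0 <- reference_probability(3:10, potential_params(alpha = 0))
  expect_equal(unname(p0[1]), 0.3)
  expect_true(all(abs(p0[-1] - 0.1) < 1e-15))
  # high-precision evaluation of 10^1.61 * 1 / sum_r r^1.61 dr
  expect_equal(reference_probability(10, potential_params(alpha = 1.61)),
               0.22061470712184624, tolerance = 1e-9)
  expect_error(reference_probability(11), "invalid")
})

make_kb_with_counts <- function(counts_list) {
  kb <- suppressMessages(build_knowledgebase(list(passing_fixture(5))))
  kb$counts[] <- 0L
  for (nm in names(counts_list)) {
    key <- strsplit(nm, " ")[[1]]
    kb$counts[key[1], key[2], ] <- counts_list[[nm]]
  }
  kb
}

test_that("observed probabilities follow the stated normalizations", {
  kb <- make_kb_with_counts(list(
    "ALA.CA DG.N7" = c(0, 0, 0, 0, 0, 0, 0, 8),
    "ALA.CB DG.N7" = rep(1L, 8)))
  p0 <- potential_params(pseudocount = 0)
  expect_equal(observed_probability(kb, "ALA.CA", "DG.N7", 10, p0), 1)
  expect_equal(observed_probability(kb, "ALA.CA", "DG.N7", 4, p0), 0)
  for (r in 3:10)
    expect_equal(observed_probability(kb, "ALA.CB", "DG.N7", r, p0), 1 / 8)
  # power weighting: uniform counts tilt as w(r) = r / r_cut
  pw <- potential_params(pseudocount = 0, weighting = "power", gamma = 1)
  expect_equal(observed_probability(kb, "ALA.CB", "DG.N7", 10, pw) /
               observed_probability(kb, "ALA.CB", "DG.N7", 3, pw),
               10 / 3, tolerance = 1e-12)
  # uninformative pair with no pseudocount
  expect_true(is.na(observed_probability(kb, "GLY.N", "DT.O4", 4, p0)))
})

test_that("the potential is the negative log-ratio to the reference state", {
  params <- potential_params(pseudocount = 0)
  pref <- reference_probability(3:10, params)
  # counts proportional to the reference state -> u = 0 everywhere
  kb <- make_kb_with_counts(list("ALA.CA DG.N7" = 1000 * pref))
  for (r in 3:10)
    expect_equal(pair_potential(kb, "ALA.CA", "DG.N7", r, params), 0,
                 tolerance = 1e-12)
  # P = e * P_ref in one bin -> u = -1 there
  pp <- pref; pp[4] <- exp(1) * pref[4]
  pp[-4] <- pp[-4] * (1 - pp[4]) / sum(pp[-4])
  kb2 <- make_kb_with_counts(list("ALA.CA DG.N7" = 1e6 * pp))
  expect_equal(pair_potential(kb2, "ALA.CA", "DG.N7", 6, params), -1,
               tolerance = 1e-9)
  # uninformative pairs contribute nothing
  expect_equal(pair_potential(kb2, "GLY.N", "DT.O4", 5, params), 0)
})

test_that("enrichment strictly lowers the potential", {
  set.seed(31)
  params <- potential_params()
  for (k in 1:20) {
    counts <- sample(0:50, 8, TRUE)
    r <- sample(3:10, 1)
    kb1 <- make_kb_with_counts(list("LYS.NZ DG.O6" = counts))
    counts2 <- counts; counts2[r - 2] <- counts2[r - 2] + sample(1:20, 1)
    kb2 <- make_kb_with_counts(list("LYS.NZ DG.O6" = counts2))
    expect_lt(pair_potential(kb2, "LYS.NZ", "DG.O6", r, params),
              pair_potential(kb1, "LYS.NZ", "DG.O6", r, params))
  }
})

test_that("binding free energy sums table lookups over in-range pairs", {
  kb <- suppressMessages(build_knowledgebase(list(passing_fixture(6))))
  pot <- derive_potential(kb)
  # empty sum: protein far beyond the cutoff
  far <- cloud_complex("ALA.CA", "DG.N7",
                       matrix(c(50, 0, 0), 1), matrix(c(0, 0, 0), 1))
  expect_equal(binding_free_energy(far, pot), 0)
  # two-pair toy: independent lookup sum
  cx <- cloud_complex(c("ALA.CA", "ARG.NH1"), "DG.N7",
                      rbind(c(3.5, 0, 0), c(0, 6.2, 0)),
                      matrix(c(0, 0, 0), 1))
  expected <- pot$u["ALA.CA", "DG.N7", "4"] + pot$u["ARG.NH1", "DG.N7", "7"]
  expect_equal(binding_free_energy(cx, pot), expected, tolerance = 1e-12)
  # a pair at 11 A contributes zero
  cx11 <- cloud_complex(c("ALA.CA", "ARG.NH1"), "DG.N7",
                        rbind(c(3.5, 0, 0), c(11, 0, 0)),
                        matrix(c(0, 0, 0), 1))
  expect_equal(binding_free_energy(cx11, pot),
               unname(pot$u["ALA.CA", "DG.N7", "4"]), tolerance = 1e-12)
})

test_that("binding free energy is rigid-invariant and additive over
           well-separated sub-complexes", {
  kb <- suppressMessages(build_knowledgebase(list(passing_fixture(7))))
  pot <- derive_potential(kb)
  cx <- passing_fixture(8)
  e0 <- binding_free_energy(cx, pot)
  set.seed(17)
  for (k in 1:5) {
    e1 <- binding_free_energy(apply_transform(cx, random_transform()), pot)
    expect_equal(e1, e0, tolerance = 1e-9)
  }
  # additivity: shift a copy far away and merge
  a2 <- cx$atoms
  a2$chain <- chartr("ABP", "DEQ", a2$chain)
  a2$x <- a2$x + 200
  merged <- as_complex(rbind(cx$atoms, a2), resolution = cx$resolution,
                       method = cx$method)
  expect_equal(binding_free_energy(merged, pot), 2 * e0, tolerance = 1e-9)
})

test_that("potential tables export with their parameter block", {
  kb <- suppressMessages(build_knowledgebase(list(passing_fixture(5))))
  pot <- derive_potential(kb, potential_params(pseudocount = 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  save_potential(pot, f)
  lines <- readLines(f)
  expect_true(any(grepl("^#alpha\t1.61", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), sum(pot$u != 0))
})
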