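make_counts <- function(counts) {
  structure(list(counts = counts, mode = "calpha", n_structures = 1L),
            class = "contact_counts")
}

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

test_that("parse_structure maps ATOM records, altlocs and models", {
  s0 <- residue_structure(1:3, c("A", "A", "A"),
                          rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)))
  txt <- write_pdb(s0)
  s <- parse_structure(txt)
  expect_s3_class(s, "residue_structure")
  expect_identical(s$resno, 1:3)
  expect_identical(s$resname, c("A", "A", "A"))
  expect_equal(s$calpha[2, ], c(3.8, 0, 0))

  # two alternate locations: only altloc A retained
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  1.00  0.00")
  sa <- parse_structure(alt)
  expect_equal(nrow(sa$atoms[[1]]), 1)
  expect_equal(sa$calpha[1, ], c(0, 0, 0))

  # only the first model is read
  two_models <- c(txt[1], "ENDMDL", txt[2:3])
  expect_equal(length(parse_structure(two_models)$resno), 1)

  # water-only input is empty
  expect_error(parse_structure(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000"),
    class = "neopred_empty_structure")
  # malformed coordinates are named
  expect_error(parse_structure(
    "ATOM      1  CA  ALA A   1       x.000   0.000   0.000"),
    class = "neopred_parse_error")
  # non-canonical residues skipped with a warning
  expect_warning(
    parse_structure(c(txt[1:3],
      "ATOM      9  CA  MSE A   9       0.000   5.000   0.000")),
    "non-canonical")
})

test_that("contact_pairs honours cutoffs and sequence exclusions", {
  colinear <- residue_structure(1:3, rep("A", 3),
                                rbind(c(0, 0, 0), c(3.8, 0, 0),
                                      c(7.6, 0, 0)))
  expect_equal(nrow(contact_pairs(colinear, "calpha")), 0)

  near <- residue_structure(c(1L, 4L), c("A", "G"),
                            rbind(c(0, 0, 0), c(6.4, 0, 0)))
  expect_equal(contact_pairs(near, "calpha"),
               matrix(c(1L, 4L), 1, dimnames = list(NULL, c("i", "j"))))
  # inclusive boundary
  at_cut <- residue_structure(c(1L, 4L), c("A", "G"),
                              rbind(c(0, 0, 0), c(6.5, 0, 0)))
  expect_equal(nrow(contact_pairs(at_cut, "calpha")), 1)
  # |i - j| <= 1 excluded in calpha mode, <= 2 in allatom mode
  close_neighbours <- residue_structure(1:3, rep("A", 3),
                                        rbind(c(0, 0, 0), c(3, 0, 0),
                                              c(4, 0, 0)))
  cp <- contact_pairs(close_neighbours, "calpha")
  expect_equal(cp[, "i"], 1L, ignore_attr = TRUE)
  expect_equal(cp[, "j"], 3L, ignore_attr = TRUE)
  expect_equal(nrow(contact_pairs(close_neighbours, "allatom")), 0)

  expect_error(contact_pairs(near, "sidechain"),
               class = "neopred_config_error")
})

test_that("contact_pairs agrees with a brute-force all-pairs scan", {
  for (seed in 1:4) {
    s <- withr::with_seed(seed, {
      n <- 10L
      residue_structure(seq_len(n), sample(aa20, n, replace = TRUE),
                        matrix(runif(n * 3, 0, 12), n, 3))
    })
    for (mode in c("calpha", "allatom")) {
      cutoff <- if (mode == "calpha") 6.5 else 4.5
      excl <- if (mode == "calpha") 1L else 2L
      ref <- list()
      for (a in 1:9) for (b in (a + 1):10) {
        if (b - a <= excl) next
        d <- sqrt(sum((s$calpha[a, ] - s$calpha[b, ])^2))
        if (d <= cutoff) ref[[length(ref) + 1]] <- c(a, b)
      }
      got <- contact_pairs(s, mode)
      expect_equal(nrow(got), length(ref))
      if (length(ref) > 0)
        expect_equal(unname(got), do.call(rbind, ref))
    }
  }
})

test_that("count_contacts tallies symmetric type counts", {
  one <- residue_structure(c(1L, 4L), c("A", "G"),
                           rbind(c(0, 0, 0), c(5, 0, 0)))
  cc <- count_contacts(one, "calpha")
  expect_equal(cc$counts["A", "G"], 1)
  expect_equal(cc$counts["G", "A"], 1)
  expect_equal(sum(cc$counts), 2)

  far <- residue_structure(c(1L, 4L), c("A", "G"),
                           rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(sum(count_contacts(far, "calpha")$counts), 0)

  aa <- residue_structure(c(1L, 4L), c("A", "A"),
                          rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(count_contacts(list(aa, aa), "calpha")$counts["A", "A"], 2)
  # symmetry holds for arbitrary structures
  s <- gen_structure_fixture(40, "helix", seed = 2)
  m <- count_contacts(s, "calpha")$counts
  expect_identical(m, t(m))
})

test_that("energy_matrix implements the quasi-chemical log-odds", {
  # uniform counts over all 210 unordered pairs -> all entries equal
  uni <- matrix(1L, 20, 20, dimnames = list(aa20, aa20))
  E <- energy_matrix(make_counts(uni))
  expect_true(all(is.finite(E$values)))
  expect_lt(diff(range(E$values)), 1e-12)

  # A-A at exactly twice its marginal expectation -> e(A,A) = -ln 2
  cm <- matrix(0L, 20, 20, dimnames = list(aa20, aa20))
  cm["A", "A"] <- 2L
  cm["A", "C"] <- 1L; cm["C", "A"] <- 1L
  cm["C", "C"] <- 6L
  E2 <- suppressWarnings(energy_matrix(make_counts(cm)))
  expect_equal(E2$values["A", "A"], -log(2))

  # symmetry and scale invariance
  s <- gen_structure_fixture(60, "helix", seed = 5)
  cc <- count_contacts(s, "calpha")
  E3 <- suppressWarnings(energy_matrix(cc))
  expect_equal(E3$values, t(E3$values))
  cc2 <- cc; cc2$counts <- cc$counts * 2L
  E4 <- suppressWarnings(energy_matrix(cc2))
  expect_equal(E3$values, E4$values)

  # unseen residue types are imputed 0 with a warning
  expect_warning(energy_matrix(make_counts(cm)), "no contacts")
  expect_true(all(E2$values["D", ] == 0))

  expect_error(energy_matrix(make_counts(uni * 0L)),
               class = "neopred_degenerate_counts")
})

test_that("control matrices: null is zero, permutation preserves multiset", {
  E <- fixture_energy()
  Z <- control_matrix(E, "null")
  expect_true(all(Z$values == 0))
  P1 <- control_matrix(E, "permuted", seed = 11)
  P2 <- control_matrix(E, "permuted", seed = 11)
  expect_identical(P1$values, P2$values)
  expect_equal(P1$values, t(P1$values))
  ut <- upper.tri(E$values, diag = TRUE)
  expect_equal(sort(P1$values[ut]), sort(E$values[ut]))
  expect_error(control_matrix(E, "bogus"), class = "neopred_config_error")
})

test_that("energy matrix TSV round trip is bit-exact", {
  E <- fixture_random_energy(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_matrix(E, path)
  E2 <- read_energy_matrix(path)
  expect_identical(E2$values, E$values)
  expect_identical(E2$variant, "loaded")
})
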