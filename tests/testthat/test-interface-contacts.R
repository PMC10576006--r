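test_that("PDB parsing reads toy records exactly and round-trips", {
  txt <- paste(
    "ATOM      1  CA  GLU A  37      11.104   6.134   0.000  1.00  0.00           C",
    "ATOM      2  OE1 GLU A  37      14.104   6.134   1.000  1.00  0.00           O",
    "END", sep = "\n")
  coords <- parse_structure(txt)
  expect_identical(nrow(coords$atoms), 2L)
  expect_equal(coords$atoms$x, c(11.104, 14.104))
  expect_identical(coords$atoms$residue_name, c("GLU", "GLU"))
  # write -> parse preserves coordinates to PDB precision
  rt <- parse_structure(write_pdb(coords))
  expect_equal(rt$atoms$x, coords$atoms$x, tolerance = 1e-9)
  expect_equal(rt$atoms[c("chain", "residue_id", "atom_name")],
               coords$atoms[c("chain", "residue_id", "atom_name")])
})

test_that("altloc keeps the highest-occupancy conformer", {
  txt <- paste(
    "ATOM      1  CA AGLU A  37      10.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BGLU A  37      20.000   0.000   0.000  0.40  0.00           C",
    sep = "\n")
  coords <- parse_structure(txt)
  expect_identical(nrow(coords$atoms), 1L)
  expect_equal(coords$atoms$x, 10.0)
})

test_that("malformed records are rejected with a line number", {
  expect_error(parse_structure("ATOM      1  CA  GLU A  37"), "line 1")
  bad <- paste(
    "ATOM      1  CA  GLU A  37      11.104   6.134   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLU A  38      xx.xxx   6.134   0.000  1.00  0.00           C",
    sep = "\n")
  expect_error(parse_structure(bad), "line 2")
  expect_error(parse_structure("END"), "no ATOM")
})

test_that("planted contacts are detected with their exact class, no extras", {
  coords <- parse_structure(gen_toy_interface(toy_plants))
  cs <- detect_contacts(coords, "A", "B")
  expect_identical(nrow(cs$contacts), 3L)
  got <- cs$contacts[order(cs$contacts$res_a), ]
  expect_identical(got$class, c("salt_bridge", "hbond", "hydrophobic"))
  expect_equal(got$distance, c(3.0, 2.9, 3.6), tolerance = 1e-3)
  # residue identities carried through (E37 against R653)
  expect_identical(got$res_a[1], 37L)
  expect_identical(got$res_b[1], 653L)
})

test_that("pairs beyond every cutoff yield no contact", {
  far <- list(planted_contact("GLU", "OE1", "ARG", "NH1", 6.0, 37, 653),
              planted_contact("ALA", "CB", "ALA", "CB", 4.5, 50, 700))
  coords <- parse_structure(gen_toy_interface(far))
  cs <- detect_contacts(coords, "A", "B")
  expect_identical(nrow(cs$contacts), 0L)
})

test_that("a carboxylate-amine pair near 4 A is a salt bridge but not an hbond", {
  p <- list(planted_contact("GLU", "OE1", "LYS", "NZ", 3.8, 10, 20))
  cs <- detect_contacts(parse_structure(gen_toy_interface(p)), "A", "B")
  expect_identical(cs$contacts$class, "salt_bridge")
})

test_that("contact detection is symmetric and monotone in cutoffs", {
  coords <- parse_structure(gen_toy_interface(toy_plants))
  ab <- detect_contacts(coords, "A", "B")
  ba <- detect_contacts(coords, "B", "A")
  key_ab <- with(ab$contacts, paste(res_a, atom_a, res_b, atom_b, class))
  key_ba <- with(ba$contacts, paste(res_b, atom_b, res_a, atom_a, class))
  expect_setequal(key_ab, key_ba)
  tight <- detect_contacts(coords, "A", "B",
                           contact_criteria(2.0, 2.5, 2.0))
  expect_lte(nrow(tight$contacts), nrow(ab$contacts))
  expect_error(detect_contacts(coords, "A", "A"), "overlap")
  expect_error(detect_contacts(coords, "A", "C"), "empty")
})

test_that("contacts are invariant under rigid-body motion", {
  coords <- parse_structure(gen_toy_interface(toy_plants))
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(coords$atoms[c("x", "y", "z")]) %*% t(R)
  moved <- coords
  moved$atoms$x <- xyz[, 1] + 12.3
  moved$atoms$y <- xyz[, 2] - 4.5
  moved$atoms$z <- xyz[, 3] + 2.2
  cs0 <- detect_contacts(coords, "A", "B")
  cs1 <- detect_contacts(moved, "A", "B")
  expect_identical(cs1$contacts$class, cs0$contacts$class)
  expect_equal(cs1$contacts$distance, cs0$contacts$distance, tolerance = 1e-6)
})

test_that("interface residue sets and CSP overlap", {
  coords <- parse_structure(gen_toy_interface(toy_plants))
  cs <- detect_contacts(coords, "A", "B")
  ir <- interface_residues(cs)
  expect_identical(ir$A, c(37L, 40L, 43L))
  expect_identical(ir$B, c(653L, 655L, 659L))
  empty <- detect_contacts(parse_structure("END", allow_empty = TRUE),
                           "A", "B")
  expect_length(interface_residues(empty), 0L)
  # planted perturbation exactly on the interface -> Jaccard 1
  residues <- 640:670
  ref <- peak_list(residues, rep(8, length(residues)),
                   rep(120, length(residues)))
  obs <- ref
  obs$dH <- ifelse(residues %in% ir$B, obs$dH + 0.3, obs$dH)
  prof <- classify_residues(compute_csp(ref, obs), csp_threshold = 0.1)
  ov <- csp_overlap(ir$B, prof, what = "shifted")
  expect_equal(ov$jaccard, 1)
  expect_identical(ov$both, ir$B)
  # disjoint numbering warns in notes
  prof_lo <- classify_residues(compute_csp(peak_list(1:5, 1:5, 1:5),
                                           peak_list(1:5, 1:5, 1:5)),
                               csp_threshold = 0.1)
  ov2 <- csp_overlap(ir$B, prof_lo, what = "shifted")
  expect_match(ov2$notes, "numbering")
  expect_equal(ov2$jaccard, 0)
})
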