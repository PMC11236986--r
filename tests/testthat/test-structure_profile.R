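# Complex ingest, contacts, aromatic classification, cavities, superposition,
# residue deviations, MSA masking.

test_that("PDB complexes are read with ligand selection and altloc A", {
  gc <- gen_complex(seed = 17)
  f <- tempfile(fileext = ".pdb")
  write_complex_pdb(gc$complex, f)
  cx <- suppressWarnings(read_complex(f, "LIG"))
  expect_s3_class(cx, "structure_complex")
  expect_equal(nrow(cx$ligand), nrow(gc$complex$ligand))
  expect_equal(nrow(cx$protein), nrow(gc$complex$protein))
  expect_error(suppressWarnings(read_complex(f, "XYZ")), "matches nothing")

  # altloc fixture: two locations for one atom, water to drop
  alt <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  O   HOH A  99       5.000   5.000   5.000  1.00  0.00           O",
    "HETATM    4  C1  LIG L 900       1.000   0.000   0.000  1.00  0.00           C",
    "END"), alt)
  cxa <- suppressWarnings(read_complex(alt, "LIG"))
  expect_equal(nrow(cxa$protein), 1)          # altloc A only, water gone
  expect_equal(cxa$protein$x, 0)
})

test_that("close contacts classify planted polar and apolar pairs", {
  # constructed geometry: N...O at 3.0 -> hydrogen bond; C...C at 5.0 -> none
  cx <- structure(list(
    protein = data.frame(element = c("O", "C"), name = c("OG", "CB"),
                         resid = "SER", resno = 1L, chain = "A",
                         x = c(0, 20), y = 0, z = 0,
                         stringsAsFactors = FALSE),
    ligand = data.frame(element = c("N", "C"), name = c("N1", "C1"),
                        resid = "LIG", resno = 900L, chain = "L",
                        x = c(3, 25), y = 0, z = 0,
                        stringsAsFactors = FALSE),
    metadata = list(source = "toy")), class = "structure_complex")
  cc <- close_contacts(cx)
  expect_equal(nrow(cc), 1)
  expect_identical(cc$class, "hydrogen_bond")
  expect_equal(cc$distance, 3.0)
  # polar pair beyond hbond_max but inside contact_max is a plain contact
  cx$ligand$x[1] <- 3.8
  expect_identical(close_contacts(cx)$class, "close_contact")
  expect_error(close_contacts(structure(list(protein = cx$protein,
    ligand = cx$ligand[0, ], metadata = list()),
    class = "structure_complex")), "empty ligand")
})

test_that("planted contact counts are recovered exactly without rings", {
  gc <- gen_complex(n_hbonds = 4, n_apolar = 2,
                    stacks = data.frame(distance = numeric(0),
                                        angle = numeric(0),
                                        offset = numeric(0)),
                    seed = 23)
  cc <- close_contacts(gc$complex)
  expect_equal(sum(cc$class == "hydrogen_bond"), 4)
  expect_equal(sum(cc$class == "close_contact"), 2)
  s <- interaction_summary(gc$complex)
  expect_equal(s$n_close_contacts, 6)
  expect_equal(s$n_aromatic, 0)
})

test_that("aromatic ring pairs classify by angle and offset", {
  geoms <- list(list(3.5, 0, 0, "parallel"),
                list(3.5, 0, 2.0, "parallel_displaced"),
                list(5.0, 90, 0, "t_shaped"),
                list(4.5, 45, 0, "unclassified"))
  for (g in geoms) {
    gc <- gen_complex(n_hbonds = 0, n_apolar = 0,
                      stacks = data.frame(distance = g[[1]], angle = g[[2]],
                                          offset = g[[3]]), seed = 29)
    ai <- aromatic_interactions(gc$complex)
    expect_equal(nrow(ai), 1)
    expect_identical(ai$class, g[[4]])
    expect_equal(ai$distance, g[[1]], tolerance = 1e-6)
    expect_equal(ai$angle, g[[2]], tolerance = 1e-6)
    expect_equal(ai$offset, g[[3]], tolerance = 1e-6)
  }
  # no rings on either side: empty result, not an error
  none <- gen_complex(n_hbonds = 1, n_apolar = 0,
                      stacks = data.frame(distance = numeric(0),
                                          angle = numeric(0),
                                          offset = numeric(0)), seed = 31)
  expect_equal(nrow(aromatic_interactions(none$complex)), 0)
})

test_that("interaction counts are monotone in their cutoffs", {
  gc <- gen_complex(n_hbonds = 2, n_apolar = 1, seed = 37)
  base <- interaction_summary(gc$complex)
  wide <- interaction_summary(gc$complex, hbond_max = 7, contact_max = 8,
                              d_stack_max = 11)
  expect_gte(wide$n_close_contacts, base$n_close_contacts)
  expect_gte(wide$n_aromatic, base$n_aromatic)
})

test_that("cavity occupancy and the two-of-three criterion", {
  gc <- gen_complex(n_hbonds = 0, n_apolar = 0,
                    stacks = data.frame(distance = numeric(0),
                                        angle = numeric(0),
                                        offset = numeric(0)),
                    cavity_residues = list(C277 = TRUE, Q169 = FALSE,
                                           W241 = TRUE),
                    seed = 41)
  cavs <- list(list(label = "catalytic", residues = "C277"),
               list(label = "surface", residues = "Q169"),
               list(label = "wide", residues = "W241"))
  occ <- cavity_occupancy(gc$complex, cavs)
  expect_setequal(occ$occupied, c("catalytic", "wide"))
  expect_true(occ$two_of_three)
  expect_error(cavity_occupancy(gc$complex,
    list(list(label = "ghost", residues = "K999"))), "ghost")

  far <- gen_complex(n_hbonds = 0, n_apolar = 0,
                     stacks = data.frame(distance = numeric(0),
                                         angle = numeric(0),
                                         offset = numeric(0)),
                     cavity_residues = list(C277 = FALSE, Q169 = FALSE,
                                            W241 = FALSE),
                     seed = 43)
  occ2 <- cavity_occupancy(far$complex, cavs)
  expect_length(occ2$occupied, 0)
  expect_false(occ2$two_of_three)
})

test_that("superposition recovers rigid transforms exactly", {
  cx <- gen_complex(seed = 47)$complex
  expect_lt(superpose(cx, cx)$rmsd, 1e-9)
  shifted <- transform_complex(cx, diag(3), c(5, -3, 2))
  expect_lt(superpose(shifted, cx)$rmsd, 1e-9)
  rot <- rotation_about_z(0.8)
  moved <- transform_complex(cx, rot, c(1, 2, 3))
  fit <- superpose(moved, cx)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$rotation - rot)), 1e-6)   # recovered inverse motion
  # fewer than 3 pairs is an error
  tiny <- cx; tiny$protein <- tiny$protein[1:2, ]
  expect_error(superpose(tiny, tiny), "3 paired atoms")
})

test_that("superposed RMSD is invariant under random rigid motions", {
  cx <- gen_complex(seed = 53)$complex
  jit <- cx
  set.seed(7)
  jit$protein$x <- jit$protein$x + stats::rnorm(nrow(jit$protein), sd = 0.3)
  base_rmsd <- superpose(jit, cx)$rmsd
  for (k in 1:5) {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    moved <- transform_complex(jit, q, stats::rnorm(3, sd = 10))
    expect_equal(superpose(moved, cx)$rmsd, base_rmsd, tolerance = 1e-8)
  }
})

test_that("superposition agrees with the bio3d reference fit", {
  cx <- gen_complex(seed = 59)$complex
  moved <- transform_complex(cx, rotation_about_z(1.1), c(4, 4, -2))
  moved$protein$x <- moved$protein$x + stats::rnorm(nrow(moved$protein),
                                                    sd = 0.2)
  mine <- superpose(moved, cx)$rmsd
  a <- as.numeric(t(as.matrix(cx$protein[, c("x", "y", "z")])))
  b <- as.numeric(t(as.matrix(moved$protein[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = a, mobile = b))
  # bio3d::rmsd rounds to 3 decimals; compare at that precision
  expect_equal(mine, bio3d::rmsd(a, fitted), tolerance = 5e-3)
})

test_that("residue deviations localize a displaced residue", {
  # enough residues that the C-alpha fit is dominated by the unmoved ones
  cx <- gen_complex(n_hbonds = 7, n_apolar = 7, seed = 61)$complex
  copy <- cx
  # displace one residue's atoms by 2 A, leave the rest untouched
  target <- copy$protein$resno == 2
  copy$protein$x[target] <- copy$protein$x[target] + 2
  dev <- residue_deviations(list(cx, copy),
                            residues = c("S1", "S2", "A8"))
  expect_equal(dev["S2", 1], 2, tolerance = 0.2)
  expect_lt(dev["S1", 1], 0.4)
  expect_lt(dev["A8", 1], 0.4)
  # a residue absent from both is flagged missing, run still succeeds
  dev2 <- residue_deviations(list(cx, copy), residues = c("S1", "K999"))
  expect_true(is.na(dev2["K999", 1]))
  expect_gt(length(attr(dev2, "missing")), 0)
  # identical structures give all zeros
  dev3 <- residue_deviations(list(cx, cx), residues = c("S1", "S2"))
  expect_true(all(dev3[, 1] < 1e-9))
})

test_that("bridging sulfur removal only strips covalent-range sulfur", {
  cx <- structure(list(
    protein = data.frame(element = c("S", "C", "C"),
                         name = c("SG", "CB", "CA"), resid = "CYS",
                         resno = 277L, chain = "A",
                         x = c(0, 1.8, 2.8), y = 0, z = 0,
                         stringsAsFactors = FALSE),
    ligand = data.frame(element = c("S", "C"), name = c("S1", "C1"),
                        resid = "LIG", resno = 900L, chain = "L",
                        x = c(2.0, 3.4), y = 0, z = 0,
                        stringsAsFactors = FALSE),
    metadata = list(source = "toy")), class = "structure_complex")
  out <- remove_bridging_sulfur(cx)
  expect_equal(nrow(out$ligand), 1)
  expect_identical(out$ligand$element, "C")
  expect_equal(out$metadata$n_bridging_sulfur_removed, 1L)
})

test_that("alanine masking hits exactly the targeted columns", {
  aln <- c(target = "MKQCVLAQRS", homolog1 = "MKACV-AQRT",
           homolog2 = "MK-CVLAQKS")
  masked <- mask_msa_alanine(aln, "target", 2, 4, expected_letters = NULL)
  expect_identical(unname(masked["target"]), "MAAAVLAQRS")
  expect_identical(unname(masked["homolog1"]), "MAAAV-AQRT")
  expect_identical(unname(masked["homolog2"]), "MA-AVLAQKS")   # gap kept
  expect_equal(attr(masked, "masked_columns"), 2:4)
  expect_identical(nchar(masked), nchar(aln))                  # shape

  # target-only mode leaves homologs untouched
  solo <- mask_msa_alanine(aln, "target", 2, 4, expected_letters = NULL,
                           all_sequences = FALSE)
  expect_identical(unname(solo["homolog1"]), unname(aln["homolog1"]))
})

test_that("masking follows target non-gap numbering across gaps", {
  aln <- c(t = "MK-QCV", h = "MKAQCV")
  masked <- mask_msa_alanine(aln, "t", 2, 4, expected_letters = NULL)
  # target residues 2..4 are K, Q, C at string positions 2, 4, 5
  expect_identical(unname(masked["t"]), "MA-AAV")
  expect_equal(length(attr(masked, "masked_columns")), 3)   # end-start+1
  expect_error(mask_msa_alanine(aln, "t", 2, 99, expected_letters = NULL),
               "exceeds")
  expect_error(mask_msa_alanine(aln, "zz", 2, 4), "not in alignment")
})

test_that("guard letters verify the numbering before masking", {
  tgt <- make_guarded_target()
  aln <- c(P21980 = tgt, hom = tgt)
  masked <- mask_msa_alanine(aln, "P21980")    # defaults: 276..336, Q/C
  expect_equal(length(attr(masked, "masked_columns")), 61)
  chars <- strsplit(masked[["P21980"]], "")[[1]]
  expect_true(all(chars[276:336] == "A"))
  expect_identical(chars[1:275], strsplit(tgt, "")[[1]][1:275])
  # shifting the sequence breaks the guard
  shifted <- c(P21980 = paste0("G", substr(tgt, 1, nchar(tgt) - 1)))
  expect_error(mask_msa_alanine(shifted, "P21980"), "numbering")
})
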