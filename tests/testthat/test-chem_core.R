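# Molecular model, fingerprints, similarity, descriptors, PAINS.

test_that("SMILES parsing canonicalizes, round-trips and rejects garbage", {
  m <- parse_smiles("c1ccccc1")
  expect_s3_class(m, "molecule")
  expect_equal(n_heavy(m), 6)
  expect_equal(n_heavy(parse_smiles("CCO")), 3)
  # canonical SMILES round-trips to itself
  expect_identical(parse_smiles(m$smiles)$smiles, m$smiles)
  expect_error(parse_smiles("C1CC"), "unparseable.*C1CC")
  expect_error(parse_smiles(""), "empty")
})

test_that("salt stripping keeps the largest covalent fragment", {
  m <- parse_smiles("CCO.[Na+]")
  expect_identical(m$smiles, "CCO")
  expect_equal(m$n_fragments_stripped, 1L)
  raw <- parse_smiles("CCO.[Na+]", strip_salts = FALSE)
  expect_equal(raw$n_fragments_stripped, 0L)
})

test_that("circular fingerprints are deterministic and spelling-invariant", {
  spellings <- list(c("OCC", "CCO"),
                    c("Cc1ccccc1", "c1ccccc1C"),
                    c("N#Cc1ccc(F)cc1", "Fc1ccc(cc1)C#N"),
                    c("C1CCN(c2ccccc2)CC1", "c1ccccc1N1CCCCC1"))
  for (pair in spellings) {
    f1 <- circular_fingerprint(parse_smiles(pair[1]))
    f2 <- circular_fingerprint(parse_smiles(pair[2]))
    expect_identical(unclass(f1), unclass(f2), label = pair[1])
  }
  # regenerating from the same molecule is bit-identical
  m <- parse_smiles("COc1ccc2ncccc2c1")
  expect_identical(unclass(circular_fingerprint(m)),
                   unclass(circular_fingerprint(m)))
  expect_gte(sum(circular_fingerprint(parse_smiles("C"))), 1)
  expect_error(circular_fingerprint(m, nbits = 0), "nbits")
  expect_error(circular_fingerprint(m, radius = -1), "radius")
})

test_that("the hashing itself is atom-order independent (raw SDF route)", {
  # bypass canonicalization: build molecules straight from differently
  # ordered SDF blocks and require identical bitsets
  skip_if_not_installed("ChemmineR")
  pairs <- list(c("OCC", "CCO"), c("Cc1ccc(O)cc1", "Oc1ccc(C)cc1"))
  for (pair in pairs) {
    m1 <- chemtriage:::molecule_from_sdf(
      suppressWarnings(ChemmineR::smiles2sdf(pair[1]))[[1]], "a", pair[1])
    m2 <- chemtriage:::molecule_from_sdf(
      suppressWarnings(ChemmineR::smiles2sdf(pair[2]))[[1]], "b", pair[2])
    expect_identical(unclass(circular_fingerprint(m1)),
                     unclass(circular_fingerprint(m2)), label = pair[1])
  }
})

test_that("Tanimoto similarity matches hand counts and its invariants", {
  mkfp <- function(on, nbits = 16L) {
    bits <- logical(nbits); bits[on] <- TRUE
    structure(bits, nbits = nbits, radius = 3L, class = "chemfp")
  }
  expect_equal(tanimoto(mkfp(c(1, 2, 3)), mkfp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(mkfp(1:3), mkfp(1:3)), 1.0)
  expect_equal(tanimoto(mkfp(1:3), mkfp(4:6)), 0.0)
  expect_equal(tanimoto(mkfp(integer(0)), mkfp(integer(0))), 1.0)
  expect_error(tanimoto(mkfp(1, nbits = 16L), mkfp(1, nbits = 32L)),
               "mismatch")
  # symmetry and bounds over random fingerprints
  set.seed(11)
  fps <- random_fps(12)
  for (k in 1:20) {
    ij <- sample.int(12, 2)
    s1 <- tanimoto(fps[[ij[1]]], fps[[ij[2]]])
    s2 <- tanimoto(fps[[ij[2]]], fps[[ij[1]]])
    expect_identical(s1, s2)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
  # distinct molecules are not bit-identical
  fb <- circular_fingerprint(parse_smiles("c1ccccc1"))
  fe <- circular_fingerprint(parse_smiles("CC"))
  expect_lt(tanimoto(fb, fe), 1)
})

test_that("descriptors match hand counts and the substrate oracle", {
  d <- descriptors(parse_smiles("CC"))
  expect_equal(d$rotb, 0)
  expect_equal(descriptors(parse_smiles("CCCC"))$rotb, 1)
  e <- descriptors(parse_smiles("CCO"))
  expect_equal(e$hbd, 1); expect_equal(e$hba, 1)
  # amide C-N exclusion: N-methylacetamide has no rotatable bond by the
  # stated definition (both candidate bonds are amide or terminal)
  expect_equal(descriptors(parse_smiles("CC(=O)NC"))$rotb, 0)

  # oracle equivalence on a 20-molecule panel (counts exact, mw to 0.05 Da,
  # clogp within 0.5 of the substrate's Crippen-type value). Thioethers and
  # secondary aryl amines are excluded: the substrate counts thioether S as
  # an acceptor and drops aryl-NH nitrogens, where the plain Lipinski
  # convention used here (all N/O) does neither.
  panel <- c("CCO", "CC(=O)O", "c1ccccc1O", "c1ccc2ncccc2c1", "CC(N)=O",
             "CCN(CC)CC", "c1ccccc1S(N)(=O)=O", "COc1ccc(Cl)cc1",
             "CC(C)CC(=O)NC", "OCC(O)CO", "c1ccc(-c2ccccc2)cc1",
             "C1CCN(c2ccccc2)CC1", "CC#N", "CCOC(=O)C", "Nc1ccccc1",
             "O=C(O)c1ccccc1N", "FC(F)(F)c1ccccc1", "CNC", "CC(C)=O",
             "c1ccc(-c2nc3ccccc3o2)cc1")
  for (smi in panel) {
    m <- parse_smiles(smi)
    mine <- descriptors(m)
    ob <- ChemmineOB::prop_OB(
      ChemmineOB::forEachMol("SMILES", m$smiles, identity))
    expect_equal(mine$hbd, ob$HBD, label = paste("hbd", smi))
    expect_equal(mine$hba, ob$HBA2, label = paste("hba", smi))
    expect_lt(abs(mine$mw - ob$MW), 0.05, label = paste("mw", smi))
    expect_lt(abs(mine$clogp - ob$logP), 0.5, label = paste("clogp", smi))
  }
})

test_that("rule-of-five verdicts follow the descriptor thresholds", {
  expect_true(ro5_pass(descriptors(parse_smiles("CCO"))))
  # a grossly lipophilic long chain fails on clogP
  expect_false(ro5_pass(descriptors(parse_smiles(
    paste(rep("C", 40), collapse = "")))))
})

test_that("PAINS matching agrees with the substrate substructure engine", {
  pat <- load_pains_patterns()
  expect_gt(nrow(pat), 10)
  expect_length(pains_match(parse_smiles("C"), pat), 0)
  # a pattern molecule matches its own pattern
  quinone <- parse_smiles("O=C1C=CC(=O)C=C1")
  expect_true("quinone_para" %in% pains_match(quinone, pat))
  # embedding: a substituted quinone still matches, and the substrate's
  # SMARTS engine agrees
  embedded <- parse_smiles("CC1=CC(=O)C=CC1=O")
  hits <- pains_match(embedded, pat)
  oracle <- as.numeric(chemtriage:::smarts_count(embedded$smiles,
                                                 "O=C1C=CC(=O)C=C1"))
  expect_identical("quinone_para" %in% hits, oracle > 0)
  # malformed pattern file errors at load with the pattern named
  bad <- tempfile(fileext = ".smarts")
  writeLines(c("ok\tCC", "broken_line_without_tab"), bad)
  expect_error(load_pains_patterns(bad), "malformed")
})

test_that("SMILES tables ingest with warnings for bad rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,ic50", "a,CCO,120", "b,C1CC,50", "c,c1ccccc1,900"),
             f)
  expect_warning(res <- read_smiles_table(f), "unparseable.*b")
  expect_length(res$molecules, 2)
  expect_equal(res$activities$compound_id, c("a", "c"))
})
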