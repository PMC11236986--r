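# Butina clustering, representatives, similarity search, scaffold mining.

test_that("degenerate clustering inputs behave per the sphere-exclusion rule", {
  fp <- circular_fingerprint(parse_smiles("c1ccccc1"))
  one <- butina_cluster(list(fp), 0.4, ids = "only")
  expect_length(one$clusters, 1)
  expect_identical(one$clusters[[1]], "only")
  expect_identical(one$centroids, "only")

  two <- butina_cluster(list(fp, fp), 0.1, ids = c("a", "b"))
  expect_length(two$clusters, 1)
  expect_setequal(two$clusters[[1]], c("a", "b"))
  expect_error(butina_cluster(list(), 0.4), "empty")
  expect_error(butina_cluster(list(fp), 0), "cutoff")
})

test_that("clustering output is always a partition of the input", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(3:15, 1)
    fps <- random_fps(n)
    ids <- paste0("m", seq_len(n))
    ca <- butina_cluster(fps, stats::runif(1, 0.2, 0.8), ids = ids)
    members <- unlist(ca$clusters)
    expect_setequal(members, ids)                   # coverage
    expect_equal(anyDuplicated(members), 0)         # disjointness
    expect_true(all(mapply(function(cl, ce) ce %in% cl,
                           ca$clusters, ca$centroids)))
    expect_true(all(diff(lengths(ca$clusters)) <= 0))  # size-ordered
  }
})

test_that("clustering matches the brute-force sphere-exclusion oracle", {
  set.seed(31)
  for (k in 1:40) {
    n <- sample(2:10, 1)
    fps <- random_fps(n)
    cutoff <- stats::runif(1, 0.2, 0.8)
    mine <- butina_cluster(fps, cutoff)
    oracle <- butina_oracle(fps, cutoff)
    mine_sets <- lapply(mine$clusters, function(m) sort(as.integer(m)))
    expect_identical(partition_key(mine_sets),
                     partition_key(oracle$clusters))
    expect_setequal(as.integer(mine$centroids), oracle$centroids)
  }
})

test_that("stricter distance cutoffs never merge clusters", {
  set.seed(41)
  for (k in 1:8) {
    fps <- random_fps(sample(5:15, 1))
    loose <- butina_cluster(fps, 0.7)
    strict <- butina_cluster(fps, 0.3)
    expect_gte(length(strict$clusters), length(loose$clusters))
  }
})

test_that("representatives are the centroids of the largest clusters", {
  set.seed(51)
  fps <- random_fps(12)
  ca <- butina_cluster(fps, 0.5)
  expect_identical(select_representatives(ca, 3), ca$centroids[1:3])
  expect_identical(select_representatives(ca, 1), ca$centroids[1])
  expect_error(select_representatives(ca, length(ca$clusters) + 1),
               "exceeds")
  expect_error(select_representatives(ca, 0), "top_k")
})

test_that("similarity search agrees with exhaustive recomputation", {
  lib <- gen_library(per_scaffold = 9, seed = 3)
  refs <- lib$molecules[seq(1, 25, by = 5)][1:5]
  cands <- lib$molecules[sample.int(27, 20)]
  hits <- similarity_search(refs, cands, threshold = 0.3)

  rfp <- lapply(refs, circular_fingerprint)
  best_sim <- vapply(cands, function(m) {
    max(vapply(rfp, tanimoto, numeric(1),
               b = circular_fingerprint(m)))
  }, numeric(1))
  expect_setequal(hits$candidate_id,
                  vapply(cands, function(m) m$id, "")[best_sim >= 0.3])
  expect_true(all(hits$similarity >= 0.3))
  # identical candidate is a hit at similarity 1
  h1 <- similarity_search(refs[1], refs[1], threshold = 0.3)
  expect_equal(h1$similarity, 1.0)
  expect_error(similarity_search(list(), refs), "non-empty")
})

test_that("Murcko scaffolds prune to ring systems plus linkers", {
  benzene <- parse_smiles("c1ccccc1")
  expect_identical(murcko_scaffold(benzene)$smiles, benzene$smiles)
  expect_identical(murcko_scaffold(parse_smiles("Cc1ccccc1"))$smiles,
                   benzene$smiles)
  expect_null(murcko_scaffold(parse_smiles("CCCCCC")))
  # linker retained between two rings, decorations pruned
  deco <- parse_smiles("COc1ccc(CN2CCN(c3ccc(F)cc3)CC2)cc1")
  bare <- parse_smiles("c1ccc(CN2CCN(c3ccccc3)CC2)cc1")
  expect_identical(murcko_scaffold(deco)$smiles, bare$smiles)
})

test_that("scaffold extraction is idempotent", {
  lib <- gen_library(per_scaffold = 4, seed = 13)
  for (m in lib$molecules[seq(1, 12, by = 2)]) {
    s1 <- murcko_scaffold(m)
    expect_identical(murcko_scaffold(s1)$smiles, s1$smiles)
  }
})

test_that("scaffold frequency respects the inclusive threshold", {
  # counts {A:5, B:4} at min_count 5 keeps only A
  mols <- c(lapply(1:5, function(i)
    parse_smiles(paste0(c("C", "CC", "CCC", "F", "Cl")[i], "c1ccccc1"),
                 id = paste0("benz", i))),
    lapply(1:4, function(i)
      parse_smiles(paste0(c("C", "CC", "F", "Cl")[i], "c1ccc2ncccc2c1"),
                   id = paste0("quin", i))),
    list(parse_smiles("CCCC", id = "acyclic1")))
  tab <- scaffold_frequency(mols, min_count = 5)
  expect_equal(nrow(tab), 1)
  expect_identical(tab$scaffold_smiles, parse_smiles("c1ccccc1")$smiles)
  expect_equal(tab$frequency, 5)
  expect_equal(attr(tab, "n_acyclic"), 1L)

  all_rows <- scaffold_frequency(mols, min_count = 1)
  expect_equal(nrow(all_rows), 2)
  expect_true(all(diff(all_rows$frequency) <= 0))
  expect_equal(nrow(scaffold_frequency(list(), min_count = 1)), 0)
})

test_that("scaffold overlap reports the exact shared scaffolds", {
  mk <- function(prefixes, scaffold, tag) {
    lapply(seq_along(prefixes), function(i)
      parse_smiles(paste0(prefixes[i], scaffold), id = paste0(tag, i)))
  }
  a <- scaffold_frequency(c(mk(c("C", "F"), "c1ccccc1", "a"),
                            mk(c("C", "F"), "c1ccc2ncccc2c1", "b")), 1)
  b <- scaffold_frequency(c(mk(c("CC", "Cl"), "c1ccc2ncccc2c1", "c"),
                            mk(c("CC", "Cl"), "c1ccc(-c2ccccc2)cc1", "d")), 1)
  ov <- scaffold_overlap(a, b)
  expect_equal(nrow(ov), 1)
  expect_identical(ov$scaffold_smiles, parse_smiles("c1ccc2ncccc2c1")$smiles)
  expect_identical(a$scaffold_smiles[ov$row_a], b$scaffold_smiles[ov$row_b])
  expect_equal(nrow(scaffold_overlap(a, a)), 2)    # identical tables
  disjoint <- scaffold_frequency(mk(c("C", "F"), "c1ccc(-c2ccccc2)cc1",
                                    "e"), 1)
  expect_equal(nrow(scaffold_overlap(a, disjoint)), 0)
})

test_that("generic frameworks collapse heteroatoms behind the flag", {
  pyridine <- parse_smiles("c1ccncc1")
  gen <- murcko_scaffold(pyridine, generic = TRUE)
  expect_false(grepl("n|N", gen$smiles))
})
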