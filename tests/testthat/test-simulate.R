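test_that("zero substitution yields identical proteomes and zero distances", {
  tree <- balanced_guide_tree(4, edge_prob = 0)
  sim <- simulate_proteomes(sim_spec(guide_tree = tree, n_proteins = 3L,
                                     protein_length = 60L, seed = 21))
  seqs <- lapply(sim$proteomes, `[[`, "proteins")
  for (i in 2:4) {
    expect_identical(seqs[[i]], seqs[[1]])
  }
  cvs <- lapply(sim$proteomes, build_cv, k = 3)
  d <- build_distance_matrix(cvs)
  expect_true(all(abs(d) < 1e-12))
})

test_that("simulation is reproducible under a fixed seed", {
  s1 <- simulate_proteomes(sim_spec(n_leaves = 4, n_proteins = 2L,
                                    protein_length = 50L, seed = 33))
  s2 <- simulate_proteomes(sim_spec(n_leaves = 4, n_proteins = 2L,
                                    protein_length = 50L, seed = 33))
  expect_identical(lapply(s1$proteomes, `[[`, "proteins"),
                   lapply(s2$proteomes, `[[`, "proteins"))
  s3 <- simulate_proteomes(sim_spec(n_leaves = 4, n_proteins = 2L,
                                    protein_length = 50L, seed = 34))
  expect_false(identical(lapply(s1$proteomes, `[[`, "proteins"),
                         lapply(s3$proteomes, `[[`, "proteins")))
})

test_that("substitution probabilities outside [0, 0.75] are rejected", {
  tree <- balanced_guide_tree(4, edge_prob = 0.9)
  expect_error(sim_spec(guide_tree = tree), "0.75")
})

test_that("sequence divergence grows with path length in the guide tree", {
  prop_diff <- function(a, b) {
    mean(strsplit(paste(a, collapse = ""), "")[[1]] !=
           strsplit(paste(b, collapse = ""), "")[[1]])
  }
  diffs_sister <- numeric(5)
  diffs_deep <- numeric(5)
  for (r in 1:5) {
    sim <- simulate_proteomes(sim_spec(n_leaves = 8, edge_prob = 0.05,
                                       n_proteins = 5L, protein_length = 100L,
                                       seed = 100 + r))
    ps <- lapply(sim$proteomes, `[[`, "proteins")
    # g01/g02 are sisters (path = 2 edges); g01/g08 span the root (6 edges)
    diffs_sister[r] <- prop_diff(ps$g01, ps$g02)
    diffs_deep[r] <- prop_diff(ps$g01, ps$g08)
  }
  expect_gt(mean(diffs_deep), mean(diffs_sister))
})

test_that("synthesized taxa are exactly clades of the true tree", {
  for (n in c(4, 8, 12)) {
    sim <- simulate_proteomes(sim_spec(n_leaves = n, n_proteins = 2L,
                                       protein_length = 30L, seed = n))
    lt <- sim$lineage
    expect_setequal(lt$genome_id, sim$true_tree$tip.label)
    expect_true(all(lt$complete))
    rep <- full_report(sim$true_tree, lt)
    expect_true(all(rep$status %in% c("monophyletic", "singleton")))
  }
})

test_that("lineage perturbation conserves genomes and reports its moves", {
  sim <- simulate_proteomes(sim_spec(n_leaves = 8, n_proteins = 2L,
                                     protein_length = 30L, seed = 2))
  lt <- sim$lineage

  none <- perturb_lineage(lt, 0)
  expect_equal(none$lineage, lt)
  expect_equal(nrow(none$moves), 0L)

  all_moved <- perturb_lineage(lt, 8, seed = 9)
  expect_equal(sort(all_moved$lineage$genome_id), sort(lt$genome_id))
  expect_equal(nrow(all_moved$moves), 8L)
  expect_error(perturb_lineage(lt, 9), "exceeds")

  one <- perturb_lineage(lt, 1, seed = 5)
  moved <- one$moves$genome_id
  donor <- one$moves$donor_id
  expect_equal(one$lineage$species[one$lineage$genome_id == moved],
               lt$species[lt$genome_id == donor])
  # untouched genomes keep their lineage
  same <- one$lineage$genome_id != moved
  expect_equal(one$lineage[same, ], lt[same, ])
})

test_that("a simulation writes a complete, runnable project directory", {
  dir <- withr::local_tempdir()
  sim <- simulate_proteomes(sim_spec(n_leaves = 4, n_proteins = 2L,
                                     protein_length = 40L, seed = 6))
  write_simulation(sim, dir)
  expect_setequal(
    list.files(dir),
    c(paste0(names(sim$proteomes), ".faa"), "Lineage.txt", "true_tree.nwk")
  )
  p <- read_proteome(file.path(dir, "g01.faa"))
  expect_equal(p$genome_id, "g01")
  expect_identical(p$proteins, sim$proteomes$g01$proteins)
  lt <- read_lineage(file.path(dir, "Lineage.txt"),
                     genome_ids = names(sim$proteomes))
  expect_equal(lt, sim$lineage[match(lt$genome_id, sim$lineage$genome_id), ])
  tt <- read_newick(path = file.path(dir, "true_tree.nwk"))
  expect_equal(oracle_rf(tt, sim$true_tree), 0)
})
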