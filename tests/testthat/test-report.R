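test_that("the report on the true tree finds every synthetic taxon monophyletic", {
  sim <- simulate_proteomes(sim_spec(n_leaves = 8, n_proteins = 2L,
                                     protein_length = 40L, seed = 12))
  rep <- full_report(sim$true_tree, sim$lineage)
  expect_true(all(rep$status %in% c("monophyletic", "singleton")))
  # two phyla by construction of the balanced guide tree
  expect_equal(sum(rep$rank == "phylum"), 2L)
  # sum of convergence clusters equals member count, everywhere
  expect_equal(vapply(rep$clusters, sum, integer(1)), rep$n + rep$m)
})

test_that("a taxon split by the tree is reported convergent with its clusters", {
  t <- read_newick(text = "(((a,b),(c,x)),(d,y));")
  lt <- dplyr::bind_rows(
    lineage_row("a", genus = "Gsplit"), lineage_row("b", genus = "Gsplit"),
    lineage_row("c", genus = "Gsplit"), lineage_row("d", genus = "Gsplit"),
    lineage_row("x", genus = "Other"), lineage_row("y", genus = "Other2")
  )
  rep <- full_report(t, lt)
  g <- rep[rep$name == "Gsplit", ]
  expect_equal(g$status, "convergent")
  expect_equal(g$clusters[[1]], c(2L, 1L, 1L))
  expect_equal(g$rendered, "Gsplit{2/4}, Gsplit{1/4}, Gsplit{1/4}")
  single <- rep[rep$name == "Other", ]
  expect_equal(single$status, "singleton")
})

test_that("the {n + m} split reflects lineage completeness", {
  t <- read_newick(text = "((a,b),(c,d));")
  lt <- dplyr::bind_rows(
    lineage_row("a", domain = "Bac", kingdom = "K", phylum = "P1",
                class = "C", order = "O", family = "F", genus = "G",
                species = "S", strain = "a"),
    lineage_row("b", domain = "Bac", phylum = "P1"),
    lineage_row("c", domain = "Bac", phylum = "P2"),
    lineage_row("d", domain = "Bac", phylum = "P2")
  )
  rep <- full_report(t, lt)
  dom <- rep[rep$name == "Bac", ]
  expect_equal(dom$n, 1L)
  expect_equal(dom$m, 3L)
  expect_equal(dom$rendered, "Bac{1 + 3}")
  p1 <- rep[rep$name == "P1", ]
  expect_equal(p1$rendered, "P1{1 + 1}")
})

test_that("summary counts taxa by status per rank", {
  sim <- simulate_proteomes(sim_spec(n_leaves = 8, n_proteins = 2L,
                                     protein_length = 40L, seed = 3))
  rep <- full_report(sim$true_tree, sim$lineage)
  s <- report_summary(rep)
  expect_equal(sum(s$n_taxa), nrow(rep))
  expect_equal(s$monophyletic + s$convergent + s$singleton, s$n_taxa)
})

test_that("re-reporting after a modification changes only touched taxa", {
  sim <- simulate_proteomes(sim_spec(n_leaves = 8, n_proteins = 2L,
                                     protein_length = 40L, seed = 8))
  t <- sim$true_tree
  lt <- sim$lineage
  base_rep <- full_report(t, lt)

  # reassign one genome wholesale to another genome's lineage
  pert <- perturb_lineage(lt, n_moves = 1, seed = 4)
  victim <- pert$moves$genome_id
  new_rep <- full_report(t, pert$lineage)

  touched <- unique(c(
    unlist(lt[lt$genome_id == victim, cv_ranks]),
    unlist(pert$lineage[pert$lineage$genome_id == victim, cv_ranks])
  ))
  key <- function(r) paste(r$rank, r$name)
  untouched <- setdiff(key(base_rep), key(base_rep)[base_rep$name %in% touched])
  for (kk in untouched) {
    b <- base_rep[key(base_rep) == kk, c("n", "m", "status", "rendered")]
    a <- new_rep[key(new_rep) == kk, c("n", "m", "status", "rendered")]
    expect_equal(a, b)
  }
  # the receiving phylum gains a genome that sits elsewhere in the tree
  recv_phylum <- pert$lineage$phylum[pert$lineage$genome_id == victim]
  donor_phylum_members <- sum(pert$lineage$phylum == recv_phylum)
  recv <- new_rep[new_rep$rank == "phylum" & new_rep$name == recv_phylum, ]
  expect_equal(recv$status, "convergent")
  expect_equal(sum(recv$clusters[[1]]), donor_phylum_members)
  # totals are conserved: per rank, summed n + m equals the genome count
  for (r in c("domain", "phylum")) {
    expect_equal(sum(new_rep$n[new_rep$rank == r] + new_rep$m[new_rep$rank == r]),
                 8L)
  }
})

test_that("report writers emit both formats faithfully", {
  sim <- simulate_proteomes(sim_spec(n_leaves = 4, n_proteins = 2L,
                                     protein_length = 40L, seed = 5))
  rep <- full_report(sim$true_tree, sim$lineage)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_report_tsv(rep, tsv)
  write_report_json(rep, jsn)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(rep))
  expect_equal(back$name, rep$name)
  jx <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  expect_equal(nrow(jx), nrow(rep))
  expect_equal(jx$n + jx$m, rep$n + rep$m)
})
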