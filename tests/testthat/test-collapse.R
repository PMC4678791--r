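test_that("a tree whose genomes share one domain collapses to one node", {
  t <- read_newick(text = "((a,b),(c,d));")
  lt <- dplyr::bind_rows(
    lineage_row("a", domain = "Bacteria", kingdom = "K1", phylum = "P1",
                class = "C1", order = "O1", family = "F1", genus = "G1",
                species = "S1", strain = "a"),
    lineage_row("b", domain = "Bacteria"),
    lineage_row("c", domain = "Bacteria"),
    lineage_row("d", domain = "Bacteria")
  )
  ct <- collapse_tree(t, lt, max_rank = "D")
  expect_equal(nrow(ct$nodes), 1L)
  # one complete + three incomplete genomes -> {1 + 3}
  expect_equal(ct$nodes$label, "<D>Bacteria{1 + 3}")
  expect_setequal(ct$nodes$member_ids[[1]], c("a", "b", "c", "d"))
})

test_that("with nothing shared the collapsed tree is the original tree", {
  t <- read_newick(text = "((a,b),(c,d));")
  lt <- dplyr::bind_rows(
    lineage_row("a", domain = "D1"), lineage_row("b", domain = "D2"),
    lineage_row("c", domain = "D3"), lineage_row("d", domain = "D4")
  )
  # each leaf ends up its own collapsed node at its own domain
  ct <- collapse_tree(t, lt, max_rank = "T")
  expect_equal(nrow(ct$nodes), 4L)
  expect_equal(sort(unlist(ct$nodes$member_ids)), c("a", "b", "c", "d"))
  # topology preserved once labels are mapped back to their single members
  relab <- ct$tree
  relab$tip.label <- vapply(relab$tip.label, function(lab) {
    ct$nodes$member_ids[[match(lab, ct$nodes$label)]]
  }, character(1), USE.NAMES = FALSE)
  expect_equal(oracle_rf(relab, t), 0)
})

test_that("a mixed clade keeps its taxa apart at the licensing rank", {
  # domains left Unclassified so no shared-rank ancestor exists above phylum
  t <- read_newick(text = "(((f1,f2),(t1,t2)),(x1,x2));")
  lt <- dplyr::bind_rows(
    lineage_row("f1", phylum = "Firmicutes"),
    lineage_row("f2", phylum = "Firmicutes"),
    lineage_row("t1", phylum = "Tenericutes"),
    lineage_row("t2", phylum = "Tenericutes"),
    lineage_row("x1", domain = "Arc", phylum = "PX"),
    lineage_row("x2", domain = "Arc", phylum = "PX")
  )
  ct <- collapse_tree(t, lt, max_rank = "P")
  # the Firmicutes/Tenericutes clade yields two collapsed children, not one;
  # the x pair shares its domain, the shallowest rank, and is labelled there
  expect_equal(sort(ct$nodes$name), c("Arc", "Firmicutes", "Tenericutes"))
  expect_equal(ct$nodes$rank[ct$nodes$name == "Arc"], "domain")
  # label arithmetic must match member counts
  expect_equal(ct$nodes$n + ct$nodes$m, lengths(ct$nodes$member_ids))
})

test_that("Unclassified never licenses a collapse", {
  t <- read_newick(text = "((u1,u2),(n1,n2));")
  lt <- dplyr::bind_rows(
    lineage_row("u1"), lineage_row("u2"),   # fully unclassified pair
    lineage_row("n1", domain = "Bac"), lineage_row("n2", domain = "Bac")
  )
  ct <- collapse_tree(t, lt, max_rank = "T")
  # the named pair merges; the unclassified pair must stay two leaves
  expect_equal(sum(ct$nodes$name == "Bac"), 1L)
  expect_true(all(c("u1", "u2") %in% ct$nodes$label))
  expect_equal(nrow(ct$nodes), 3L)
})

test_that("collapse conserves the genome multiset and reflects monophyly", {
  set.seed(404)
  for (case in 1:30) {
    sim <- simulate_proteomes(sim_spec(n_leaves = 8, n_proteins = 2L,
                                       protein_length = 30L, seed = case))
    t <- sim$true_tree
    lt <- if (case %% 2 == 0) {
      perturb_lineage(sim$lineage, n_moves = sample(0:8, 1), seed = case)$lineage
    } else {
      sim$lineage
    }
    ct <- collapse_tree(t, lt, max_rank = sample(names(cv_rank_tags), 1))
    members <- unlist(ct$nodes$member_ids)
    expect_equal(length(members), ape::Ntip(t))          # sum stays at total
    expect_setequal(members, t$tip.label)
    expect_equal(ct$nodes$n + ct$nodes$m, lengths(ct$nodes$member_ids))
  }
})

test_that("a taxon is monophyletic iff collapse at its rank yields one node", {
  set.seed(505)
  for (case in 1:25) {
    t <- random_binary_tree(8, labels = sprintf("g%02d", 1:8))
    # random phylum assignment over two named phyla; the domain is left
    # Unclassified so only the phylum can license a collapse
    phyla <- sample(c("PA", "PB"), 8, replace = TRUE)
    lt <- dplyr::bind_rows(lapply(1:8, function(i) {
      lineage_row(t$tip.label[i], phylum = phyla[i])
    }))
    ct <- collapse_tree(t, lt, max_rank = "P")
    for (ph in unique(phyla)) {
      members <- t$tip.label[phyla == ph]
      st <- monophyly_status(t, members)
      n_nodes <- sum(ct$nodes$name == ph)
      if (st$status %in% c("monophyletic", "singleton")) {
        expect_equal(n_nodes, 1L)
      } else {
        expect_gt(n_nodes, 1L)
      }
    }
  }
})

test_that("the text rendering lists every collapsed node once", {
  t <- read_newick(text = "((a,b),(c,d));")
  # no named domain, so the phyla are the shallowest licensing rank
  lt <- dplyr::bind_rows(
    lineage_row("a", phylum = "X"), lineage_row("b", phylum = "X"),
    lineage_row("c", phylum = "Y"), lineage_row("d", phylum = "Y")
  )
  ct <- collapse_tree(t, lt, max_rank = "P")
  txt <- render_collapsed_text(ct)
  expect_equal(sum(grepl("<P>X", txt, fixed = TRUE)), 1L)
  expect_equal(sum(grepl("<P>Y", txt, fixed = TRUE)), 1L)
})
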