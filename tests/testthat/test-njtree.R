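mat_from <- function(ids, vals) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- vals
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

test_that("three taxa give the unique star tree", {
  d <- mat_from(c("a", "b", "c"), c(2, 3, 4))
  t <- neighbor_joining(d)
  expect_equal(ape::Ntip(t), 3L)
  expect_equal(t$Nnode, 1L)
  expect_setequal(t$tip.label, c("a", "b", "c"))
})

test_that("an additive quartet matrix recovers its generating split", {
  # quartet ((a:1,b:2):1,(c:1,d:3)) -> path distances
  gen <- read_newick(text = "((a:1,b:2):1,(c:1,d:3):0);")
  d <- ape::cophenetic.phylo(gen)
  d <- d[order(rownames(d)), order(colnames(d))]
  t <- neighbor_joining(d)
  # exhaustive check: of the three quartet topologies only ab|cd matches
  quartets <- list(
    "ab|cd" = read_newick(text = "((a,b),(c,d));"),
    "ac|bd" = read_newick(text = "((a,c),(b,d));"),
    "ad|bc" = read_newick(text = "((a,d),(b,c));")
  )
  rf <- vapply(quartets, oracle_rf, numeric(1), t2 = t)
  expect_equal(names(which(rf == 0)), "ab|cd")
})

test_that("ties are broken deterministically toward the first id pair", {
  d <- mat_from(c("b", "d", "a", "c"), rep(1, 6))
  t1 <- neighbor_joining(d)
  # {a, b} is the lexicographically smallest pair, so it must come out as a
  # cherry even though every pair ties on Q
  rt <- ape::root(t1, outgroup = "c", resolve.root = TRUE)
  expect_true(any(vapply(oracle_all_clades(rt), setequal, logical(1),
                         c("a", "b"))))
  # and reordering the matrix must not change the topology
  perm <- c("c", "a", "d", "b")
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(oracle_rf(t1, t2), 0)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(77)
  for (case in 1:40) {
    n <- sample(4:16, 1)
    gen <- random_binary_tree(n)
    d <- ape::cophenetic.phylo(gen)
    ord <- sample(rownames(d))
    d <- d[ord, ord]
    t <- neighbor_joining(d)
    expect_equal(oracle_rf(gen, t), 0)
    # cross-check against an independent NJ implementation
    if (case <= 10) {
      expect_equal(as.integer(phangorn::RF.dist(ape::unroot(t),
                                                ape::unroot(ape::nj(d)))), 0L)
    }
  }
})

test_that("NJ output is invariant under row permutation", {
  set.seed(19)
  cvs <- lapply(sprintf("g%d", 1:6), function(id) {
    build_cv(random_proteome(id, 4L, 30L, 50L), 3)
  })
  d <- build_distance_matrix(cvs)
  t1 <- neighbor_joining(d)
  perm <- sample(rownames(d))
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(oracle_rf(t1, t2), 0)
})

test_that("invalid matrices are rejected", {
  d <- mat_from(c("a", "b", "c"), c(1, 2, 3))
  d_bad <- d; d_bad[1, 2] <- 9
  expect_error(neighbor_joining(d_bad), "symmetric")
  d_na <- d; d_na[1, 2] <- NA; d_na[2, 1] <- NA
  expect_error(neighbor_joining(d_na), "NA")
})

test_that("outgroup rooting respects contiguity and hides on request", {
  quartet <- read_newick(text = "((a,b),(c,d));") |> ape::unroot()
  quartet$edge.length <- rep(1, nrow(quartet$edge))

  r1 <- root_with_outgroup(quartet, "a")
  expect_true(ape::is.rooted(r1))
  sets <- oracle_all_clades(r1)
  expect_true(any(vapply(sets, setequal, logical(1), c("b", "c", "d"))))
  expect_true(any(vapply(sets, setequal, logical(1), c("c", "d"))))

  r2 <- root_with_outgroup(quartet, c("c", "d"))
  sets2 <- oracle_all_clades(r2)
  expect_true(any(vapply(sets2, setequal, logical(1), c("a", "b"))))
  expect_true(any(vapply(sets2, setequal, logical(1), c("c", "d"))))

  hidden <- root_with_outgroup(quartet, "a", hide_outgroup = TRUE)
  expect_setequal(hidden$tip.label, c("b", "c", "d"))

  expect_error(root_with_outgroup(quartet, letters[1:4]), "all leaves")
  expect_error(root_with_outgroup(quartet, c("a", "c")), "not contiguous")
  expect_error(root_with_outgroup(quartet, "zz"), "not in tree")
})

test_that("Newick output is topology-first with quoting, lengths on demand", {
  t <- read_newick(text = "((a,b),(c,d));")
  expect_equal(write_newick(t), "((a,b),(c,d));")

  t$tip.label[1] <- "Candidatus X"
  nwk <- write_newick(t)
  expect_match(nwk, "'Candidatus X'", fixed = TRUE)
  back <- read_newick(text = nwk)
  expect_true("Candidatus X" %in% back$tip.label)

  expect_error(write_newick(t, with_lengths = TRUE), "no branch lengths")
  t$edge.length <- seq_len(nrow(t$edge)) / 7
  nwk_len <- write_newick(t, with_lengths = TRUE)
  expect_match(nwk_len, ":")
  reread <- read_newick(text = nwk_len)
  expect_true(all(is.finite(reread$edge.length)))
})

test_that("parse(write(t)) is isomorphic to t", {
  set.seed(99)
  for (i in 1:20) {
    t <- random_binary_tree(sample(4:12, 1))
    back <- read_newick(text = write_newick(t, with_lengths = TRUE))
    expect_equal(oracle_rf(t, back), 0)
    expect_setequal(back$tip.label, t$tip.label)
  }
})
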