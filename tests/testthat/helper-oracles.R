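# Independent brute-force oracles and tiny fixture builders used across the
# suite. These stay deliberately naive: correctness over speed, and no shared
# code paths with the implementation they check.

# naive window enumeration: loop over proteins and positions with substr
oracle_count_kmers <- function(proteins, k) {
  counts <- new.env(parent = emptyenv())
  total <- 0L
  canon <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (s in proteins) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (all(strsplit(w, "")[[1]] %in% canon)) {
        counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
        total <- total + 1L
      }
    }
  }
  keys <- sort(ls(counts))
  list(counts = stats::setNames(vapply(keys, function(k2) counts[[k2]],
                                       integer(1)), keys),
       total = total)
}

# random proteome over an optionally restricted alphabet
random_proteome <- function(id, n_proteins = 5L, min_len = 1L, max_len = 40L,
                            alphabet = cvphylo::cv_alphabet,
                            p_noncanon = 0) {
  prots <- vapply(seq_len(n_proteins), function(i) {
    len <- sample(min_len:max_len, 1L)
    chars <- sample(alphabet, len, replace = TRUE)
    if (p_noncanon > 0) {
      hit <- stats::runif(len) < p_noncanon
      chars[hit] <- sample(c("X", "B", "Z", "*"), sum(hit), replace = TRUE)
    }
    paste(chars, collapse = "")
  }, character(1))
  proteome(id, prots)
}

# build a composition vector object directly from a named score vector
make_cv <- function(id, k, scores) {
  structure(list(genome_id = id, k = as.integer(k), scores = scores,
                 norm = sqrt(sum(scores^2))),
            class = "cv_composition_vector")
}

# all clades of a rooted tree as leaf-label sets (tips included)
oracle_all_clades <- function(t) {
  ntip <- ape::Ntip(t)
  sets <- lapply(seq_len(ntip), function(i) t$tip.label[i])
  for (node in (ntip + 1L):(ntip + t$Nnode)) {
    sets[[node]] <- ape::extract.clade(t, node)$tip.label
  }
  sets
}

# maximal pure clades by exhaustive enumeration: all clades that are subsets
# of `members` and not contained in a larger such clade
oracle_pure_clades <- function(t, members) {
  sets <- oracle_all_clades(t)
  pure <- Filter(function(s) all(s %in% members), sets)
  maximal <- Filter(function(s) {
    !any(vapply(pure, function(o) length(o) > length(s) && all(s %in% o),
                logical(1)))
  }, pure)
  # drop duplicates (a cherry tip and ... cannot happen, but normalize)
  uniq <- unique(lapply(maximal, function(s) sort(s)))
  stopifnot(setequal(unlist(uniq), members),
            sum(lengths(uniq)) == length(members))
  uniq
}

# unrooted bipartitions (nontrivial splits) as canonical strings: each split
# is represented by its side not containing the alphabetically first label
oracle_splits <- function(t) {
  t <- ape::unroot(t)
  labs <- sort(t$tip.label)
  out <- character(0)
  rt <- ape::root(t, outgroup = labs[1], resolve.root = TRUE)
  pp <- ape::prop.part(rt)
  tips <- attr(pp, "labels")
  for (s in pp) {
    side <- sort(tips[s])
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    if (labs[1] %in% side) {
      side <- sort(setdiff(labs, side))
    }
    if (length(side) <= 1L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

# Robinson-Foulds by symmetric difference of bipartition sets
oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1)
  s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# random rooted binary tree over n labelled leaves with positive edge lengths
random_binary_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  t <- ape::rtree(n, tip.label = sample(labels))
  t$edge.length <- stats::runif(nrow(t$edge), 0.1, 1)
  t
}

# a tiny complete lineage table built from explicit rank values
lineage_row <- function(genome_id, ...) {
  vals <- list(...)
  lin <- stats::setNames(rep(cvphylo::cv_unclassified, 9L), cvphylo::cv_ranks)
  lin[names(vals)] <- unlist(vals)
  tibble::as_tibble(c(list(genome_id = genome_id), as.list(lin),
                      list(complete = !any(lin == cvphylo::cv_unclassified))))
}
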