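#' Specify a proteome simulation
#'
#' A simulation is defined by a guide tree whose edge lengths are per-edge
#' substitution probabilities, a root proteome spec, an amino-acid frequency
#' profile for the root, and a seed. The model is intentionally minimal —
#' independent per-site replacement with a uniform choice among the 19
#' alternative residues, no indels — which is exactly the statistical
#' structure the K-peptide composition signal responds to.
#'
#' @param guide_tree A rooted binary `phylo` tree; `edge.length` entries are
#'   substitution probabilities in `[0, 0.75]`. Defaults to a balanced tree
#'   over `n_leaves` with probability `edge_prob` on every edge.
#' @param n_leaves,edge_prob Used only when `guide_tree` is `NULL`.
#' @param n_proteins Number of proteins in the root proteome (default 200).
#' @param protein_length Length of each root protein (default 300 residues).
#' @param aa_freqs Amino-acid frequency profile for the root proteome; a
#'   named numeric vector over [cv_alphabet] (default uniform). Normalized
#'   internally.
#' @param seed Integer seed; the whole simulation is reproducible given the
#'   spec.
#' @return A list of class `cv_sim_spec`.
#' @export
sim_spec <- function(guide_tree = NULL, n_leaves = 8L, edge_prob = 0.05,
                     n_proteins = 200L, protein_length = 300L,
                     aa_freqs = NULL, seed = 1L) {
  if (is.null(guide_tree)) {
    guide_tree <- balanced_guide_tree(n_leaves, edge_prob)
  }
  stopifnot(inherits(guide_tree, "phylo"))
  if (is.null(guide_tree$edge.length)) {
    stop("guide tree must carry per-edge substitution probabilities",
         call. = FALSE)
  }
  if (any(guide_tree$edge.length < 0) || any(guide_tree$edge.length > 0.75)) {
    stop("substitution probabilities must lie in [0, 0.75]", call. = FALSE)
  }
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep(1 / 20, 20), cv_alphabet)
  }
  if (!setequal(names(aa_freqs), cv_alphabet) || any(aa_freqs < 0)) {
    stop("`aa_freqs` must be a nonnegative profile over the 20 canonical residues",
         call. = FALSE)
  }
  aa_freqs <- aa_freqs[cv_alphabet] / sum(aa_freqs)
  structure(
    list(guide_tree = guide_tree, n_proteins = as.integer(n_proteins),
         protein_length = as.integer(protein_length), aa_freqs = aa_freqs,
         seed = as.integer(seed)),
    class = "cv_sim_spec"
  )
}

#' Balanced guide tree with uniform edge substitution probability
#'
#' @param n_leaves Number of leaves (a power of two gives a fully balanced
#'   shape; otherwise the tree is as balanced as possible).
#' @param edge_prob Substitution probability assigned to every edge.
#' @return A rooted `phylo` tree with leaves `g01, g02, ...`.
#' @export
balanced_guide_tree <- function(n_leaves, edge_prob = 0.05) {
  stopifnot(n_leaves >= 2L)
  build <- function(ids) {
    if (length(ids) == 1L) {
      return(ids)
    }
    h <- ceiling(length(ids) / 2)
    paste0("(", build(ids[seq_len(h)]), ":", edge_prob, ",",
           build(ids[-seq_len(h)]), ":", edge_prob, ")")
  }
  ids <- sprintf("g%02d", seq_len(n_leaves))
  ape::read.tree(text = paste0(build(ids), ";"))
}

#' Simulate proteomes along a guide tree
#'
#' Draws a root proteome from the amino-acid profile, then walks the guide
#' tree from the root, replacing each residue independently with probability
#' equal to the edge's substitution probability (replacement uniform over the
#' other 19 residues). Leaves are emitted as [proteome()] objects. A lineage
#' table is synthesized whose taxa at every rank are exactly clades of the
#' true tree, so ground-truth monophyly is known: running [full_report()]
#' against the true tree must find every named taxon monophyletic (or
#' singleton).
#'
#' @param spec A [sim_spec()].
#' @return A list of class `cv_simulation`: `proteomes` (named list),
#'   `true_tree` (the guide tree, rooted), and `lineage` (lineage tibble).
#' @export
simulate_proteomes <- function(spec) {
  stopifnot(inherits(spec, "cv_sim_spec"))
  set.seed(spec$seed)
  t <- spec$guide_tree
  ntip <- ape::Ntip(t)
  root <- ntip + 1L
  nsites <- spec$n_proteins * spec$protein_length
  root_seq <- sample(cv_alphabet, nsites, replace = TRUE, prob = spec$aa_freqs)
  seqs <- vector("list", ntip + t$Nnode)
  seqs[[root]] <- root_seq
  # preorder walk: parents are simulated before children
  edges <- ape::reorder.phylo(t, "cladewise")$edge
  elens <- ape::reorder.phylo(t, "cladewise")$edge.length
  aa_idx <- stats::setNames(seq_along(cv_alphabet), cv_alphabet)
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]
    ch <- edges[e, 2]
    p <- elens[e]
    s <- seqs[[par]]
    nmut <- stats::rbinom(1L, nsites, p)
    if (nmut > 0L) {
      pos <- sample.int(nsites, nmut)
      shift <- sample.int(19L, nmut, replace = TRUE)
      s[pos] <- cv_alphabet[(aa_idx[s[pos]] - 1L + shift) %% 20L + 1L]
    }
    seqs[[ch]] <- s
  }
  proteomes <- lapply(seq_len(ntip), function(i) {
    chars <- seqs[[i]]
    starts <- (seq_len(spec$n_proteins) - 1L) * spec$protein_length + 1L
    prots <- vapply(starts, function(s0) {
      paste(chars[s0:(s0 + spec$protein_length - 1L)], collapse = "")
    }, character(1))
    proteome(t$tip.label[i], prots)
  })
  names(proteomes) <- t$tip.label
  structure(
    list(proteomes = proteomes, true_tree = t,
         lineage = synthesize_lineage(t)),
    class = "cv_simulation"
  )
}

#' Synthesize a clade-consistent lineage table from a rooted tree
#'
#' Maps the nine ranks onto absolute tree depths spread evenly between the
#' root (domain) and the deepest leaf (strain): the taxon of a genome at rank
#' r is its ancestor at the rank's depth, named after that tree node, or the
#' leaf itself when the leaf is shallower. Because each taxon is "all leaves
#' below one node", every taxon at every rank is exactly a clade of the true
#' tree — the ground truth the monophyly report is checked against.
#'
#' @param t A rooted `phylo` tree.
#' @return A complete lineage tibble over the leaves.
#' @export
synthesize_lineage <- function(t) {
  stopifnot(inherits(t, "phylo"))
  ntip <- ape::Ntip(t)
  parent <- rep(NA_integer_, ntip + t$Nnode)
  parent[t$edge[, 2]] <- t$edge[, 1]
  nranks <- length(cv_ranks)
  paths <- lapply(seq_len(ntip), function(i) {
    path <- i
    while (!is.na(parent[path[1]])) {
      path <- c(parent[path[1]], path)
    }
    path
  })
  maxdepth <- max(lengths(paths)) - 1L
  # rank r lives at depth d_r; d_1 = 0 (root), d_9 = maxdepth (leaves)
  depth_of_rank <- round((seq_len(nranks) - 1L) / (nranks - 1L) * maxdepth)
  rows <- lapply(seq_len(ntip), function(i) {
    path <- paths[[i]]
    leafdepth <- length(path) - 1L
    taxa <- vapply(seq_len(nranks), function(r) {
      node <- path[min(depth_of_rank[r], leafdepth) + 1L]
      if (node <= ntip) {
        if (r == nranks) t$tip.label[node] else paste0(cv_ranks[r], "_", t$tip.label[node])
      } else {
        paste0(cv_ranks[r], "_n", node)
      }
    }, character(1))
    tibble::as_tibble(c(list(genome_id = t$tip.label[i]),
                        stats::setNames(as.list(taxa), cv_ranks),
                        list(complete = TRUE)))
  })
  dplyr::bind_rows(rows)
}

#' Randomly corrupt a lineage table
#'
#' Reassigns `n_moves` distinct genomes to the lineage of another genome from
#' a different species (ranks domain through species are copied; the strain
#' stays the genome's own), so the touched taxa are known to change. The move
#' list records source and donor, letting tests predict which taxa must
#' become convergent.
#'
#' @param lt Lineage tibble.
#' @param n_moves Number of genomes to reassign (`<=` number of genomes).
#' @param seed Integer seed.
#' @return A list: `lineage` (the perturbed tibble; the input is untouched)
#'   and `moves` (tibble with `genome_id`, `donor_id`).
#' @export
perturb_lineage <- function(lt, n_moves, seed = 1L) {
  lt <- validate_lineage_table(lt)
  if (n_moves > nrow(lt)) {
    stop("`n_moves` exceeds the number of genomes", call. = FALSE)
  }
  out <- lt
  if (n_moves == 0L) {
    return(list(lineage = out, moves = tibble::tibble(
      genome_id = character(0), donor_id = character(0))))
  }
  set.seed(seed)
  targets <- sample(lt$genome_id, n_moves)
  donors <- character(n_moves)
  copy_ranks <- cv_ranks[cv_ranks != "strain"]
  for (i in seq_along(targets)) {
    gi <- match(targets[i], out$genome_id)
    other <- which(lt$species != lt$species[gi] & lt$genome_id != targets[i])
    if (length(other) == 0L) {
      other <- setdiff(seq_len(nrow(lt)), gi)
    }
    di <- if (length(other) == 1L) other else sample(other, 1L)
    donors[i] <- lt$genome_id[di]
    for (r in copy_ranks) {
      out[[r]][gi] <- lt[[r]][di]
    }
  }
  out$complete <- lineage_complete(out)
  list(lineage = out, moves = tibble::tibble(genome_id = targets,
                                             donor_id = donors))
}

#' Write a simulation to a project directory
#'
#' Emits one `.faa` file per genome, the `Lineage.txt` annotation, and the
#' true tree (`true_tree.nwk`) into `dir`, ready for [run_project()].
#'
#' @param sim A `cv_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cv_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in sim$proteomes) {
    write_proteome(p, file.path(dir, paste0(p$genome_id, ".faa")))
  }
  write_lineage(sim$lineage, file.path(dir, "Lineage.txt"))
  writeLines(write_newick(sim$true_tree, with_lengths = TRUE),
             file.path(dir, "true_tree.nwk"))
  invisible(dir)
}
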