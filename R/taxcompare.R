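#' Group genomes by taxon at one rank
#'
#' Buckets the project's genomes by their taxon name at `rank`. Buckets are
#' keyed by the full lineage prefix down to `rank` (so two homonymous genera
#' under different families stay distinct) but rendered by name. The
#' `"Unclassified"` sentinel at the rank forms its own bucket. Within a
#' bucket, a genome is counted on the *incomplete* side of the `{n + m}`
#' split iff its full nine-rank lineage is incomplete.
#'
#' @param lt Lineage tibble ([read_lineage()]).
#' @param rank Rank tag (`"P"`) or name (`"phylum"`).
#' @return A tibble with `rank`, `name`, `key`, and list-columns
#'   `complete_ids` / `incomplete_ids`.
#' @export
taxon_members <- function(lt, rank) {
  lt <- validate_lineage_table(lt)
  rname <- resolve_rank(rank)
  if (nrow(lt) == 0L) {
    return(tibble::tibble(rank = character(0), name = character(0),
                          key = character(0), complete_ids = list(),
                          incomplete_ids = list()))
  }
  ridx <- rank_index(rname)
  # bucket key: the chain of *named* ancestors down to the rank, so that
  # homonyms under different named parents stay apart while genomes with an
  # Unclassified intermediate rank still land in their named taxon; all
  # genomes Unclassified at the rank itself form one bucket
  key <- lineage_chain_key(lt, ridx)
  split_idx <- split(seq_len(nrow(lt)), key)
  ord <- order(names(split_idx), method = "radix")
  rows <- lapply(names(split_idx)[ord], function(kk) {
    idx <- split_idx[[kk]]
    tibble::tibble(
      rank = rname,
      name = lt[[rname]][idx[1]],
      key = kk,
      complete_ids = list(lt$genome_id[idx][lt$complete[idx]]),
      incomplete_ids = list(lt$genome_id[idx][!lt$complete[idx]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Monophyly status of a taxon on a rooted tree
#'
#' A taxon is *monophyletic* when all its genomes are represented exclusively
#' by the leaves of a single clade of the tree. Otherwise the taxon's genomes
#' fall into several maximal pure clades (clades whose leaves all belong to
#' the taxon) which together partition its members, and the taxon is
#' *convergent*; a one-genome taxon is flagged *singleton* so summaries are
#' not inflated by trivial monophyly. Convergent taxa are rendered in the
#' `Name{k/n}` notation, one term per cluster of `k` among `n` members.
#'
#' @param t A rooted `phylo` tree.
#' @param members Nonempty character vector of leaf labels belonging to the
#'   taxon.
#' @param rank,name Optional bookkeeping fields copied into the result.
#' @param n_complete,n_incomplete Optional `{n + m}` split of `members`;
#'   default counts all members as complete.
#' @return An object of class `cv_taxon_status`: list with `rank`, `name`,
#'   `n_complete`, `n_incomplete`, `status`
#'   (`"monophyletic"|"convergent"|"singleton"`), `clusters` (sizes of the
#'   maximal pure clades, descending) and `cluster_ids` (their leaf sets).
#' @export
monophyly_status <- function(t, members, rank = NA_character_,
                             name = NA_character_,
                             n_complete = NULL, n_incomplete = NULL) {
  stopifnot(inherits(t, "phylo"))
  members <- unique(as.character(members))
  if (length(members) == 0L) {
    stop("`members` must be nonempty", call. = FALSE)
  }
  bad <- setdiff(members, t$tip.label)
  if (length(bad) > 0L) {
    stop("member id(s) not leaves of the tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  clusters <- pure_clades(t, members)
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, function(s) {
    sort(s, method = "radix")[1]
  }, character(1)), method = "radix")
  clusters <- clusters[ord]
  sizes <- sizes[ord]
  stopifnot(sum(sizes) == length(members))
  status <- if (length(clusters) > 1L) {
    "convergent"
  } else if (length(members) == 1L) {
    "singleton"
  } else {
    "monophyletic"
  }
  if (is.null(n_complete)) {
    n_complete <- length(members)
    n_incomplete <- 0L
  }
  structure(
    list(rank = rank, name = name, n_complete = as.integer(n_complete),
         n_incomplete = as.integer(n_incomplete), status = status,
         clusters = as.integer(sizes), cluster_ids = clusters),
    class = "cv_taxon_status"
  )
}

# Taxon identity key for every genome at rank index `ridx`. Two genomes with
# the same name at the rank belong to one taxon iff their shallower ranks are
# compatible: equal, or Unclassified on at least one side. This keeps
# homonyms under different *named* parents apart while an Unclassified
# intermediate rank never splits a named taxon (so its incomplete members
# still count in the taxon's m). Genomes Unclassified at the rank itself
# share one sentinel bucket per rank. Grouping is a deterministic union-find
# over row order.
lineage_chain_key <- function(lt, ridx) {
  n <- nrow(lt)
  rname <- cv_ranks[ridx]
  if (n == 0L) {
    return(character(0))
  }
  vals <- vapply(cv_ranks[seq_len(ridx)], function(r) lt[[r]], character(n))
  if (n == 1L) {
    vals <- matrix(vals, nrow = 1L)
  }
  at_rank <- vals[, ridx]
  keys <- rep(NA_character_, n)
  keys[at_rank == cv_unclassified] <- paste0(rname, "\r", cv_unclassified)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  shallower <- seq_len(ridx - 1L)
  for (nm in unique(at_rank[at_rank != cv_unclassified])) {
    idx <- which(at_rank == nm)
    if (length(idx) > 1L) {
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          i <- idx[a]
          j <- idx[b]
          vi <- vals[i, shallower]
          vj <- vals[j, shallower]
          compatible <- all(vi == vj | vi == cv_unclassified |
                              vj == cv_unclassified)
          if (compatible) {
            parent[find(j)] <- find(i)
          }
        }
      }
    }
    roots <- vapply(idx, find, integer(1))
    grp <- match(roots, unique(roots))
    keys[idx] <- paste0(rname, "\r", nm, "\r#", grp)
  }
  keys
}

# maximal clades of t whose leaf sets are subsets of `members`; top-down
# greedy descent, so the returned clades are maximal and partition members
pure_clades <- function(t, members) {
  ntip <- ape::Ntip(t)
  sets <- clade_leafsets(t)
  children <- split(t$edge[, 2], t$edge[, 1])
  out <- list()
  walk <- function(node) {
    s <- sets[[node]]
    inside <- s %in% members
    if (all(inside)) {
      out[[length(out) + 1L]] <<- s
    } else if (any(inside)) {
      for (ch in children[[as.character(node)]]) {
        walk(ch)
      }
    }
  }
  walk(ntip + 1L)
  out
}

#' @export
print.cv_taxon_status <- function(x, ...) {
  cat("<cv_taxon_status> ", render_status(x), " [", x$status, "]\n", sep = "")
  invisible(x)
}

# Name{n}, Name{n + m}, or convergent Name{k/n} terms
render_status <- function(x) {
  if (x$status == "convergent") {
    n <- x$n_complete + x$n_incomplete
    paste(sprintf("%s{%d/%d}", x$name, x$clusters, n), collapse = ", ")
  } else {
    paste0(x$name, render_nm(x$n_complete, x$n_incomplete))
  }
}

# the {n + m} bracket: {n} when m = 0, {0 + m} when n = 0
render_nm <- function(n, m) {
  if (m == 0L) {
    sprintf("{%d}", n)
  } else {
    sprintf("{%d + %d}", n, m)
  }
}
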