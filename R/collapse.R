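#' Collapse a tree by shared taxonomy
#'
#' Bottom-up maximal collapsing: an internal node (or leaf) is replaced by a
#' single collapsed node iff all its descendant leaves share one and the same
#' named taxon — identical lineage down to some rank no deeper than
#' `max_rank`, with a name other than `"Unclassified"` at that rank — and no
#' ancestor of the node qualifies. The replacement label uses the shallowest
#' shared rank and carries the `{n + m}` bracket (`n` members with complete
#' lineage, `m` incomplete). Sharing only `"Unclassified"` never licenses a
#' collapse, but incomplete genomes inside a named taxon's clade still count
#' in `m`. Every genome appears exactly once across the collapsed leaves.
#'
#' @param t A rooted `phylo` tree whose leaves are genome ids.
#' @param lt Lineage tibble covering the leaves.
#' @param max_rank Deepest rank allowed to license a collapse (tag or name);
#'   default `"T"` (any rank).
#' @return A list of class `cv_collapsed_tree`: `tree` (a `phylo` whose tip
#'   labels are the collapsed-node labels) and `nodes` (tibble: `label`,
#'   `rank`, `name`, `n`, `m`, list-column `member_ids`).
#' @export
collapse_tree <- function(t, lt, max_rank = "T") {
  stopifnot(inherits(t, "phylo"))
  lt <- validate_lineage_table(lt)
  max_idx <- rank_index(resolve_rank(max_rank))
  miss <- setdiff(t$tip.label, lt$genome_id)
  if (length(miss) > 0L) {
    stop("leaves missing from lineage table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ntip <- ape::Ntip(t)
  children <- split(t$edge[, 2], t$edge[, 1])
  row_of <- match(t$tip.label, lt$genome_id)
  complete <- lt$complete[row_of]
  # taxon identity per leaf and rank: the named-ancestor chain key, shared
  # with taxon_members() so collapse and report agree on what one taxon is
  lt_leaf <- lt[row_of, ]
  prefmat <- vapply(seq_len(length(cv_ranks)), function(r) {
    lineage_chain_key(lt_leaf, r)
  }, character(ntip))
  if (ntip == 1L) {
    prefmat <- matrix(prefmat, nrow = 1L)
  }
  named <- vapply(seq_len(length(cv_ranks)), function(r) {
    lt[[cv_ranks[r]]][row_of] != cv_unclassified
  }, logical(ntip))
  if (ntip == 1L) {
    named <- matrix(named, nrow = 1L)
  }

  # shallowest rank (index) at which all leaves below `node` share a named
  # taxon, or NA if none at ranks <= max_idx
  nodes_tbl <- list()
  shared_rank <- function(tips) {
    for (r in seq_len(max_idx)) {
      if (all(named[tips, r]) && length(unique(prefmat[tips, r])) == 1L) {
        return(r)
      }
    }
    NA_integer_
  }
  make_label <- function(tips, r) {
    nm <- lt[[cv_ranks[r]]][row_of[tips[1]]]
    n <- sum(complete[tips])
    m <- sum(!complete[tips])
    lab <- paste0("<", names(cv_rank_tags)[r], ">", nm, render_nm(n, m))
    nodes_tbl[[length(nodes_tbl) + 1L]] <<- tibble::tibble(
      label = lab, rank = cv_ranks[r], name = nm, n = n, m = m,
      member_ids = list(t$tip.label[tips])
    )
    lab
  }
  tips_below <- function(node) {
    if (node <= ntip) {
      return(node)
    }
    unlist(lapply(children[[as.character(node)]], tips_below))
  }
  rec <- function(node) {
    tips <- tips_below(node)
    r <- shared_rank(tips)
    if (!is.na(r)) {
      return(quote_newick_label(make_label(tips, r)))
    }
    if (node <= ntip) {
      # leaf sharing nothing nameable: keep as a singleton genome leaf
      gid <- t$tip.label[node]
      nodes_tbl[[length(nodes_tbl) + 1L]] <<- tibble::tibble(
        label = gid, rank = NA_character_, name = gid,
        n = sum(complete[node]), m = sum(!complete[node]),
        member_ids = list(gid)
      )
      return(quote_newick_label(gid))
    }
    paste0("(", paste(vapply(children[[as.character(node)]], rec,
                             character(1)), collapse = ","), ")")
  }
  s <- rec(ntip + 1L)
  # a fully collapsed tree is a single labelled node; wrap it so the Newick
  # parser accepts it
  nwk <- if (startsWith(s, "(")) paste0(s, ";") else paste0("(", s, ");")
  ctree <- read_newick(text = nwk)
  nodes <- dplyr::bind_rows(nodes_tbl)
  # conservation: every genome exactly once across collapsed leaves
  all_members <- unlist(nodes$member_ids)
  stopifnot(length(all_members) == ntip, setequal(all_members, t$tip.label))
  structure(list(tree = ctree, nodes = nodes), class = "cv_collapsed_tree")
}

#' @export
print.cv_collapsed_tree <- function(x, ...) {
  cat("<cv_collapsed_tree> ", nrow(x$nodes), " collapsed nodes over ",
      length(unlist(x$nodes$member_ids)), " genomes\n", sep = "")
  cat(render_collapsed_text(x), sep = "\n")
  invisible(x)
}

#' Indented-text rendering of a collapsed tree
#'
#' @param ct A `cv_collapsed_tree`.
#' @param indent Indentation unit.
#' @return Character vector of lines.
#' @export
render_collapsed_text <- function(ct, indent = "  ") {
  t <- ct$tree
  ntip <- ape::Ntip(t)
  children <- split(t$edge[, 2], t$edge[, 1])
  lines <- character(0)
  rec <- function(node, depth) {
    pad <- strrep(indent, depth)
    if (node <= ntip) {
      lines[length(lines) + 1L] <<- paste0(pad, t$tip.label[node])
    } else {
      lines[length(lines) + 1L] <<- paste0(pad, "+")
      for (ch in children[[as.character(node)]]) {
        rec(ch, depth + 1L)
      }
    }
  }
  if (ntip == 1L) {
    rec(1L, 0L)
  } else {
    rec(ntip + 1L, 0L)
  }
  lines
}
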