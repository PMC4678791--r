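#' Neighbor-joining tree inference with deterministic tie-breaking
#'
#' Standard Saitou–Nei neighbor joining: at each step the pair of clusters
#' minimizing the Q-criterion
#' \deqn{Q_{ij} = (n - 2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}}
#' is joined. Exact ties in Q are broken by the lexicographically smallest
#' pair of cluster representatives (each cluster represented by its smallest
#' leaf label), so the output is fully reproducible for a given matrix
#' regardless of row order or scheduling. Estimated branch lengths may be
#' negative and are retained as such — topology, not length, is the product
#' of this method.
#'
#' @param d Symmetric distance matrix with zero diagonal and unique
#'   `dimnames` (at least 3 taxa).
#' @return An unrooted `phylo` tree (class from \pkg{ape}) over all ids, with
#'   edge lengths.
#' @export
neighbor_joining <- function(d) {
  validate_nj_input(d)
  labels <- rownames(d)
  n <- nrow(d)
  # each active cluster: newick fragment (with lengths) + representative label
  frag <- labels
  rep_lab <- labels
  D <- unname(d)
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest sorted representative-label pair
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]), method = "radix")
      paste(p[1], p[2], sep = "\r")
    })
    pick <- cand[order(keys, method = "radix")[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":",
                       fmt(vj), ")")
    new_rep <- sort(c(rep_lab[i], rep_lab[j]), method = "radix")[1]
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    D <- D2
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # connect the last three clusters to one internal node
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(v1), ",", frag[2], ":", fmt(v2),
                ",", frag[3], ":", fmt(v3), ");")
  tr <- ape::read.tree(text = nwk)
  stopifnot(setequal(tr$tip.label, labels))
  tr
}

validate_nj_input <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3L) {
    stop("neighbor joining needs a square matrix over >= 3 taxa", call. = FALSE)
  }
  if (is.null(rownames(d)) || anyDuplicated(rownames(d))) {
    stop("distance matrix must carry unique taxon names", call. = FALSE)
  }
  if (anyNA(d)) {
    stop("distance matrix contains NA/NaN", call. = FALSE)
  }
  if (!all(d == t(d))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  invisible(d)
}

#' Root a tree at a designated outgroup
#'
#' Checks that the outgroup leaves form one side of some edge of the unrooted
#' tree (i.e. are contiguous), then roots on that edge, splitting its length
#' equally between the two sides. Optionally the outgroup leaves are removed
#' from the returned tree so that displayed genome counts cover the ingroup
#' only; the rooting they induced is kept.
#'
#' @param t An unrooted (or rooted) `phylo` tree.
#' @param outgroup_ids Character vector of leaf labels, nonempty, a proper
#'   subset of the leaves.
#' @param hide_outgroup Drop the outgroup leaves from the returned tree
#'   (default `FALSE`).
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(t, outgroup_ids, hide_outgroup = FALSE) {
  stopifnot(inherits(t, "phylo"))
  outgroup_ids <- as.character(outgroup_ids)
  if (length(outgroup_ids) == 0L) {
    stop("outgroup must be nonempty", call. = FALSE)
  }
  missing <- setdiff(outgroup_ids, t$tip.label)
  if (length(missing) > 0L) {
    stop("outgroup id(s) not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (setequal(outgroup_ids, t$tip.label)) {
    stop("outgroup cannot contain all leaves", call. = FALSE)
  }
  rt <- root_at_split(t, outgroup_ids)
  if (is.null(rt)) {
    stop("outgroup {", paste(outgroup_ids, collapse = ", "),
         "} is not contiguous (not monophyletic) on the tree; refusing to force a root",
         call. = FALSE)
  }
  if (hide_outgroup) {
    rt <- ape::drop.tip(rt, outgroup_ids)
  }
  rt
}

# Root an (unrooted) tree on the edge whose removal separates `side` from the
# rest, splitting that edge's length equally between the two root children.
# Returns NULL when no such edge exists (side not contiguous). Works directly
# on the adjacency structure so the result never depends on where ape happens
# to place its basal multifurcation.
root_at_split <- function(t, side) {
  ntip <- ape::Ntip(t)
  nn <- ntip + t$Nnode
  adj <- vector("list", nn)
  elen <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  has_len <- !is.null(t$edge.length)
  for (e in seq_len(nrow(t$edge))) {
    a <- t$edge[e, 1]
    b <- t$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    assign(ekey(a, b), if (has_len) t$edge.length[e] else NA_real_, envir = elen)
  }
  tips_from <- function(start, avoid) {
    seen <- rep(FALSE, nn)
    seen[avoid] <- TRUE
    stack <- start
    tips <- integer(0)
    while (length(stack) > 0L) {
      nd <- stack[1]
      stack <- stack[-1]
      if (seen[nd]) next
      seen[nd] <- TRUE
      if (nd <= ntip) tips <- c(tips, nd)
      stack <- c(stack, adj[[nd]][!seen[adj[[nd]]]])
    }
    sort(tips)
  }
  target <- sort(match(side, t$tip.label))
  split_edge <- NULL
  for (e in seq_len(nrow(t$edge))) {
    a <- t$edge[e, 1]
    b <- t$edge[e, 2]
    if (identical(tips_from(b, a), target)) {
      split_edge <- c(a, b)   # b-side is the outgroup
      break
    }
    if (identical(tips_from(a, b), target)) {
      split_edge <- c(b, a)
      break
    }
  }
  if (is.null(split_edge)) {
    return(NULL)
  }
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  sub_newick <- function(node, parent) {
    kids <- adj[[node]][adj[[node]] != parent]
    body <- if (node <= ntip) {
      quote_newick_label(t$tip.label[node])
    } else {
      paste0("(", paste(vapply(kids, function(k) sub_newick(k, node),
                               character(1)), collapse = ","), ")")
    }
    body
  }
  sub_newick_len <- function(node, parent) {
    L <- get(ekey(node, parent), envir = elen)
    paste0(sub_newick(node, parent), if (has_len) paste0(":", fmt(L)) else "")
  }
  a <- split_edge[1]
  b <- split_edge[2]
  half <- if (has_len) get(ekey(a, b), envir = elen) / 2 else NA_real_
  part <- function(node, parent) {
    kids <- adj[[node]][adj[[node]] != parent]
    body <- if (node <= ntip) {
      quote_newick_label(t$tip.label[node])
    } else {
      paste0("(", paste(vapply(kids, function(k) sub_newick_len(k, node),
                               character(1)), collapse = ","), ")")
    }
    paste0(body, if (has_len) paste0(":", fmt(half)) else "")
  }
  nwk <- paste0("(", part(b, a), ",", part(a, b), ");")
  # a previously rooted input leaves its old root as a degree-2 node
  ape::collapse.singles(read_newick(text = nwk))
}

# TRUE iff `ids` form one side of some edge (a bipartition) of tree t
outgroup_contiguous <- function(t, ids) {
  !is.null(root_at_split(t, unique(ids)))
}

#' Serialize a tree to Newick
#'
#' Topology-first Newick output: branch lengths are omitted by default (the
#' CV method treats branching order, not length, as the result) and emitted
#' at full precision when `with_lengths = TRUE`. Labels containing spaces,
#' parentheses, or other Newick metacharacters are single-quoted.
#'
#' @param t A `phylo` tree.
#' @param with_lengths Emit branch lengths (default `FALSE`).
#' @param digits Significant digits for lengths.
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(t, with_lengths = FALSE, digits = 10) {
  stopifnot(inherits(t, "phylo"))
  ntip <- ape::Ntip(t)
  root <- ntip + 1L
  children <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  el <- t$edge.length
  if (with_lengths && is.null(el)) {
    stop("tree carries no branch lengths", call. = FALSE)
  }
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- quote_newick_label(t$tip.label[node])
    } else {
      kids <- children[[as.character(node)]]
      s <- paste0("(", paste(vapply(kids, function(e) {
        rec(t$edge[e, 2], e)
      }, character(1)), collapse = ","), ")")
    }
    if (with_lengths && !is.na(edge_idx)) {
      s <- paste0(s, ":", formatC(el[edge_idx], format = "g", digits = digits))
    }
    s
  }
  paste0(rec(root, NA_integer_), ";")
}

quote_newick_label <- function(lab) {
  if (grepl("[\\[\\](){},;:'\" \t]", lab, perl = TRUE)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else {
    lab
  }
}

#' Read a Newick tree
#'
#' Wrapper over \pkg{ape}'s reader that also strips the single quotes ape
#' leaves around quoted labels, so `read_newick(write_newick(t))` round-trips
#' labels with spaces.
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path File containing one Newick tree.
#' @return A `phylo` tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(text)) {
    ape::read.tree(text = text)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tr)) {
    stop("could not parse Newick input", call. = FALSE)
  }
  unquote <- function(x) {
    q <- startsWith(x, "'") & endsWith(x, "'") & nchar(x) >= 2L
    x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L), fixed = TRUE)
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) {
    tr$node.label <- unquote(tr$node.label)
  }
  tr
}

# leaf-label sets of every node (tips and internal), rooted tree
clade_leafsets <- function(t) {
  ntip <- ape::Ntip(t)
  nnode <- t$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) {
    sets[[i]] <- t$tip.label[i]
  }
  # edges in postorder so children are filled before parents
  po <- ape::reorder.phylo(t, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}
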