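#' Cosine correlation between two composition vectors
#'
#' The correlation `C` between two sparse composition vectors is their dot
#' product over the shared K-peptides divided by the product of their
#' Euclidean norms, clamped to `[-1, 1]` against floating-point overshoot.
#'
#' @param u,v `cv_composition_vector` objects at the same `k`, both with
#'   positive norm.
#' @return `C` in `[-1, 1]`.
#' @export
cv_cosine <- function(u, v) {
  stopifnot(inherits(u, "cv_composition_vector"),
            inherits(v, "cv_composition_vector"))
  if (u$k != v$k) {
    stop("composition vectors have different k (", u$k, " vs ", v$k, ")",
         call. = FALSE)
  }
  if (u$norm <= 0 || v$norm <= 0) {
    bad <- c(u$genome_id[u$norm <= 0], v$genome_id[v$norm <= 0])
    stop("degenerate (zero-norm) composition vector for genome(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  common <- intersect(names(u$scores), names(v$scores))
  if (length(common) == 0L) {
    return(0)
  }
  # sum() accumulates in extended precision, so the dot product is
  # reproducible for a fixed component order; `common` follows u's sorted
  # peptide order deterministically
  C <- sum(u$scores[common] * v$scores[common]) / (u$norm * v$norm)
  max(-1, min(1, C))
}

#' Dissimilarity between two composition vectors
#'
#' `D = (1 - C) / 2` with `C` the cosine correlation ([cv_cosine()]), so `D`
#' ranges over `[0, 1]`: 0 for identical vectors, 0.5 for orthogonal
#' (e.g. disjoint-support) vectors, 1 for anti-parallel ones.
#'
#' @inheritParams cv_cosine
#' @return `D` in `[0, 1]`.
#' @export
cv_dissimilarity <- function(u, v) {
  (1 - cv_cosine(u, v)) / 2
}

#' Assemble the pairwise distance matrix
#'
#' Computes [cv_dissimilarity()] for every pair, iterating the upper triangle
#' in input id order and mirroring each value, so the matrix is exactly
#' symmetric with a zero diagonal regardless of evaluation order.
#'
#' @param cvs List of >= 3 `cv_composition_vector` objects at one `k` with
#'   unique genome ids.
#' @return A symmetric numeric matrix with `dimnames` the genome ids and
#'   attribute `k`.
#' @export
build_distance_matrix <- function(cvs) {
  if (length(cvs) < 3L) {
    stop("need at least 3 composition vectors (tree inference requires >= 3 taxa)",
         call. = FALSE)
  }
  ids <- vapply(cvs, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) {
    stop("duplicated genome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ks <- vapply(cvs, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) {
    stop("composition vectors mix different k values", call. = FALSE)
  }
  n <- length(cvs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- cv_dissimilarity(cvs[[i]], cvs[[j]])
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  validate_distance_matrix(d)
  attr(d, "k") <- ks[1]
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (anyNA(d)) {
    stop("distance matrix contains NA/NaN", call. = FALSE)
  }
  if (!all(d == t(d))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) {
    stop("distance matrix has nonzero diagonal", call. = FALSE)
  }
  if (any(d < -1e-12) || any(d > 1 + 1e-12)) {
    stop("distance matrix entries outside [0, 1]", call. = FALSE)
  }
  invisible(d)
}

#' Write / read a PHYLIP square distance matrix
#'
#' Relaxed PHYLIP format: first line the number of taxa, then one line per
#' taxon with its name, whitespace, and the full row at full precision. Names
#' are not truncated to 10 characters (relaxed dialect) and must not contain
#' whitespace.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output (or input) file path.
#' @return `write_phylip_dist()` returns `path` invisibly;
#'   `read_phylip_dist()` returns the matrix.
#' @export
write_phylip_dist <- function(d, path) {
  validate_distance_matrix(d)
  ids <- rownames(d)
  if (any(grepl("\\s", ids))) {
    stop("PHYLIP names must not contain whitespace: ",
         paste(ids[grepl("\\s", ids)], collapse = ", "), call. = FALSE)
  }
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(ids[i], paste(formatC(d[i, ], format = "g", digits = 17),
                        collapse = " "))
  }, character(1))
  writeLines(c(format(nrow(d)), rows), path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  body <- lines[1L + seq_len(n)]
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(d) <- list(ids, ids)
  validate_distance_matrix(d)
  d
}
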