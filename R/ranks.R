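#' Taxonomic ranks used throughout cvphylo
#'
#' Lineages carry nine ranks, tagged by single letters in the on-disk format:
#' `<D>` Domain, `<K>` Kingdom, `<P>` Phylum, `<C>` Class, `<O>` Order,
#' `<F>` Family, `<G>` Genus, `<S>` Species and `<T>` sTrain. A missing
#' assignment at any rank is written with the sentinel `"Unclassified"`.
#'
#' @format `cv_rank_tags` is a named character vector mapping tag letter to
#'   rank name; `cv_ranks` is the vector of the nine rank (column) names in
#'   canonical shallow-to-deep order.
#' @name cv_ranks
NULL

#' @rdname cv_ranks
#' @export
cv_rank_tags <- c(
  D = "domain", K = "kingdom", P = "phylum", C = "class", O = "order",
  F = "family", G = "genus", S = "species", T = "strain"
)

#' @rdname cv_ranks
#' @export
cv_ranks <- unname(cv_rank_tags)

#' @rdname cv_ranks
#' @export
cv_unclassified <- "Unclassified"

# Resolve a rank given either a tag letter ("P") or a rank name ("phylum").
# Returns the rank name; errors on anything else.
resolve_rank <- function(rank) {
  if (length(rank) != 1L || !is.character(rank)) {
    stop("`rank` must be a single rank tag or name", call. = FALSE)
  }
  if (rank %in% names(cv_rank_tags)) {
    return(unname(cv_rank_tags[[rank]]))
  }
  low <- tolower(rank)
  if (low %in% cv_ranks) {
    return(low)
  }
  stop("unknown rank: '", rank, "' (use one of ",
       paste(names(cv_rank_tags), collapse = ", "), " or ",
       paste(cv_ranks, collapse = ", "), ")", call. = FALSE)
}

# Index of a rank name in canonical D -> T order.
rank_index <- function(rank_name) match(rank_name, cv_ranks)
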