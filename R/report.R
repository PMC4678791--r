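#' Taxonomy-congruence report over all ranks
#'
#' For every rank from domain down to species (strains are the leaves
#' themselves) and every named taxon with at least one member among the
#' tree's leaves, computes the taxon's [monophyly_status()] on the rooted
#' tree. The report is sorted by rank (shallow to deep) and, within a rank,
#' by descending member count.
#'
#' @param t A rooted `phylo` tree whose leaves are genome ids.
#' @param lt Lineage tibble covering the leaves.
#' @return A tibble with columns `rank`, `name`, `n` (complete-lineage
#'   members), `m` (incomplete), `status`, `n_clusters`, `clusters`
#'   (list-column of descending cluster sizes) and `rendered` (the
#'   `Name{n + m}` / `Name{k/n}` display form).
#' @export
full_report <- function(t, lt) {
  stopifnot(inherits(t, "phylo"))
  lt <- validate_lineage_table(lt)
  lt <- lt[lt$genome_id %in% t$tip.label, ]
  report_ranks <- cv_ranks[cv_ranks != "strain"]
  rows <- list()
  for (rname in report_ranks) {
    tm <- taxon_members(lt, rname)
    tm <- tm[tm$name != cv_unclassified, ]
    for (i in seq_len(nrow(tm))) {
      members <- c(tm$complete_ids[[i]], tm$incomplete_ids[[i]])
      st <- monophyly_status(
        t, members, rank = rname, name = tm$name[i],
        n_complete = length(tm$complete_ids[[i]]),
        n_incomplete = length(tm$incomplete_ids[[i]])
      )
      stopifnot(sum(st$clusters) == st$n_complete + st$n_incomplete)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rank = rname, name = st$name, n = st$n_complete, m = st$n_incomplete,
        status = st$status, n_clusters = length(st$clusters),
        clusters = list(st$clusters), rendered = render_status(st)
      )
    }
  }
  rep <- dplyr::bind_rows(rows)
  if (nrow(rep) == 0L) {
    return(tibble::tibble(rank = character(0), name = character(0),
                          n = integer(0), m = integer(0), status = character(0),
                          n_clusters = integer(0), clusters = list(),
                          rendered = character(0)))
  }
  rep$rank <- factor(rep$rank, levels = report_ranks, ordered = TRUE)
  dplyr::arrange(rep, rank, dplyr::desc(n + m), name)
}

#' Per-rank summary of a taxonomy report
#'
#' Counts monophyletic, convergent and singleton taxa at each rank.
#'
#' @param rep A report tibble from [full_report()].
#' @return A tibble with one row per rank: `rank`, `n_taxa`, `monophyletic`,
#'   `convergent`, `singleton`.
#' @export
report_summary <- function(rep) {
  rep |>
    dplyr::group_by(.data$rank) |>
    dplyr::summarise(
      n_taxa = dplyr::n(),
      monophyletic = sum(.data$status == "monophyletic"),
      convergent = sum(.data$status == "convergent"),
      singleton = sum(.data$status == "singleton"),
      .groups = "drop"
    )
}

#' Write a taxonomy report as TSV or JSON
#'
#' The TSV carries `rank`, `name`, `n`, `m`, `status` and the cluster sizes
#' joined by `/`; the JSON mirrors the tibble including the cluster vectors.
#'
#' @param rep Report tibble from [full_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(rep, path) {
  flat <- data.frame(
    rank = as.character(rep$rank), name = rep$name, n = rep$n, m = rep$m,
    status = rep$status,
    clusters = vapply(rep$clusters, paste, character(1), collapse = "/"),
    rendered = rep$rendered,
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(rep, path) {
  obj <- lapply(seq_len(nrow(rep)), function(i) {
    list(rank = as.character(rep$rank[i]), name = rep$name[i],
         n = rep$n[i], m = rep$m[i], status = rep$status[i],
         clusters = rep$clusters[[i]], rendered = rep$rendered[i])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
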