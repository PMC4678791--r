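#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into one report tibble
#'
#' Binds the per-K taxonomy reports into a single tibble with a leading `k`
#' column, ready for dplyr/ggplot2 work.
#'
#' @param x A `cv_run` from [run_project()].
#' @param ... Unused.
#' @return A tibble: `k`, `rank`, `name`, `n`, `m`, `status`, `n_clusters`,
#'   `clusters`, `rendered`.
#' @method tidy cv_run
#' @export
tidy.cv_run <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$per_k), function(kk) {
    r <- x$per_k[[kk]]$report
    dplyr::bind_cols(tibble::tibble(k = as.integer(rep(kk, nrow(r)))), r)
  }))
}

#' One-row-per-K overview of a pipeline run
#'
#' @param x A `cv_run` from [run_project()].
#' @param ... Unused.
#' @return A tibble with per-K counts of taxa by monophyly status and the
#'   number of genomes.
#' @method glance cv_run
#' @export
glance.cv_run <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$per_k), function(kk) {
    r <- x$per_k[[kk]]$report
    tibble::tibble(
      k = as.integer(kk),
      n_genomes = ape::Ntip(x$per_k[[kk]]$rooted),
      n_taxa = nrow(r),
      monophyletic = sum(r$status == "monophyletic"),
      convergent = sum(r$status == "convergent"),
      singleton = sum(r$status == "singleton")
    )
  }))
}

#' Plot the monophyly report of a run
#'
#' A tile map of taxa (rows, grouped by rank) against peptide length K,
#' colored by monophyly status — the at-a-glance answer to "which taxa are
#' recovered, and at which K".
#'
#' @param object A `cv_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_run
#' @export
autoplot.cv_run <- function(object, ...) {
  td <- tidy(object)
  td$taxon <- paste0("<", names(cv_rank_tags)[match(as.character(td$rank),
                                                    cv_ranks)], ">", td$name)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$k), y = .data$taxon,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::facet_grid(rank ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "peptide length K", y = NULL, fill = "status") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.cv_run <- function(x, ...) {
  g <- glance(x)
  cat("<cv_run> ", g$n_genomes[1], " genomes, K = ",
      paste(g$k, collapse = ","), "\n", sep = "")
  print(g)
  invisible(x)
}
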