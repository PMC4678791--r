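#' Configure a cvphylo project
#'
#' Collects everything a run needs: where the proteomes and lineage
#' annotations live, which peptide lengths to compute, the outgroup, and
#' output options. Composition vectors are computed for every `k` in
#' `k_values` in a single run; watching how the branching order changes with
#' K is part of the method's quality control, and K values of 5–6 are the
#' usual choice for prokaryotic proteomes.
#'
#' @param genome_paths Character vector of protein FASTA paths, or `NULL`
#'   when `proteomes` is given.
#' @param proteomes Optional named list of in-memory [proteome()] objects
#'   (takes precedence over `genome_paths`).
#' @param lineage_path Path to the lineage file (optional; absent genomes get
#'   all-`"Unclassified"` lineages).
#' @param mods_path Optional lineage-modification file.
#' @param use_modified_lineage Apply `mods_path` before reporting.
#' @param k_values Integer vector of peptide lengths, all `>= 3` (default
#'   `3:8`).
#' @param outgroup Optional character vector of genome ids used to root each
#'   tree.
#' @param hide_outgroup Drop outgroup leaves from reported trees.
#' @param collapse_rank Deepest rank licensing a collapse (default `"T"`).
#' @param with_lengths Also write Newick with branch lengths.
#' @param out_dir Output directory; `NULL` disables file output.
#' @return A list of class `cv_project_config`.
#' @export
project_config <- function(genome_paths = NULL, proteomes = NULL,
                           lineage_path = NULL, mods_path = NULL,
                           use_modified_lineage = FALSE, k_values = 3:8,
                           outgroup = NULL, hide_outgroup = FALSE,
                           collapse_rank = "T", with_lengths = FALSE,
                           out_dir = NULL) {
  k_values <- sort(unique(as.integer(k_values)))
  if (length(k_values) == 0L || any(k_values < 3L)) {
    stop("`k_values` must all be >= 3", call. = FALSE)
  }
  if (is.null(proteomes) && (is.null(genome_paths) || length(genome_paths) < 3L)) {
    stop("need at least 3 genomes (paths or in-memory proteomes)", call. = FALSE)
  }
  if (!is.null(proteomes) && length(proteomes) < 3L) {
    stop("need at least 3 genomes (paths or in-memory proteomes)", call. = FALSE)
  }
  structure(
    list(genome_paths = genome_paths, proteomes = proteomes,
         lineage_path = lineage_path, mods_path = mods_path,
         use_modified_lineage = isTRUE(use_modified_lineage),
         k_values = k_values, outgroup = outgroup,
         hide_outgroup = isTRUE(hide_outgroup),
         collapse_rank = collapse_rank, with_lengths = isTRUE(with_lengths),
         out_dir = out_dir),
    class = "cv_project_config"
  )
}

#' Run the full composition-vector pipeline
#'
#' For each configured `k`: build composition vectors (cached on disk when an
#' output directory is set), assemble the distance matrix, infer the
#' neighbor-joining tree, root it (outgroup if given, midpoint otherwise),
#' collapse it by lineage, and produce the taxonomy-congruence report.
#' Finally a cross-K summary records, per taxon, at which K values it is
#' monophyletic — a taxon monophyletic for at least one K is considered
#' well supported. The run is fully deterministic for a fixed configuration:
#' rerunning produces byte-identical outputs.
#'
#' @param cfg A [project_config()].
#' @return A list of class `cv_run`: `per_k` (named list with `cv`, `dist`,
#'   `tree` (unrooted NJ), `rooted`, `collapsed`, `report` per k), `summary`
#'   (cross-K monophyly tibble), `lineage` (the lineage table used) and
#'   `config`.
#' @export
run_project <- function(cfg) {
  stopifnot(inherits(cfg, "cv_project_config"))
  proteomes <- cfg$proteomes
  if (is.null(proteomes)) {
    proteomes <- lapply(cfg$genome_paths, read_proteome)
  }
  ids <- vapply(proteomes, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) {
    stop("duplicated genome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(proteomes) <- ids
  lt <- if (!is.null(cfg$lineage_path)) {
    read_lineage(cfg$lineage_path, genome_ids = ids)
  } else {
    empty <- tibble::as_tibble(c(
      list(genome_id = character(0)),
      stats::setNames(rep(list(character(0)), length(cv_ranks)), cv_ranks),
      list(complete = logical(0))
    ))
    align_lineage(empty, ids)
  }
  if (cfg$use_modified_lineage && !is.null(cfg$mods_path)) {
    lt <- apply_modifications(lt, read_lineage_mods(cfg$mods_path))
  }
  out_dir <- cfg$out_dir
  cache_dir <- if (!is.null(out_dir)) file.path(out_dir, "cv_cache") else NULL
  # one counting pass per genome covering every length any k needs
  needed <- sort(unique(unlist(lapply(cfg$k_values, function(k) (k - 2L):k))))
  counts_by_genome <- lapply(proteomes, count_kmer_range, ks = needed)
  per_k <- list()
  for (k in cfg$k_values) {
    message("cvphylo: k=", k, " building composition vectors for ",
            length(proteomes), " genomes")
    cvs <- lapply(ids, function(id) {
      cv <- build_cv(proteomes[[id]], k, counts = counts_by_genome[[id]])
      if (!is.null(cache_dir)) {
        dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
        write_cv_cache(cv, file.path(
          cache_dir, paste0(proteome_hash(proteomes[[id]]), "_k", k, ".tsv")))
      }
      cv
    })
    d <- build_distance_matrix(cvs)
    tr <- neighbor_joining(d)
    rooted <- if (!is.null(cfg$outgroup)) {
      root_with_outgroup(tr, cfg$outgroup, hide_outgroup = cfg$hide_outgroup)
    } else {
      phangorn::midpoint(tr)
    }
    lt_rep <- lt[lt$genome_id %in% rooted$tip.label, ]
    collapsed <- collapse_tree(rooted, lt_rep, max_rank = cfg$collapse_rank)
    rep <- full_report(rooted, lt_rep)
    if (!is.null(out_dir)) {
      kdir <- file.path(out_dir, paste0("k", k))
      dir.create(kdir, recursive = TRUE, showWarnings = FALSE)
      write_phylip_dist(d, file.path(kdir, "distance.phylip"))
      writeLines(write_newick(tr), file.path(kdir, "nj_unrooted.nwk"))
      writeLines(write_newick(rooted), file.path(kdir, "tree.nwk"))
      if (cfg$with_lengths) {
        writeLines(write_newick(rooted, with_lengths = TRUE),
                   file.path(kdir, "tree_with_lengths.nwk"))
      }
      writeLines(write_newick(collapsed$tree),
                 file.path(kdir, "collapsed.nwk"))
      writeLines(render_collapsed_text(collapsed),
                 file.path(kdir, "collapsed.txt"))
      write_report_tsv(rep, file.path(kdir, "report.tsv"))
      write_report_json(rep, file.path(kdir, "report.json"))
    }
    per_k[[as.character(k)]] <- list(cv = cvs, dist = d, tree = tr,
                                     rooted = rooted, collapsed = collapsed,
                                     report = rep)
  }
  summary <- cross_k_summary(per_k)
  if (!is.null(out_dir)) {
    utils::write.table(
      summary_flat(summary), file.path(out_dir, "summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  structure(list(per_k = per_k, summary = summary, lineage = lt, config = cfg),
            class = "cv_run")
}

# per taxon: at which k values is it monophyletic (singletons count as
# trivially monophyletic)
cross_k_summary <- function(per_k) {
  reps <- lapply(names(per_k), function(k) {
    r <- per_k[[k]]$report
    tibble::tibble(k = as.integer(k), rank = as.character(r$rank),
                   name = r$name, n = r$n, m = r$m,
                   mono = r$status %in% c("monophyletic", "singleton"))
  })
  combined <- dplyr::bind_rows(reps)
  if (nrow(combined) == 0L) {
    return(tibble::tibble(rank = character(0), name = character(0),
                          n = integer(0), m = integer(0),
                          monophyletic_at = list(),
                          n_k_monophyletic = integer(0),
                          any_k_monophyletic = logical(0)))
  }
  combined |>
    dplyr::group_by(.data$rank, .data$name) |>
    dplyr::summarise(
      n = max(.data$n), m = max(.data$m),
      monophyletic_at = list(sort(.data$k[.data$mono])),
      n_k_monophyletic = sum(.data$mono),
      any_k_monophyletic = any(.data$mono),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$rank, cv_ranks), dplyr::desc(.data$n + .data$m),
                   .data$name)
}

summary_flat <- function(s) {
  data.frame(
    rank = s$rank, name = s$name, n = s$n, m = s$m,
    monophyletic_at = vapply(s$monophyletic_at, paste, character(1),
                             collapse = ","),
    any_k_monophyletic = s$any_k_monophyletic,
    stringsAsFactors = FALSE
  )
}

#' Pairwise Robinson–Foulds distances between per-K trees
#'
#' Quantifies how the branching order moves as the peptide length changes:
#' identical topologies give 0, and each differing bipartition adds one per
#' tree.
#'
#' @param trees Named list of `phylo` trees over the identical leaf set
#'   (typically one per k).
#' @return A symmetric integer matrix of RF distances with the list names as
#'   dimnames.
#' @export
compare_k_topologies <- function(trees) {
  if (length(trees) < 2L) {
    stop("need at least two trees to compare", call. = FALSE)
  }
  leaves <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leaves, identical, logical(1), leaves[[1]]))) {
    stop("trees do not share an identical leaf set", call. = FALSE)
  }
  n <- length(trees)
  nm <- names(trees)
  if (is.null(nm)) {
    nm <- as.character(seq_len(n))
  }
  rf <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- as.integer(phangorn::RF.dist(ape::unroot(trees[[i]]),
                                        ape::unroot(trees[[j]])))
      rf[i, j] <- v
      rf[j, i] <- v
    }
  }
  rf
}
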