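#' Build a background-subtracted composition vector
#'
#' The composition vector of a proteome at peptide length `k` scores every
#' observed K-peptide `w` by the relative deviation of its observed frequency
#' `f(w)` from the Markov-predicted background `q(w)` (see
#' [markov_expected()]):
#'
#' \deqn{a(w) = \frac{f(w) - q(w)}{q(w)} \quad (q(w) > 0), \qquad a(w) = 0
#'       \quad (q(w) = 0).}
#'
#' The subtraction suppresses the neutral-mutation background so that the
#' remaining signal reflects selection. Peptides never observed at length `k`
#' are absent from the sparse vector even when their predicted background is
#' positive. The Euclidean norm of the scores is precomputed and stored.
#'
#' @param p A [proteome()].
#' @param k Peptide length, an integer >= 3 (the background model needs
#'   k-2 >= 1).
#' @param counts Optional precomputed list of `cv_kmer_counts` indexed by
#'   length (as produced by [count_kmer_range()]); lengths `k`, `k-1`, `k-2`
#'   are used. When omitted they are counted here.
#' @return An object of class `cv_composition_vector`: list with `genome_id`,
#'   `k`, `scores` (named numeric, sparse over observed peptides) and `norm`.
#' @examples
#' build_cv(proteome("toy", "AAAC"), k = 3)
#' @export
build_cv <- function(p, k, counts = NULL) {
  stopifnot(inherits(p, "cv_proteome"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 3 || k != round(k)) {
    stop("`k` must be a single integer >= 3", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.null(counts)) {
    counts <- count_kmer_range(p, (k - 2L):k)
  }
  ck <- counts[[as.character(k)]]
  ck1 <- counts[[as.character(k - 1L)]]
  ck2 <- counts[[as.character(k - 2L)]]
  if (is.null(ck) || is.null(ck1) || is.null(ck2)) {
    stop("`counts` must cover lengths k, k-1, k-2", call. = FALSE)
  }
  for (cc in list(ck, ck1, ck2)) {
    if (cc$total_windows == 0L) {
      stop("genome '", p$genome_id, "' is degenerate: no countable windows at ",
           "peptide length ", cc$k, call. = FALSE)
    }
  }
  peptides <- names(ck$counts)
  f <- as.numeric(ck$counts) / ck$total_windows
  q <- markov_expected(ck1, ck2, peptides)
  a <- numeric(length(peptides))
  pos <- q > 0
  a[pos] <- (f[pos] - q[pos]) / q[pos]
  scores <- stats::setNames(a, peptides)
  structure(
    list(genome_id = p$genome_id, k = k, scores = scores,
         norm = sqrt(sum(a * a))),
    class = "cv_composition_vector"
  )
}

#' Count K-peptides at several lengths in one pass over a proteome
#'
#' @param p A [proteome()].
#' @param ks Integer vector of peptide lengths.
#' @return Named list of `cv_kmer_counts`, names being the lengths.
#' @export
count_kmer_range <- function(p, ks) {
  ks <- sort(unique(as.integer(ks)))
  out <- lapply(ks, function(k) count_kmers(p, k))
  stats::setNames(out, as.character(ks))
}

#' @export
print.cv_composition_vector <- function(x, ...) {
  cat("<cv_composition_vector> ", x$genome_id, " k=", x$k, ": ",
      length(x$scores), " components, norm=", format(x$norm), "\n", sep = "")
  invisible(x)
}

#' Build composition vectors for many genomes, with optional caching
#'
#' Computes one composition vector per proteome at each requested `k`. With a
#' `cache_dir`, each vector is stored as a plain-text table keyed by the
#' proteome's content hash and `k`, so re-runs over a different K subset
#' reuse prior work.
#'
#' @param proteomes List of [proteome()] objects.
#' @param k Single peptide length.
#' @param cache_dir Optional directory for the on-disk CV cache.
#' @return List of `cv_composition_vector`, one per proteome, input order.
#' @export
build_cvs <- function(proteomes, k, cache_dir = NULL) {
  lapply(proteomes, function(p) {
    if (!is.null(cache_dir)) {
      key <- file.path(cache_dir, paste0(proteome_hash(p), "_k", k, ".tsv"))
      if (file.exists(key)) {
        return(read_cv_cache(key, p$genome_id, k))
      }
      cv <- build_cv(p, k)
      dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
      write_cv_cache(cv, key)
      return(cv)
    }
    build_cv(p, k)
  })
}

# cache format: two tab-separated columns, peptide and score (full precision)
write_cv_cache <- function(cv, path) {
  lines <- c(
    paste0("#cvphylo\t", cv$k),
    paste(names(cv$scores), formatC(cv$scores, format = "g", digits = 17),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

read_cv_cache <- function(path, genome_id, k) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[-1]
  if (length(body) == 0L) {
    scores <- stats::setNames(numeric(0), character(0))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    scores <- stats::setNames(
      as.numeric(vapply(parts, `[[`, character(1), 2L)),
      vapply(parts, `[[`, character(1), 1L)
    )
  }
  structure(
    list(genome_id = genome_id, k = as.integer(k), scores = scores,
         norm = sqrt(sum(scores^2))),
    class = "cv_composition_vector"
  )
}
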