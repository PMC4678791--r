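#' Count K-peptides in a proteome
#'
#' Slides a length-`k` window over every protein independently — windows never
#' span protein boundaries — and tallies each peptide. Windows containing any
#' symbol outside the canonical 20-letter alphabet (ambiguity codes, `U`,
#' `O`, `*`, gaps) are skipped; proteins shorter than `k` contribute nothing.
#'
#' @param p A [proteome()].
#' @param k Peptide length, an integer >= 1.
#' @return An object of class `cv_kmer_counts`: list with `k`, `counts`
#'   (named integer vector, names sorted), and `total_windows`
#'   (`sum(counts)`).
#' @examples
#' count_kmers(proteome("g", "MAMA"), 2)  # MA:2, AM:1
#' @export
count_kmers <- function(p, k) {
  stopifnot(inherits(p, "cv_proteome"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  wins <- extract_windows(p$proteins, k)
  if (length(wins) > 0L) {
    wins <- wins[!grepl(noncanonical_re, wins)]
  }
  if (length(wins) == 0L) {
    counts <- stats::setNames(integer(0), character(0))
  } else {
    tab <- table(wins)
    counts <- stats::setNames(as.integer(tab), names(tab))
    counts <- counts[order(names(counts))]
  }
  structure(
    list(k = k, counts = counts, total_windows = sum(counts)),
    class = "cv_kmer_counts"
  )
}

# all length-k windows of each sequence, concatenated
extract_windows <- function(seqs, k) {
  lens <- nchar(seqs)
  seqs <- seqs[lens >= k]
  lens <- lens[lens >= k]
  if (length(seqs) == 0L) {
    return(character(0))
  }
  unlist(lapply(seq_along(seqs), function(i) {
    n <- lens[i]
    substring(seqs[i], 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

#' @export
print.cv_kmer_counts <- function(x, ...) {
  cat("<cv_kmer_counts> k=", x$k, ": ", length(x$counts),
      " distinct peptides over ", x$total_windows, " windows\n", sep = "")
  invisible(x)
}

#' Markov-predicted K-peptide frequencies
#'
#' The neutral background model: the expected frequency of a K-peptide
#' `a1..aK` under a (K-2)-th order Markov chain fitted to the same proteome,
#'
#' \deqn{q(a_1 \dots a_K) = \frac{f(a_1 \dots a_{K-1}) \, f(a_2 \dots a_K)}
#'                               {f(a_2 \dots a_{K-1})}}
#'
#' where each `f` is a window count divided by its own total window count.
#' The prediction is 0 whenever either (K-1)-mer is unobserved or the interior
#' (K-2)-mer is unobserved.
#'
#' @param c_k1 `cv_kmer_counts` at length `k - 1` for the proteome.
#' @param c_k2 `cv_kmer_counts` at length `k - 2` for the same proteome.
#' @param peptides Character vector of K-peptides (all the same length `k`).
#' @return Numeric vector of predicted frequencies, one per peptide.
#' @export
markov_expected <- function(c_k1, c_k2, peptides) {
  stopifnot(inherits(c_k1, "cv_kmer_counts"), inherits(c_k2, "cv_kmer_counts"))
  if (length(peptides) == 0L) {
    return(numeric(0))
  }
  k <- unique(nchar(peptides))
  if (length(k) != 1L || k < 3L) {
    stop("peptides must share one length k >= 3", call. = FALSE)
  }
  if (c_k1$k != k - 1L || c_k2$k != k - 2L) {
    stop("count tables must have lengths k-1 and k-2 (got ", c_k1$k, ", ",
         c_k2$k, " for k=", k, ")", call. = FALSE)
  }
  if (c_k1$total_windows == 0L || c_k2$total_windows == 0L) {
    return(rep(0, length(peptides)))
  }
  pre <- lookup_counts(c_k1$counts, substr(peptides, 1L, k - 1L))
  suf <- lookup_counts(c_k1$counts, substr(peptides, 2L, k))
  mid <- lookup_counts(c_k2$counts, substr(peptides, 2L, k - 1L))
  f_pre <- pre / c_k1$total_windows
  f_suf <- suf / c_k1$total_windows
  f_mid <- mid / c_k2$total_windows
  q <- numeric(length(peptides))
  ok <- pre > 0L & suf > 0L & mid > 0L
  q[ok] <- f_pre[ok] * f_suf[ok] / f_mid[ok]
  q
}

lookup_counts <- function(counts, keys) {
  v <- counts[match(keys, names(counts))]
  v[is.na(v)] <- 0L
  as.integer(v)
}
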