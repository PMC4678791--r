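#' The canonical amino-acid alphabet
#'
#' The twenty standard residues. K-peptide windows containing anything else
#' (ambiguity codes `X B Z J`, the rare `U O`, stop `*`, gaps `-`) are skipped
#' during counting rather than being remapped.
#'
#' @export
cv_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# regex matching any character outside the canonical alphabet
noncanonical_re <- paste0("[^", paste(cv_alphabet, collapse = ""), "]")

#' Construct a proteome
#'
#' A proteome is a genome identifier plus the full set of its annotated
#' protein sequences — the raw material for K-peptide counting. The
#' identifier doubles as the tree leaf label downstream, so it must be
#' nonempty and unique within a project.
#'
#' @param genome_id Single nonempty string.
#' @param proteins Character vector of amino-acid sequences; empty sequences
#'   are rejected. Sequences are upper-cased.
#' @return An object of class `cv_proteome`: a list with `genome_id` and
#'   `proteins`.
#' @export
proteome <- function(genome_id, proteins) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id)) {
    stop("`genome_id` must be a single nonempty string", call. = FALSE)
  }
  proteins <- toupper(as.character(proteins))
  if (length(proteins) == 0L || any(!nzchar(proteins))) {
    stop("proteome '", genome_id, "' must contain only nonempty protein sequences",
         call. = FALSE)
  }
  structure(list(genome_id = genome_id, proteins = proteins),
            class = "cv_proteome")
}

#' @export
print.cv_proteome <- function(x, ...) {
  cat("<cv_proteome> ", x$genome_id, ": ", length(x$proteins),
      " proteins, ", sum(nchar(x$proteins)), " residues\n", sep = "")
  invisible(x)
}

#' Read a proteome from a protein multi-FASTA file
#'
#' Reads all protein records of one genome (typically a `.faa` file with all
#' annotated protein products). Sequences are upper-cased; records with an
#' empty sequence are dropped with a warning.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @return A [proteome()].
#' @export
read_proteome <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    stop("proteome file not found: ", path, call. = FALSE)
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  seqs <- Biostrings::readAAStringSet(path)
  seqs_chr <- as.character(seqs)
  empty <- !nzchar(seqs_chr)
  if (any(empty)) {
    warning("dropped ", sum(empty), " empty record(s) in ", basename(path),
            call. = FALSE)
    seqs_chr <- seqs_chr[!empty]
  }
  if (length(seqs_chr) == 0L) {
    stop("no parseable protein records in ", path, call. = FALSE)
  }
  proteome(genome_id, unname(seqs_chr))
}

#' Write a proteome to a FASTA file
#'
#' @param p A [proteome()].
#' @param path Output file path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(p, path, width = 70L) {
  stopifnot(inherits(p, "cv_proteome"))
  ids <- sprintf("%s_p%04d", p$genome_id, seq_along(p$proteins))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(p$proteins)) {
    writeLines(paste0(">", ids[i]), con)
    s <- p$proteins[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# content hash of a proteome, used as the CV cache key component
proteome_hash <- function(p) {
  rlang::hash(list(p$genome_id, p$proteins))
}
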