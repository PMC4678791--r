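#' Parse one tagged lineage line
#'
#' A lineage record is one line: a genome identifier, whitespace, then zero or
#' more `<X>Name` segments where `X` is one of the nine rank tag letters
#' `D K P C O F G S T`. Both the ASCII `<D>` and the typographic
#' `〈D〉` delimiters are accepted on input; ASCII is emitted on
#' output. The tag delimiter — not whitespace — separates fields, so taxon
#' names may contain spaces and punctuation. Ranks absent from the line are
#' filled with `"Unclassified"`; a lineage is *complete* iff none of the nine
#' ranks is `"Unclassified"`.
#'
#' @param line A single lineage record.
#' @return A one-row tibble: `genome_id`, one column per rank
#'   (see [cv_ranks]), and `complete`.
#' @examples
#' parse_lineage_line("g1 <D>Bacteria<P>Firmicutes")
#' @export
parse_lineage_line <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  row <- parse_lineage_fields(line)
  lin <- row$ranks
  lin[is.na(lin)] <- cv_unclassified
  tibble::as_tibble(c(
    list(genome_id = row$genome_id),
    as.list(lin),
    list(complete = !any(lin == cv_unclassified))
  ))
}

# Shared parser: returns genome_id plus a named vector over cv_ranks with NA
# for ranks not mentioned on the line (the distinction matters for
# modification fragments, where NA means "leave alone").
parse_lineage_fields <- function(line) {
  tag_re <- "[<〈]([A-Za-z])[>〉]"
  m <- gregexpr(tag_re, line, perl = TRUE)[[1]]
  ranks <- stats::setNames(rep(NA_character_, length(cv_ranks)), cv_ranks)
  if (m[1] == -1L) {
    genome_id <- trimws(line)
  } else {
    genome_id <- trimws(substr(line, 1L, m[1] - 1L))
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    letters_seen <- toupper(substring(line, starts + 1L, starts + 1L))
    bad <- setdiff(letters_seen, names(cv_rank_tags))
    if (length(bad) > 0L) {
      stop("unknown lineage rank tag(s): ", paste0("<", bad, ">", collapse = ", "),
           call. = FALSE)
    }
    dup <- unique(letters_seen[duplicated(letters_seen)])
    if (length(dup) > 0L) {
      stop("duplicated lineage rank tag(s): ",
           paste0("<", dup, ">", collapse = ", "), call. = FALSE)
    }
    val_start <- starts + lens
    val_end <- c(starts[-1] - 1L, nchar(line))
    vals <- trimws(substring(line, val_start, val_end))
    ranks[unname(cv_rank_tags[letters_seen])] <- vals
  }
  if (!nzchar(genome_id)) {
    stop("lineage line has no genome identifier: '", line, "'", call. = FALSE)
  }
  list(genome_id = genome_id, ranks = ranks)
}

#' Serialize lineage rows to tagged lines
#'
#' Inverse of [parse_lineage_line()]: emits the genome identifier followed by
#' all nine `<X>Name` segments in canonical `D` to `T` order.
#'
#' @param lt A lineage tibble (one or more rows) as produced by
#'   [parse_lineage_line()] or [read_lineage()].
#' @return Character vector of lines, one per row.
#' @export
format_lineage <- function(lt) {
  lt <- validate_lineage_table(lt)
  vapply(seq_len(nrow(lt)), function(i) {
    segs <- paste0("<", names(cv_rank_tags), ">",
                   vapply(cv_ranks, function(r) lt[[r]][i], character(1)))
    paste0(lt$genome_id[i], " ", paste(segs, collapse = ""))
  }, character(1))
}

#' Read a lineage annotation file
#'
#' Reads the one-record-per-line tagged lineage dialect (the `Lineage.txt`
#' convention). Blank lines and lines starting with `#` are skipped. When
#' `genome_ids` is supplied, the table is aligned to the project: genomes
#' missing from the file receive an all-`"Unclassified"` lineage (and count as
#' incomplete), and file records for genomes outside the project are dropped
#' with a warning.
#'
#' @param path Path to the lineage file.
#' @param genome_ids Optional character vector of the project's genome ids.
#' @return A lineage tibble: `genome_id`, the nine rank columns, `complete`.
#' @export
read_lineage <- function(path, genome_ids = NULL) {
  if (!file.exists(path)) {
    stop("lineage file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lt <- dplyr::bind_rows(lapply(lines, parse_lineage_line))
  if (nrow(lt) > 0L && anyDuplicated(lt$genome_id)) {
    stop("duplicated genome id(s) in lineage file: ",
         paste(unique(lt$genome_id[duplicated(lt$genome_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(genome_ids)) {
    lt <- align_lineage(lt, genome_ids)
  }
  lt
}

#' Align a lineage table to a set of project genomes
#'
#' @param lt Lineage tibble.
#' @param genome_ids The project's genome ids.
#' @return A lineage tibble whose keys are exactly `genome_ids` (in that
#'   order); absent genomes get all-`"Unclassified"` rows.
#' @export
align_lineage <- function(lt, genome_ids) {
  extra <- setdiff(lt$genome_id, genome_ids)
  if (length(extra) > 0L) {
    warning("lineage records for genome(s) not in project dropped: ",
            paste(extra, collapse = ", "), call. = FALSE)
    lt <- lt[!lt$genome_id %in% extra, ]
  }
  missing <- setdiff(genome_ids, lt$genome_id)
  if (length(missing) > 0L) {
    fill <- tibble::as_tibble(c(
      list(genome_id = missing),
      stats::setNames(rep(list(cv_unclassified), length(cv_ranks)), cv_ranks),
      list(complete = FALSE)
    ))
    lt <- dplyr::bind_rows(lt, fill)
  }
  lt[match(genome_ids, lt$genome_id), ]
}

#' Write a lineage table to a file
#'
#' @param lt Lineage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lt, path) {
  writeLines(format_lineage(lt), path)
  invisible(path)
}

#' Read a lineage-modification file
#'
#' Modification fragments use the identical tagged dialect, but ranks absent
#' from a fragment line mean "keep the base value" rather than
#' `"Unclassified"`, so they are returned as `NA`.
#'
#' @param path Path to the modification file.
#' @return A tibble with `genome_id` and the nine rank columns; `NA` marks a
#'   rank the fragment does not touch.
#' @export
read_lineage_mods <- function(path) {
  if (!file.exists(path)) {
    stop("lineage modification file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- lapply(lines, function(l) {
    row <- parse_lineage_fields(l)
    tibble::as_tibble(c(list(genome_id = row$genome_id), as.list(row$ranks)))
  })
  dplyr::bind_rows(rows)
}

#' Apply trial lineage modifications
#'
#' Returns a new lineage table where, for each genome named in `mods`, the
#' ranks the fragment names overwrite the base values and all other ranks are
#' preserved; the base table is never altered. This is the mechanism for
#' trying taxonomic revisions (e.g. moving a species to a different phylum)
#' and re-running the monophyly report.
#'
#' @param base Lineage tibble covering the project.
#' @param mods Modification tibble from [read_lineage_mods()], or a lineage
#'   tibble (whose every named rank then overwrites).
#' @return A new lineage tibble with the same genomes in the same order.
#' @export
apply_modifications <- function(base, mods) {
  base <- validate_lineage_table(base)
  if (nrow(mods) == 0L) {
    return(base)
  }
  unknown <- setdiff(mods$genome_id, base$genome_id)
  if (length(unknown) > 0L) {
    stop("lineage modification(s) for unknown genome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- base
  for (i in seq_len(nrow(mods))) {
    j <- match(mods$genome_id[i], out$genome_id)
    for (r in cv_ranks) {
      v <- mods[[r]][i]
      if (!is.na(v)) {
        out[[r]][j] <- v
      }
    }
  }
  out$complete <- lineage_complete(out)
  out
}

# recompute the complete flag from the nine rank columns
lineage_complete <- function(lt) {
  m <- as.matrix(lt[, cv_ranks])
  apply(m != cv_unclassified, 1L, all)
}

validate_lineage_table <- function(lt) {
  need <- c("genome_id", cv_ranks)
  miss <- setdiff(need, names(lt))
  if (length(miss) > 0L) {
    stop("lineage table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"complete" %in% names(lt)) {
    lt$complete <- lineage_complete(lt)
  }
  if (anyDuplicated(lt$genome_id)) {
    stop("lineage table has duplicated genome ids", call. = FALSE)
  }
  tibble::as_tibble(lt)
}
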