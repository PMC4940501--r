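#' Aligned 16S sequence sets
#'
#' An `aligned_seqs` object is a tibble with one row per sequence and columns
#' `id` and `sequence` (aligned, uppercase, over `A C G T - N`), plus a
#' `class_label` attribute identifying the rhizobial class the alignment
#' belongs to (`"alpha"` or `"beta"`; alpha- and beta-proteobacterial 16S
#' genes are aligned separately and never compared across classes).
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of aligned sequences, all the same length.
#' @param class_label `"alpha"`, `"beta"`, or another single label.
#' @return An `aligned_seqs` tibble.
#' @examples
#' aligned_seqs(c("s1", "s2"), c("ACGT", "ACGA"))
#' @export
aligned_seqs <- function(id, sequence, class_label = "alpha") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) stop("sequence ids must be unique", call. = FALSE)
  if (length(sequence)) {
    widths <- nchar(sequence)
    if (length(unique(widths)) > 1L) {
      stop("all sequences must have the same aligned length", call. = FALSE)
    }
    bad <- grepl("[^ACGTN-]", sequence)
    if (any(bad)) {
      stop("sequences may only contain A, C, G, T, N and '-' (first offender: ",
           id[which(bad)[1L]], ")", call. = FALSE)
    }
    allgap <- !grepl("[ACGTN]", sequence)
    if (any(allgap)) {
      stop("every sequence needs at least one non-gap character (offender: ",
           id[which(allgap)[1L]], ")", call. = FALSE)
    }
  }
  out <- tibble::tibble(id = id, sequence = sequence)
  attr(out, "class_label") <- as.character(class_label)[1L]
  class(out) <- c("aligned_seqs", class(out))
  out
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat(sprintf("<aligned_seqs> %d sequences, %d columns, class '%s'\n",
              nrow(x), alignment_length(x), attr(x, "class_label")))
  NextMethod()
}

#' Alignment length (number of columns) of an aligned set
#' @param seqs An [aligned_seqs] object.
#' @return Integer number of alignment columns.
#' @export
alignment_length <- function(seqs) {
  if (nrow(seqs) == 0L) return(0L)
  nchar(seqs$sequence[[1L]])
}

#' Read an aligned FASTA file
#'
#' Uses Biostrings when available, otherwise a plain-text fallback. Sequences
#' are uppercased; `.` gaps are normalised to `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @param class_label Class label to attach (`"alpha"` or `"beta"`).
#' @return An [aligned_seqs] tibble.
#' @export
read_aligned_fasta <- function(path, class_label = "alpha") {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- chartr(".", "-", toupper(as.character(ss)))
    ids <- sub("\\s.*$", "", names(ss))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("no FASTA records in ", path, call. = FALSE)
    grp <- cumsum(hdr)
    ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(x, collapse = ""), character(1))
    seqs <- chartr(".", "-", toupper(seqs))
  }
  aligned_seqs(ids, unname(seqs), class_label = class_label)
}

#' Write an aligned set to FASTA
#'
#' @param seqs An [aligned_seqs] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(c(paste0(">", seqs$id[[i]]), seqs$sequence[[i]]), con)
  }
  invisible(path)
}

# Internal: alignment as an n x L character matrix
seq_char_matrix <- function(seqs) {
  L <- alignment_length(seqs)
  m <- matrix("", nrow = nrow(seqs), ncol = L, dimnames = list(seqs$id, NULL))
  for (i in seq_len(nrow(seqs))) {
    m[i, ] <- strsplit(seqs$sequence[[i]], "", fixed = TRUE)[[1L]]
  }
  m
}
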