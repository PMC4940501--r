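#' Pairwise sequence identity from an alignment
#'
#' Computes the fraction of matching positions for every pair of aligned
#' sequences. A column is *comparable* for a pair when neither sequence has
#' `N` there and the two characters are not both gaps; a gap aligned to a
#' base counts as a mismatch, gap-gap columns and any column involving `N`
#' are excluded from the denominator. This is the usual OTU-clustering
#' convention for distance from a multiple alignment.
#'
#' @param seqs An [aligned_seqs] object.
#' @return An `identity_matrix`: a symmetric numeric matrix in `[0, 1]` with
#'   unit diagonal, dimnames set to the sequence ids.
#' @examples
#' s <- aligned_seqs(c("a", "b"), c("ACG-T", "ACGAT"))
#' pairwise_identity(s)  # 4/5 = 0.8 off the diagonal
#' @export
pairwise_identity <- function(seqs) {
  n <- nrow(seqs)
  if (n == 0L) stop("empty sequence set", call. = FALSE)
  ch <- seq_char_matrix(seqs)
  # crossprod over per-base indicator matrices: matches and comparable
  # column counts for all pairs at once
  match_ct <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (ch == b) * 1
    match_ct <- match_ct + tcrossprod(ind)
  }
  non_n <- (ch != "N") * 1
  gap <- (ch == "-") * 1
  comparable <- tcrossprod(non_n) - tcrossprod(gap)
  if (n > 1L) {
    off <- comparable[upper.tri(comparable)]
    if (any(off == 0)) {
      idx <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1L, ]
      stop(sprintf("no comparable alignment columns between '%s' and '%s'",
                   seqs$id[idx[1L]], seqs$id[idx[2L]]), call. = FALSE)
    }
  }
  idm <- match_ct / comparable
  diag(idm) <- 1
  dimnames(idm) <- list(seqs$id, seqs$id)
  class(idm) <- c("identity_matrix", class(idm))
  idm
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d sequences\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Turn an identity matrix into a long tibble of pairs
#' @param x An `identity_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `id1`, `id2`, `identity` (upper triangle).
#' @export
tidy.identity_matrix <- function(x, ...) {
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    id1 = rownames(x)[ut[, 1L]],
    id2 = colnames(x)[ut[, 2L]],
    identity = x[ut]
  )
}
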