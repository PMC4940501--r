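#' Collapse an alignment to 16S genotypes
#'
#' Sequences at pairwise identity exactly 1.0 share a genotype; the relation
#' is closed transitively, so chains of identical pairs collapse together
#' even when gap patterns make some pairs incomparable at a few columns.
#'
#' @param seqs An [aligned_seqs] object.
#' @param prefix Prefix for taxon ids (defaults to the class label).
#' @return A `taxon_assignment` tibble: columns `sequence_id`, `taxon_id`;
#'   attributes `level = "genotype"` and `n_taxa`.
#' @export
collapse_genotypes <- function(seqs, prefix = NULL) {
  idm <- pairwise_identity(seqs)
  n <- nrow(idm)
  # union-find over identity == 1 pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    eq <- which(idm >= 1 - 1e-12 & upper.tri(idm), arr.ind = TRUE)
    for (k in seq_len(nrow(eq))) {
      ri <- find(eq[k, 1L]); rj <- find(eq[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, sort(unique(roots)))
  new_taxon_assignment(seqs$id, labels, level = "genotype",
                       prefix = prefix %||% attr(seqs, "class_label"))
}

#' Cluster sequences into taxa at an identity threshold
#'
#' Complete-linkage agglomerative clustering on distance `1 - identity`, cut
#' so that every within-cluster pair has identity at or above the threshold.
#' Cuts at decreasing thresholds are nested: a cluster at a higher threshold
#' is always a subset of exactly one cluster at a lower threshold.
#'
#' @param idm An `identity_matrix` from [pairwise_identity()].
#' @param threshold Identity threshold in `(0, 1]`, e.g. `0.98`.
#' @param level Label stored on the result (defaults to the threshold).
#' @param prefix Prefix for taxon ids.
#' @return A `taxon_assignment` tibble (`sequence_id`, `taxon_id`).
#' @export
cluster_at_threshold <- function(idm, threshold, level = NULL, prefix = "taxon") {
  threshold <- check_fraction(threshold, "threshold", lo = 0, hi = 1, lo_open = TRUE)
  n <- nrow(idm)
  ids <- rownames(idm)
  if (n == 1L) {
    labels <- 1L
  } else {
    d <- stats::as.dist(1 - unclass(idm))
    hc <- stats::hclust(d, method = "complete")
    # small slack absorbs float noise in the identity ratios; merges at
    # distance exactly 1 - threshold are included (identity == threshold
    # satisfies ">= threshold")
    labels <- stats::cutree(hc, h = 1 - threshold + 1e-9)
  }
  new_taxon_assignment(ids, labels,
                       level = level %||% format(threshold), prefix = prefix)
}

#' Hierarchical taxon delineation at several similarity levels
#'
#' Runs genotype collapsing and threshold clustering (default 99, 98 and 95
#' percent identity) on one alignment and stacks the assignments. Alignments
#' from different bacterial classes should be delineated separately and the
#' results row-bound; taxon ids are namespaced by the class prefix so a
#' later union is safe.
#'
#' @param seqs An [aligned_seqs] object.
#' @param levels Character vector drawn from
#'   `c("genotype", "0.99", "0.98", "0.95")` (numeric strings are thresholds).
#' @return A tibble with columns `sequence_id`, `level`, `taxon_id`.
#' @examples
#' sim <- gen_sequence_community(n_taxa = 2, genotypes_per_taxon = 2,
#'                               seq_length = 200, within_taxon_identity = 0.99,
#'                               between_taxon_identity = 0.9, seed = 1)
#' delineate_taxa(sim$seqs, levels = c("genotype", "0.95"))
#' @export
delineate_taxa <- function(seqs, levels = c("genotype", "0.99", "0.98", "0.95")) {
  levels <- as.character(levels)
  prefix <- attr(seqs, "class_label") %||% "taxon"
  idm <- NULL
  out <- purrr::map(levels, function(lv) {
    if (identical(lv, "genotype")) {
      asg <- collapse_genotypes(seqs, prefix = prefix)
    } else {
      thr <- suppressWarnings(as.numeric(lv))
      if (is.na(thr)) stop("unknown level: ", lv, call. = FALSE)
      if (is.null(idm)) idm <<- pairwise_identity(seqs)
      asg <- cluster_at_threshold(idm, thr, level = lv, prefix = prefix)
    }
    tibble::tibble(sequence_id = asg$sequence_id, level = lv,
                   taxon_id = asg$taxon_id)
  })
  dplyr::bind_rows(out)
}

new_taxon_assignment <- function(ids, labels, level, prefix) {
  # relabel in order of first appearance for deterministic, readable ids
  first <- labels[!duplicated(labels)]
  lab <- match(labels, first)
  width <- max(3L, nchar(length(first)))
  out <- tibble::tibble(
    sequence_id = as.character(ids),
    taxon_id = sprintf("%s_%s_%0*d", prefix, gsub("[^A-Za-z0-9]", "", level),
                       width, lab)
  )
  attr(out, "level") <- level
  attr(out, "n_taxa") <- length(first)
  class(out) <- c("taxon_assignment", class(out))
  out
}

#' Number of taxa in an assignment
#' @param assignment A `taxon_assignment` or any tibble with `taxon_id`.
#' @return Integer count of distinct taxa.
#' @export
n_taxa <- function(assignment) {
  dplyr::n_distinct(assignment$taxon_id)
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("<taxon_assignment> level '%s': %d sequences in %d taxa\n",
              attr(x, "level"), nrow(x), attr(x, "n_taxa")))
  NextMethod()
}
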