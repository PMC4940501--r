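#' Quantitative bipartite interaction webs
#'
#' A `bipartite_web` is a plant-by-bacterial-taxon matrix of nodule-occupancy
#' counts: rows are legume species, columns are bacterial taxa at one
#' delineation level, and cell `a[i, j]` is the number of nodules of plant
#' `i` occupied by taxon `j`. Row and column metadata (plant invasion status,
#' taxon clade) travel as attributes.
#'
#' @param counts Non-negative integer matrix with row and column dimnames.
#' @param plant_status Optional named character vector (`native`/`invasive`)
#'   over the row names.
#' @param taxon_clade Optional named character vector over the column names.
#' @param drop_empty Drop all-zero rows/columns (with a warning) instead of
#'   erroring; metrics divide by marginals so empty margins are not allowed.
#' @return A `bipartite_web` object.
#' @export
bipartite_web <- function(counts, plant_status = NULL, taxon_clade = NULL,
                          drop_empty = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("plant_%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("taxon_%03d", seq_len(ncol(counts)))
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("web counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  empty_r <- rowSums(counts) == 0
  empty_c <- colSums(counts) == 0
  if (any(empty_r) || any(empty_c)) {
    if (!drop_empty) stop("web has all-zero rows or columns", call. = FALSE)
    warning(sprintf("dropping %d empty row(s) and %d empty column(s)",
                    sum(empty_r), sum(empty_c)), call. = FALSE)
    counts <- counts[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L || sum(counts) == 0) {
    stop("web is empty after dropping zero margins", call. = FALSE)
  }
  structure(counts,
            plant_status = align_meta(plant_status, rownames(counts)),
            taxon_clade = align_meta(taxon_clade, colnames(counts)),
            class = c("bipartite_web", "matrix", "array"))
}

align_meta <- function(meta, labels) {
  if (is.null(meta)) return(NULL)
  out <- unname(meta[labels])
  names(out) <- labels
  out
}

#' @export
print.bipartite_web <- function(x, ...) {
  cat(sprintf("<bipartite_web> %d plants x %d taxa, F = %d nodules, I = %d links\n",
              nrow(x), ncol(x), as.integer(sum(x)), sum(x > 0)))
  print(unclass(x), ...)
  invisible(x)
}

#' Build a web from nodule records and a taxon assignment
#'
#' Cross-tabulates nodule records (one row per sequenced nodule) against a
#' taxon assignment at one delineation level, weighting each plant-taxon edge
#' by its frequency of nodule occupancy.
#'
#' @param table Nodule-record data frame with columns `sequence_id`, `site`,
#'   `plant_species`, and optionally `plant_status`, `clade`.
#' @param assignment Data frame with `sequence_id`, `taxon_id` (one level).
#' @param sites Optional character vector of sites to keep (default: all).
#' @return A [bipartite_web()] with plants sorted alphabetically and taxa by
#'   id; `F` equals the number of contributing records.
#' @export
build_web <- function(table, assignment, sites = NULL) {
  stopifnot(is.data.frame(table), is.data.frame(assignment))
  if (!is.null(sites)) table <- dplyr::filter(table, .data$site %in% sites)
  if (nrow(table) == 0L) stop("no nodule records selected", call. = FALSE)
  if ("level" %in% names(assignment) &&
      dplyr::n_distinct(assignment$level) > 1L) {
    stop("`assignment` mixes delineation levels; filter to one first",
         call. = FALSE)
  }
  table <- table[setdiff(names(table), "taxon_id")]  # assignment wins
  missing <- setdiff(table$sequence_id, assignment$sequence_id)
  if (length(missing)) {
    stop("records without a taxon assignment, e.g. ", missing[[1L]],
         call. = FALSE)
  }
  joined <- dplyr::inner_join(table, assignment[c("sequence_id", "taxon_id")],
                              by = "sequence_id")
  counts <- table(factor(joined$plant_species,
                         levels = sort(unique(joined$plant_species))),
                  factor(joined$taxon_id,
                         levels = sort(unique(joined$taxon_id))))
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  bipartite_web(counts,
                plant_status = meta_lookup(joined, "plant_species", "plant_status"),
                taxon_clade = meta_lookup(joined, "taxon_id", "clade"))
}

meta_lookup <- function(df, key, value) {
  if (!value %in% names(df)) return(NULL)
  u <- dplyr::distinct(df, .data[[key]], .data[[value]])
  if (anyDuplicated(u[[key]])) {
    stop(sprintf("conflicting `%s` metadata for some `%s`", value, key),
         call. = FALSE)
  }
  stats::setNames(as.character(u[[value]]), u[[key]])
}

#' Combine site webs into one pooled web
#'
#' Cell-wise sum over the union of plant and taxon labels. A plant species
#' occurring at several sites is a single row of the combined web; its
#' status metadata must agree across inputs.
#'
#' @param webs List of [bipartite_web()] objects (a single web passes
#'   through unchanged).
#' @return A [bipartite_web()] with grand total equal to the summed inputs.
#' @export
combine_webs <- function(webs) {
  if (inherits(webs, "bipartite_web")) return(webs)
  stopifnot(is.list(webs), length(webs) >= 1L)
  rows <- sort(unique(unlist(lapply(webs, rownames))))
  cols <- sort(unique(unlist(lapply(webs, colnames))))
  acc <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  status <- character(0); clade <- character(0)
  for (w in webs) {
    acc[rownames(w), colnames(w)] <- acc[rownames(w), colnames(w)] + unclass(w)
    status <- merge_meta(status, attr(w, "plant_status"), "plant_status")
    clade <- merge_meta(clade, attr(w, "taxon_clade"), "clade")
  }
  bipartite_web(acc,
                plant_status = if (length(status)) status else NULL,
                taxon_clade = if (length(clade)) clade else NULL)
}

merge_meta <- function(acc, meta, what) {
  if (is.null(meta)) return(acc)
  shared <- intersect(names(acc), names(meta))
  bad <- shared[acc[shared] != meta[shared]]
  if (length(bad)) {
    stop(sprintf("conflicting %s metadata for '%s'", what, bad[[1L]]),
         call. = FALSE)
  }
  c(acc, meta[setdiff(names(meta), names(acc))])
}

#' Long-format view of a web
#' @param x A [bipartite_web()].
#' @param keep_zero Keep zero cells (default drops them).
#' @param ... Unused.
#' @return Tibble with `plant`, `taxon`, `count` (plus status/clade if known).
#' @export
tidy.bipartite_web <- function(x, keep_zero = FALSE, ...) {
  out <- tibble::tibble(
    plant = rep(rownames(x), times = ncol(x)),
    taxon = rep(colnames(x), each = nrow(x)),
    count = as.vector(unclass(x))
  )
  ps <- attr(x, "plant_status"); tc <- attr(x, "taxon_clade")
  if (!is.null(ps)) out$plant_status <- unname(ps[out$plant])
  if (!is.null(tc)) out$clade <- unname(tc[out$taxon])
  if (!keep_zero) out <- dplyr::filter(out, .data$count > 0)
  out
}

#' Write a web as a labeled TSV matrix
#' @param web A [bipartite_web()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_web_tsv <- function(web, path) {
  df <- data.frame(plant = rownames(web), unclass(web), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
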