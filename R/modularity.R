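#' Weighted bipartite (Barber) modularity of a partition
#'
#' `Q = (1/F) * sum_ij [a_ij - k_i d_j / F] * delta(m_i, m_j)`, where the
#' delta is 1 when plant `i` and taxon `j` carry the same module label:
#' the excess interaction weight concentrated within joint plant-taxon
#' modules, relative to the marginal-product expectation. `Q = 0` for the
#' trivial one-module partition; the fully compartmentalized diagonal web
#' scores `(n-1)/n` over `n` equal blocks.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @param row_modules Module labels for the rows (vector, or a
#'   `module_partition` from [find_modules()], in which case `col_modules`
#'   is ignored).
#' @param col_modules Module labels for the columns.
#' @return Modularity Q in `[-1, 1]`.
#' @export
barber_q <- function(web, row_modules, col_modules = NULL) {
  m <- as_count_matrix(web)
  if (inherits(row_modules, "module_partition")) {
    part <- row_modules
    row_modules <- stats::setNames(part$module, part$node)[rownames(m)]
    col_modules <- stats::setNames(part$module, part$node)[colnames(m)]
  }
  if (length(row_modules) != nrow(m) || length(col_modules) != ncol(m)) {
    stop("module labels must cover every row and column", call. = FALSE)
  }
  if (anyNA(row_modules) || anyNA(col_modules)) {
    stop("missing module labels", call. = FALSE)
  }
  F <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / F
  delta <- outer(as.character(row_modules), as.character(col_modules), "==")
  sum((m - expected)[delta]) / F
}

#' Search for the maximum-modularity module partition
#'
#' Simulated annealing over joint plant/taxon module assignments (single-node
#' reassignments and module merges, geometric cooling, every node starting in
#' its own singleton), run `n_runs` times; the best partition across runs is
#' polished by a greedy hill-climb and returned. Deterministic given `seed`.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @param n_runs Independent search restarts (default 5).
#' @param n_steps Elementary moves per run (default `1e6`; small webs
#'   converge far earlier, so tests and simulations can use `1e4`).
#' @param seed Integer seed.
#' @param cooling Geometric cooling factor applied per batch of moves.
#' @return A `module_partition`: tibble with columns `node`, `side`
#'   (`plant`/`bacterium`), `module` (1-based, empty modules dropped), and
#'   attributes `Q`, `n_modules`, `n_runs`, `n_steps`, `seed`.
#' @examples
#' w <- bipartite_web(diag(5) * 4)
#' find_modules(w, n_steps = 1e3, seed = 1)
#' @export
find_modules <- function(web, n_runs = 5, n_steps = 1e6, seed = NULL,
                         cooling = 0.999) {
  n_runs <- check_count(n_runs, "n_runs")
  n_steps <- check_count(n_steps, "n_steps")
  m <- as_count_matrix(web)
  res <- with_rng(seed, anneal_modules(m, n_runs, n_steps, cooling))
  labels <- res$labels
  labels <- match(labels, labels[!duplicated(labels)])  # compact, 1-based
  out <- tibble::tibble(
    node = c(rownames(m), colnames(m)),
    side = rep(c("plant", "bacterium"), c(nrow(m), ncol(m))),
    module = labels
  )
  attr(out, "Q") <- res$Q
  attr(out, "n_modules") <- max(labels)
  attr(out, "n_runs") <- n_runs
  attr(out, "n_steps") <- n_steps
  attr(out, "seed") <- seed
  class(out) <- c("module_partition", class(out))
  out
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> Q = %.4f, %d modules (%d runs x %s steps)\n",
              attr(x, "Q"), attr(x, "n_modules"),
              attr(x, "n_runs"), format(attr(x, "n_steps"))))
  NextMethod()
}

#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(Q = attr(x, "Q"), n_modules = attr(x, "n_modules"),
                 n_runs = attr(x, "n_runs"), n_steps = attr(x, "n_steps"))
}

#' Null-model significance of web modularity
#'
#' Re-runs the module search (same budget) on `n_null` fixed-marginal
#' randomizations of the web and converts the observed maximum Q into a
#' z-score and an add-one empirical p-value (one-tailed, greater).
#'
#' @param web A [bipartite_web()] or count matrix.
#' @param partition Optional `module_partition` already found for `web`
#'   (searched here if missing).
#' @param n_null Number of randomized webs (default 100).
#' @param n_runs,n_steps Search budget passed to [find_modules()].
#' @param seed Integer seed covering the null draws and all searches.
#' @return One-row tibble from [zscore_and_p()] with `n_modules` appended.
#' @export
modularity_significance <- function(web, partition = NULL, n_null = 100,
                                    n_runs = 5, n_steps = 1e6, seed = NULL) {
  m <- as_count_matrix(web)
  ens <- with_rng(seed, {
    if (is.null(partition)) {
      partition <- find_modules(m, n_runs = n_runs, n_steps = n_steps)
    }
    r <- rowSums(m); s <- colSums(m)
    nulls <- vapply(seq_len(n_null), function(i) {
      nm <- r2dtable_fixed(1L, round(r), round(s))[[1L]]
      keep_r <- rowSums(nm) > 0; keep_c <- colSums(nm) > 0
      nm <- nm[keep_r, keep_c, drop = FALSE]
      attr(find_modules(nm, n_runs = n_runs, n_steps = n_steps), "Q")
    }, numeric(1))
    structure(list(statistic = "Q", observed = attr(partition, "Q"),
                   null = nulls, n = n_null, n_failed = 0L, seed = seed),
              class = "null_ensemble")
  })
  out <- zscore_and_p(ens, tail = "greater")
  out$n_modules <- attr(partition, "n_modules")
  out
}
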