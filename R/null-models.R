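#' Random contingency table with fixed marginals
#'
#' Draws a plant-by-taxon count table uniformly from the multinomial
#' distribution over tables with exactly the given row and column totals,
#' via Patefield's algorithm (`stats::r2dtable`). This is the quantitative
#' null of the web analyses: it scrambles who interacts with whom while
#' conserving every species' observed nodule total.
#'
#' @param row_totals Non-negative integer vector; must sum to `sum(col_totals)`.
#' @param col_totals Non-negative integer vector.
#' @param seed Optional integer seed for a reproducible draw.
#' @return An integer matrix with the requested marginals.
#' @examples
#' patefield_sample(c(2, 2), c(2, 2), seed = 1)
#' @export
patefield_sample <- function(row_totals, col_totals, seed = NULL) {
  row_totals <- as.integer(round(row_totals))
  col_totals <- as.integer(round(col_totals))
  if (any(row_totals < 0) || any(col_totals < 0)) {
    stop("marginal totals must be non-negative", call. = FALSE)
  }
  if (sum(row_totals) != sum(col_totals) || sum(row_totals) == 0L) {
    stop("row and column totals must agree and be positive", call. = FALSE)
  }
  with_rng(seed, r2dtable_fixed(1L, row_totals, col_totals)[[1L]])
}

# r2dtable with the degenerate single-row / single-column cases handled
# (those tables are forced by the marginals)
r2dtable_fixed <- function(n, r, s) {
  if (length(r) == 1L) {
    return(replicate(n, matrix(as.integer(s), nrow = 1L), simplify = FALSE))
  }
  if (length(s) == 1L) {
    return(replicate(n, matrix(as.integer(r), ncol = 1L), simplify = FALSE))
  }
  stats::r2dtable(n, r, s)
}

#' Null distribution of a web statistic under fixed marginals
#'
#' Evaluates a statistic on `n` independent Patefield randomizations of the
#' web and returns a `null_ensemble` holding the observed value and the null
#' values. Draws on which the statistic is undefined (it errors) are recorded
#' as missing and excluded; their count is kept as a diagnostic.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @param statistic Function of a count matrix returning one number, or the
#'   name of such a function (e.g. `"wnodf"`).
#' @param n Number of null webs (the nestedness analyses use 1000).
#' @param seed Integer seed; the whole ensemble is reproducible from it.
#' @return A `null_ensemble` list: `statistic`, `observed`, `null` (numeric,
#'   failures removed), `n`, `n_failed`, `seed`.
#' @export
null_distribution <- function(web, statistic, n = 1000, seed = NULL) {
  n <- check_count(n, "n", min = 0L)
  stat_name <- if (is.character(statistic)) statistic else
    deparse(substitute(statistic))[[1L]]
  f <- if (is.character(statistic)) match.fun(statistic) else statistic
  m <- as_count_matrix(web)
  observed <- f(m)
  r <- rowSums(m); s <- colSums(m)
  nulls <- with_rng(seed, {
    tables <- if (n > 0L) r2dtable_fixed(n, round(r), round(s)) else list()
    vapply(tables, function(tab) {
      stopifnot(all(rowSums(tab) == round(r)), all(colSums(tab) == round(s)))
      tryCatch(f(tab), error = function(e) NA_real_)
    }, numeric(1))
  })
  structure(list(statistic = stat_name,
                 observed = observed,
                 null = nulls[!is.na(nulls)],
                 n = n,
                 n_failed = sum(is.na(nulls)),
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s: observed %.4g, %d null values (%d failed)\n",
              x$statistic, x$observed, length(x$null), x$n_failed))
  invisible(x)
}

#' z-score and empirical p-value of an observed statistic
#'
#' `z = (observed - mean(null)) / sd(null)` and the add-one empirical
#' p-value `p = (1 + #{null at least as extreme}) / (n + 1)` for the chosen
#' tail. Nestedness and modularity are tested one-tailed with
#' `tail = "greater"`.
#'
#' @param ens A `null_ensemble` from [null_distribution()].
#' @param tail `"greater"` or `"less"`.
#' @return A one-row tibble: `statistic`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `p`, `n`, `tail`.
#' @export
zscore_and_p <- function(ens, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(inherits(ens, "null_ensemble"))
  nv <- ens$null
  if (length(nv) < 2L) stop("need at least 2 null values", call. = FALSE)
  s <- stats::sd(nv)
  if (s == 0) {
    stop(sprintf(
      "null distribution of %s is degenerate (all %d values equal %.6g); z undefined",
      ens$statistic, length(nv), nv[[1L]]), call. = FALSE)
  }
  extreme <- if (tail == "greater") sum(nv >= ens$observed) else
    sum(nv <= ens$observed)
  tibble::tibble(
    statistic = ens$statistic,
    observed = ens$observed,
    null_mean = mean(nv),
    null_sd = s,
    z = (ens$observed - mean(nv)) / s,
    p = (1 + extreme) / (length(nv) + 1),
    n = length(nv),
    tail = tail
  )
}

#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null), value = x$null)
}

#' @export
glance.null_ensemble <- function(x, ...) {
  zscore_and_p(x)
}
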