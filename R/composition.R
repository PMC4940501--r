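#' Clade-by-group contingency table of nodule occupancy
#'
#' Cross-tabulates nodule records by major rhizobial clade
#' (beta-Burkholderia / alpha-Rhizobium / alpha-Bradyrhizobium) against a
#' grouping of interest. The two built-in groupings mirror the invasion
#' questions: `"status_at_invaded"` contrasts native vs invasive legumes at
#' the invaded sites (semi and heavily invaded pooled, since their
#' communities are very similar); `"gradient_for_shared_natives"` contrasts
#' uninvaded vs invaded records of the native species present on both sides
#' of the gradient.
#'
#' @param table Nodule-record data frame (`site`, `invasion_status`,
#'   `plant_species`, `plant_status`, `clade`).
#' @param grouping `"status_at_invaded"`, `"gradient_for_shared_natives"`,
#'   or a function mapping the record tibble to a character group vector
#'   (`NA` drops the record).
#' @return An integer matrix (groups x clades) with all-zero rows/columns
#'   removed; errors if fewer than two nonempty groups remain.
#' @export
clade_table <- function(table, grouping = "status_at_invaded") {
  stopifnot(is.data.frame(table), "clade" %in% names(table))
  invaded <- c("semi", "heavy")
  group <- if (is.function(grouping)) {
    grouping(table)
  } else if (identical(grouping, "status_at_invaded")) {
    ifelse(table$invasion_status %in% invaded, table$plant_status, NA)
  } else if (identical(grouping, "gradient_for_shared_natives")) {
    shared <- intersect(
      table$plant_species[!(table$invasion_status %in% invaded) &
                            table$plant_status == "native"],
      table$plant_species[table$invasion_status %in% invaded &
                            table$plant_status == "native"])
    ifelse(table$plant_species %in% shared,
           ifelse(table$invasion_status %in% invaded, "invaded", "uninvaded"),
           NA)
  } else {
    stop("unknown grouping: ", grouping, call. = FALSE)
  }
  keep <- !is.na(group)
  if (!any(keep)) stop("grouping selects no records", call. = FALSE)
  ct <- table(group[keep], table$clade[keep])
  ct <- matrix(as.integer(ct), nrow = nrow(ct), dimnames = dimnames(ct))
  ct <- ct[rowSums(ct) > 0, colSums(ct) > 0, drop = FALSE]
  if (nrow(ct) < 2L || ncol(ct) < 2L) {
    stop("grouping yields fewer than 2 nonempty groups or clades",
         call. = FALSE)
  }
  ct
}

#' G-test of independence
#'
#' Log-likelihood-ratio test on a contingency table:
#' `G = 2 * sum O_ij * ln(O_ij / E_ij)` with `E_ij = row_i * col_j / N`,
#' zero cells contributing 0, `df = (r - 1)(c - 1)`, p-value from the
#' chi-squared upper tail. The plain statistic is reported; the Williams
#' small-sample correction divides G by `1 + (N*sum(1/row) - 1) *
#' (N*sum(1/col) - 1) / (6 N df)` when requested.
#'
#' @param ct Contingency table (matrix of non-negative counts).
#' @param williams Apply the Williams correction (default `FALSE`).
#' @return A one-row tibble: `G`, `df`, `p`, `n`, `williams`.
#' @examples
#' g_test(matrix(c(10, 0, 0, 10), 2, 2))  # G = 40 * log(2)
#' @export
g_test <- function(ct, williams = FALSE) {
  ct <- as.matrix(ct)
  if (any(ct < 0)) stop("counts must be non-negative", call. = FALSE)
  N <- sum(ct)
  if (N == 0) stop("empty contingency table", call. = FALSE)
  r <- rowSums(ct); s <- colSums(ct)
  if (any(r == 0) || any(s == 0)) {
    stop("contingency table has an all-zero row or column", call. = FALSE)
  }
  E <- outer(r, s) / N
  keep <- ct > 0
  G <- 2 * sum(ct[keep] * log(ct[keep] / E[keep]))
  df <- (nrow(ct) - 1L) * (ncol(ct) - 1L)
  if (williams) {
    qcorr <- 1 + (N * sum(1 / r) - 1) * (N * sum(1 / s) - 1) / (6 * N * df)
    G <- G / qcorr
  }
  tibble::tibble(G = G, df = df,
                 p = stats::pchisq(G, df, lower.tail = FALSE),
                 n = as.integer(N), williams = williams)
}

#' Compare a species-level metric across groups
#'
#' Compares e.g. degree, effective partner number or d' between groups of
#' species (across sites, or native vs invasive). A species observed at more
#' than one site is first averaged across its sites, so each species
#' contributes one value. One-way ANOVA is used when every group passes a
#' Shapiro-Wilk normality screen (alpha = 0.05); otherwise Kruskal-Wallis.
#'
#' @param data Data frame with one row per (species, site) observation.
#' @param value Name of the metric column.
#' @param group Name of the grouping column.
#' @param species Name of the species column used for pre-averaging.
#' @return A one-row tibble: `metric`, `test` (`anova`/`kruskal`),
#'   `statistic`, `df1`, `df2` (NA for Kruskal-Wallis), `p`, and a
#'   `group_summary` list-column of per-group mean, sd and n.
#' @export
compare_species_metrics <- function(data, value, group, species = "species") {
  stopifnot(all(c(value, group, species) %in% names(data)))
  avg <- data |>
    dplyr::group_by(.data[[species]], .data[[group]]) |>
    dplyr::summarise(value = mean(.data[[value]]), .groups = "drop")
  g <- factor(avg[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 species after averaging", call. = FALSE)
  }
  summaries0 <- avg |>
    dplyr::group_by(group = g) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  if (stats::sd(avg$value) == 0) {
    # metric is constant over every species: no test can find a difference
    return(tibble::tibble(metric = value, test = "degenerate",
                          statistic = 0, df1 = NA_real_, df2 = NA_real_,
                          p = 1, group_summary = list(summaries0)))
  }
  normal <- vapply(levels(g), function(lv) {
    x <- avg$value[g == lv]
    if (stats::sd(x) == 0) return(TRUE)  # constant: Shapiro undefined, treat as fine
    if (length(x) < 3L) return(TRUE)     # too few for the screen
    stats::shapiro.test(x)$p.value >= 0.05
  }, logical(1))
  summaries <- summaries0
  if (all(normal)) {
    fit <- stats::aov(value ~ g, data = avg)
    tab <- summary(fit)[[1L]]
    tibble::tibble(metric = value, test = "anova",
                   statistic = tab[["F value"]][[1L]],
                   df1 = tab[["Df"]][[1L]], df2 = tab[["Df"]][[2L]],
                   p = tab[["Pr(>F)"]][[1L]],
                   group_summary = list(summaries))
  } else {
    kt <- stats::kruskal.test(avg$value, g)
    tibble::tibble(metric = value, test = "kruskal",
                   statistic = unname(kt$statistic),
                   df1 = unname(kt$parameter), df2 = NA_real_,
                   p = kt$p.value,
                   group_summary = list(summaries))
  }
}

#' Percentage nodule occupancy by clade
#'
#' Per-plant (or per-group) percentage of nodule records falling in each
#' major rhizobial clade — the standard occupancy summary of such surveys.
#'
#' @param table Nodule-record data frame with `clade`.
#' @param by Grouping columns (default plant species within site status).
#' @return Tibble with the grouping columns, `clade`, `n` and `percent`.
#' @export
clade_occupancy <- function(table, by = c("invasion_status", "plant_species")) {
  table |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "clade")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
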