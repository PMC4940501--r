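#' Connectance of a bipartite web
#'
#' The proportion of possible plant-taxon links that are realized,
#' `I / (P * B)` with `I` the number of nonzero cells.
#'
#' @param web A [bipartite_web()] or plain count matrix.
#' @return A fraction in `(0, 1]`.
#' @export
connectance <- function(web) {
  m <- as_count_matrix(web)
  sum(m > 0) / (nrow(m) * ncol(m))
}

#' Interaction evenness
#'
#' Shannon evenness of the interaction-weight distribution, `IE = H / ln L`
#' where `H = -sum p_ij ln p_ij` over realized links and `L` counts links.
#' `links = "realized"` takes `L = I` (the number of observed links, the
#' literal reading of the formula); `links = "all"` takes `L = P * B`, the
#' convention of some network software.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @param links `"realized"` or `"all"`; see Details.
#' @return Evenness in `[0, 1]` (for `"realized"`).
#' @export
interaction_evenness <- function(web, links = c("realized", "all")) {
  links <- match.arg(links)
  m <- as_count_matrix(web)
  I <- sum(m > 0)
  if (I < 2L) stop("interaction evenness needs at least 2 realized links",
                   call. = FALSE)
  p <- m[m > 0] / sum(m)
  H <- -sum(p * log(p))
  L <- if (links == "realized") I else nrow(m) * ncol(m)
  H / log(L)
}

#' Weighted nestedness (WNODF)
#'
#' Weighted nestedness based on overlap and decreasing fill. For an ordered
#' row pair `(u, v)` with strictly larger marginal total in `u`, the pair
#' contributes `100 * |{j : 0 < a_vj < a_uj}| / |{j : a_vj > 0}|`; pairs with
#' non-decreasing marginals contribute 0. Column pairs are scored by the
#' symmetric rule, and WNODF is the mean contribution over all
#' `P(P-1)/2 + B(B-1)/2` pairs. 100 means every poorer species' links are a
#' strictly lighter subset of some richer species' links; fully
#' compartmentalized webs score 0.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @return A value in `[0, 100]`.
#' @export
wnodf <- function(web) {
  m <- as_count_matrix(web)
  P <- nrow(m); B <- ncol(m)
  if (P < 2L && B < 2L) {
    stop("WNODF is undefined for a single-row, single-column web",
         call. = FALSE)
  }
  total <- wnodf_axis_sum(m) + wnodf_axis_sum(t(m))
  total / (P * (P - 1) / 2 + B * (B - 1) / 2)
}

# sum of row-pair contributions for a matrix (columns scored via t())
wnodf_axis_sum <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(0)
  tot <- rowSums(m)
  s <- 0
  for (u in seq_len(n - 1L)) {
    for (v in (u + 1L):n) {
      hi <- if (tot[u] > tot[v]) u else if (tot[v] > tot[u]) v else next
      lo <- if (hi == u) v else u
      nz <- m[lo, ] > 0
      s <- s + 100 * sum(nz & m[lo, ] < m[hi, ]) / sum(nz)
    }
  }
  s
}

#' Network-level specialization H2'
#'
#' Standardized two-dimensional Shannon entropy of the interaction matrix
#' relative to the extremes achievable under its fixed marginal totals:
#' `H2' = (H2max - H2) / (H2max - H2min)`. `H2max` is the entropy of the
#' independence table (cells proportional to the product of marginal
#' fractions); `H2min` comes from a greedy packing that repeatedly assigns
#' `min(remaining row, remaining column)` to the cell of the currently
#' largest-remaining row and column. Both are the standard heuristics; the
#' result is clipped to `[0, 1]`. 0 means interactions are as mixed as the
#' marginals allow, 1 means every species depends on exclusive partners.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @return Specialization in `[0, 1]`.
#' @export
h2prime <- function(web) {
  m <- as_count_matrix(web)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("H2' needs at least 2 rows and 2 columns", call. = FALSE)
  }
  F <- sum(m)
  H2 <- shannon(m / F)
  pq <- outer(rowSums(m) / F, colSums(m) / F)
  H2max <- shannon(pq)
  H2min <- shannon(h2min_table(rowSums(m), colSums(m)) / F)
  if (H2max - H2min < 1e-12) return(0)
  min(1, max(0, (H2max - H2) / (H2max - H2min)))
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# greedy minimum-entropy integer table with the given marginals
h2min_table <- function(r, s) {
  out <- matrix(0, length(r), length(s))
  r <- as.numeric(r); s <- as.numeric(s)
  while (sum(r) > 0) {
    i <- which.max(r); j <- which.max(s)
    a <- min(r[i], s[j])
    out[i, j] <- out[i, j] + a
    r[i] <- r[i] - a; s[j] <- s[j] - a
  }
  out
}

#' Generality: weighted mean effective partner number
#'
#' For plants, `Gp = sum_i (A_i / F) * exp(H_i)` with `H_i` the Shannon
#' entropy of row `i`'s interaction distribution — the marginal-weighted mean
#' effective number of bacterial partners per plant. `axis = "bacteria"`
#' scores columns analogously (Gb).
#'
#' @param web A [bipartite_web()] or count matrix.
#' @param axis `"plants"` (rows) or `"bacteria"` (columns).
#' @return Effective partner number, at least 1.
#' @export
generality <- function(web, axis = c("plants", "bacteria")) {
  axis <- match.arg(axis)
  m <- as_count_matrix(web)
  if (axis == "bacteria") m <- t(m)
  A <- rowSums(m)
  H <- apply(m, 1L, function(row) shannon(row[row > 0] / sum(row)))
  sum(A / sum(m) * exp(H))
}

#' Species-level metrics: degree, effective partners, d'
#'
#' Per-species descriptors for both sides of the web:
#' * `degree` — number of realized partners (nonzero cells);
#' * `effective_partners` — `exp(H)` of the species' normalized interaction
#'   vector, at most `degree` with equality only for uniform use;
#' * `d` and `dprime` — Kullback-Leibler specialization. `d` is the
#'   divergence of the species' partner use from overall partner
#'   availability; `dprime` standardizes it between `d_min` (the most even
#'   integer allocation of the species' total that respects partner
#'   availability) and `d_max = ln(F / A_i)`, clipped to `[0, 1]`.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @return A tibble with columns `species`, `side` (`plant`/`bacterium`),
#'   `degree`, `effective_partners`, `d`, `dprime` (plus `status`/`clade`
#'   metadata when the web carries them).
#' @export
species_metrics <- function(web) {
  m <- as_count_matrix(web)
  res <- dplyr::bind_rows(
    species_metrics_axis(m, rownames(m), "plant"),
    species_metrics_axis(t(m), colnames(m), "bacterium")
  )
  ps <- attr(web, "plant_status"); tc <- attr(web, "taxon_clade")
  if (!is.null(ps) || !is.null(tc)) {
    meta <- c(ps, tc)
    res$group <- unname(meta[res$species])
  }
  res
}

species_metrics_axis <- function(m, labels, side) {
  F <- sum(m)
  q <- colSums(m) / F
  tibble::tibble(
    species = labels,
    side = side,
    degree = as.integer(rowSums(m > 0)),
    effective_partners = apply(m, 1L, function(row) {
      exp(shannon(row[row > 0] / sum(row)))
    }),
    d = apply(m, 1L, function(row) dkl(row / sum(row), q)),
    dprime = vapply(seq_len(nrow(m)), function(i) {
      dprime_one(m[i, ], colSums(m), F)
    }, numeric(1))
  )
}

dkl <- function(p, q) {
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

# standardized d' for one species row against column availabilities
dprime_one <- function(row, coltot, F) {
  A <- sum(row)
  q <- coltot / F
  d <- dkl(row / A, q)
  d_max <- log(F / A)
  d_min <- dkl(dmin_allocation(A, coltot) / A, q)
  if (d_max - d_min < 1e-12) return(0)
  min(1, max(0, (d - d_min) / (d_max - d_min)))
}

# greedy most-even integer allocation of A units across partners, capped by
# the partners' own totals: each unit goes where it lowers KL the most
dmin_allocation <- function(A, coltot) {
  q <- coltot / sum(coltot)
  alloc <- pmin(floor(A * q), coltot)
  left <- A - sum(alloc)
  while (left > 0) {
    open <- which(alloc < coltot)
    # marginal KL change of adding one unit to partner j
    delta <- vapply(open, function(j) {
      a <- alloc; a[j] <- a[j] + 1
      dkl(a / sum(a), q)
    }, numeric(1))
    j <- open[which.min(delta)]
    alloc[j] <- alloc[j] + 1
    left <- left - 1
  }
  alloc
}

#' All network-level metrics for one web
#'
#' One-row tibble with the descriptors of network topology: size, realized
#' links, connectance, interaction evenness, WNODF, H2', and generality of
#' both sides. Modularity is computed separately by [find_modules()] since
#' it involves a stochastic search.
#'
#' @param web A [bipartite_web()] or count matrix.
#' @return A one-row tibble.
#' @examples
#' w <- bipartite_web(matrix(c(3, 1, 0, 2), 2, 2))
#' network_metrics(w)
#' @export
network_metrics <- function(web) {
  m <- as_count_matrix(web)
  tibble::tibble(
    plants = nrow(m),
    taxa = ncol(m),
    nodules = as.integer(sum(m)),
    links = sum(m > 0),
    connectance = connectance(m),
    interaction_evenness = interaction_evenness(m),
    wnodf = wnodf(m),
    h2prime = if (nrow(m) >= 2L && ncol(m) >= 2L) h2prime(m) else NA_real_,
    generality_plants = generality(m, "plants"),
    generality_bacteria = generality(m, "bacteria")
  )
}

as_count_matrix <- function(web) {
  if (inherits(web, "bipartite_web")) {
    m <- unclass(web)
    attr(m, "plant_status") <- NULL
    attr(m, "taxon_clade") <- NULL
    return(m)
  }
  m <- as.matrix(web)
  if (any(m < 0)) stop("negative counts in web", call. = FALSE)
  m
}
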