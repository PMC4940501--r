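#' Simulate an aligned 16S sequence community with planted taxa
#'
#' Generates `n_taxa * genotypes_per_taxon` aligned sequences from a common
#' ancestral sequence so that the true taxon clusters sit at controlled
#' identity bands. Divergence is planted as substitutions on disjoint site
#' sets: each taxon mutates its own block of sites away from the root, and
#' each genotype mutates a further private block, so realized identities hit
#' the targets exactly — within-taxon pairs at `within_taxon_identity`,
#' between-taxon pairs at or below `between_taxon_identity`. Any clustering
#' threshold strictly between the two bands recovers the planted taxa.
#' Substitutions only, no indels; ancestral bases i.i.d. uniform on ACGT.
#'
#' @param n_taxa Number of planted taxa.
#' @param genotypes_per_taxon Distinct genotypes per taxon.
#' @param seq_length Alignment length (at least 100).
#' @param within_taxon_identity Target identity for within-taxon pairs.
#' @param between_taxon_identity Target (upper bound) identity between taxa;
#'   must be strictly below `within_taxon_identity`.
#' @param seed Integer seed; output is deterministic given it.
#' @param class_label Class label for the alignment.
#' @return A list: `seqs` (an [aligned_seqs]), `truth` (tibble
#'   `sequence_id`, `taxon`, `genotype`), `seed`.
#' @examples
#' sim <- gen_sequence_community(2, 1, 100, 1, 0.9, seed = 1)
#' pairwise_identity(sim$seqs)
#' @export
gen_sequence_community <- function(n_taxa, genotypes_per_taxon, seq_length,
                                   within_taxon_identity,
                                   between_taxon_identity, seed = NULL,
                                   class_label = "alpha") {
  n_taxa <- check_count(n_taxa, "n_taxa")
  genotypes_per_taxon <- check_count(genotypes_per_taxon, "genotypes_per_taxon")
  seq_length <- check_count(seq_length, "seq_length", min = 100L)
  w <- check_fraction(within_taxon_identity, "within_taxon_identity",
                      lo = 0, hi = 1, lo_open = TRUE)
  b <- check_fraction(between_taxon_identity, "between_taxon_identity",
                      lo = 0, hi = 1, lo_open = TRUE)
  if (n_taxa > 1L && b >= w) {
    stop("between_taxon_identity must be strictly below within_taxon_identity",
         call. = FALSE)
  }
  # per-taxon and per-genotype private mutation block sizes: a pair differs
  # at the union of its two private blocks, so within-taxon identity is
  # 1 - 2*geno_block/L (floor keeps it at or above the target) and
  # between-taxon identity is at most 1 - 2*taxon_block/L (ceiling keeps it
  # at or below the target)
  taxon_block <- ceiling(seq_length * (1 - b) / 2)
  geno_block <- floor(seq_length * (1 - w) / 2)
  if (w < 1 && geno_block == 0L) {
    stop(paste0("within_taxon_identity is so close to 1 that no whole-site ",
                "divergence fits; lengthen the alignment or set it to 1"),
         call. = FALSE)
  }
  need <- n_taxa * taxon_block + n_taxa * genotypes_per_taxon * geno_block
  if (need > seq_length) {
    stop(sprintf(paste0(
      "identity targets are infeasible: %d mutated sites needed but the ",
      "alignment has only %d columns"), need, seq_length), call. = FALSE)
  }
  with_rng(seed, {
    root <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)
    sites <- sample.int(seq_length)  # disjoint blocks come off this permutation
    cursor <- 0L
    take <- function(k) {
      out <- sites[seq_len(k) + cursor]
      cursor <<- cursor + k
      out
    }
    ids <- character(0); seqs <- character(0)
    taxon_of <- character(0); geno_of <- character(0)
    for (tx in seq_len(n_taxa)) {
      tx_seq <- mutate_sites(root, take(taxon_block))
      for (g in seq_len(genotypes_per_taxon)) {
        gs <- mutate_sites(tx_seq, take(geno_block))
        ids <- c(ids, sprintf("t%02dg%02d", tx, g))
        seqs <- c(seqs, paste(gs, collapse = ""))
        taxon_of <- c(taxon_of, sprintf("taxon_%02d", tx))
        geno_of <- c(geno_of, sprintf("t%02dg%02d", tx, g))
      }
    }
    list(seqs = aligned_seqs(ids, seqs, class_label = class_label),
         truth = tibble::tibble(sequence_id = ids, taxon = taxon_of,
                                genotype = geno_of),
         seed = seed)
  })
}

mutate_sites <- function(seq, sites) {
  bases <- c("A", "C", "G", "T")
  for (s in sites) {
    seq[s] <- sample(setdiff(bases, seq[s]), 1L)
  }
  seq
}

#' Simulate a bipartite web with planted modules
#'
#' Plants and taxa are assigned to `n_modules` joint modules; cell counts are
#' Poisson with rate `lambda_in` inside a module and `lambda_out` between
#' modules. With `lambda_out = 0` the web is block-diagonal — every plant
#' module has a fully private set of bacterial partners. Rows or columns
#' that sample to zero get one count added to their highest-rate cell so the
#' web stays valid (every surveyed species had occupied nodules).
#'
#' @param n_plants,n_taxa Web dimensions.
#' @param n_modules Number of planted modules (at most `min(n_plants, n_taxa)`).
#' @param lambda_in,lambda_out Poisson rates within / between modules;
#'   `lambda_in > lambda_out >= 0`.
#' @param seed Integer seed.
#' @return List: `web` (a [bipartite_web()]), `truth` (tibble `node`, `side`,
#'   `module`), `seed`.
#' @export
gen_modular_web <- function(n_plants, n_taxa, n_modules, lambda_in = 5,
                            lambda_out = 0, seed = NULL) {
  n_plants <- check_count(n_plants, "n_plants")
  n_taxa <- check_count(n_taxa, "n_taxa")
  n_modules <- check_count(n_modules, "n_modules")
  if (n_modules > min(n_plants, n_taxa)) {
    stop("n_modules may not exceed min(n_plants, n_taxa)", call. = FALSE)
  }
  if (!(lambda_in > lambda_out) || lambda_out < 0) {
    stop("need lambda_in > lambda_out >= 0", call. = FALSE)
  }
  rmod <- rep_len(seq_len(n_modules), n_plants)
  cmod <- rep_len(seq_len(n_modules), n_taxa)
  rate <- matrix(lambda_out, n_plants, n_taxa)
  rate[outer(rmod, cmod, "==")] <- lambda_in
  counts <- with_rng(seed, {
    cts <- matrix(stats::rpois(n_plants * n_taxa, rate), n_plants, n_taxa)
    repair_margins(cts, rate)
  })
  rownames(counts) <- sprintf("plant_%02d", seq_len(n_plants))
  colnames(counts) <- sprintf("taxon_%03d", seq_len(n_taxa))
  truth <- tibble::tibble(
    node = c(rownames(counts), colnames(counts)),
    side = rep(c("plant", "bacterium"), c(n_plants, n_taxa)),
    module = c(rmod, cmod)
  )
  list(web = bipartite_web(counts), truth = truth, seed = seed)
}

# add one count to the highest-rate cell of any all-zero row/column
repair_margins <- function(cts, rate) {
  for (i in which(rowSums(cts) == 0)) {
    cts[i, which.max(rate[i, ])] <- 1
  }
  for (j in which(colSums(cts) == 0)) {
    cts[which.max(rate[, j]), j] <- 1
  }
  cts
}

#' Simulate a nested bipartite web
#'
#' Plants and taxa are ranked (rank fractions `r_i`, `c_j` in `[0, 1]`).
#' Cell `(i, j)` lies in the occupied region when `c_j <= exp(-fill_decay *
#' r_i)`: a staircase whose rows' partner sets are prefixes of the rows
#' above, so every poorer species' links are a genuine subset of a richer
#' species' links — the planted structure is nested per realization, not
#' merely on average, which is what a nestedness test against fixed-marginal
#' nulls must be able to detect. Occupancy therefore falls off jointly with
#' row and column rank at rate `fill_decay`: near 0 the whole matrix is
#' occupied (connectance 1), large values leave a thin triangular fill.
#' `total_count` interaction events are spread over the occupied cells with
#' multinomial probabilities proportional to `exp(-2 (r_i + c_j))`, so
#' weights also decay along both ranks. Rows or columns left empty by the
#' multinomial get one count in their highest-probability cell.
#'
#' @param n_plants,n_taxa Web dimensions.
#' @param fill_decay Non-negative decay rate of the occupancy staircase.
#' @param total_count Total interaction events (at least `n_plants + n_taxa`).
#' @param seed Integer seed.
#' @return A [bipartite_web()].
#' @export
gen_nested_web <- function(n_plants, n_taxa, fill_decay = 3, total_count = 300,
                           seed = NULL) {
  n_plants <- check_count(n_plants, "n_plants")
  n_taxa <- check_count(n_taxa, "n_taxa")
  if (!is.numeric(fill_decay) || fill_decay < 0) {
    stop("fill_decay must be non-negative", call. = FALSE)
  }
  total_count <- check_count(total_count, "total_count",
                             min = n_plants + n_taxa)
  r <- if (n_plants == 1L) 0 else (seq_len(n_plants) - 1) / (n_plants - 1)
  s <- if (n_taxa == 1L) 0 else (seq_len(n_taxa) - 1) / (n_taxa - 1)
  mask <- outer(r, s, function(ri, cj) cj <= exp(-fill_decay * ri) + 1e-12)
  wt <- exp(-2 * outer(r, s, "+")) * mask
  counts <- with_rng(seed, {
    # one guaranteed count per occupied cell (highest-weight cells first if
    # the budget is short), the rest spread multinomially along the decay
    cts <- matrix(0, n_plants, n_taxa)
    occ <- order(wt, decreasing = TRUE)[seq_len(min(total_count, sum(mask)))]
    cts[occ] <- 1
    left <- total_count - length(occ)
    if (left > 0) {
      cts <- cts + matrix(stats::rmultinom(1L, left, as.vector(wt / sum(wt))),
                          n_plants, n_taxa)
    }
    repair_margins(cts, wt)
  })
  rownames(counts) <- sprintf("plant_%02d", seq_len(n_plants))
  colnames(counts) <- sprintf("taxon_%03d", seq_len(n_taxa))
  bipartite_web(counts)
}
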