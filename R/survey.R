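#' Specify a nodule survey design
#'
#' Bundles the pieces the survey simulator needs: which plants grow at which
#' sites (and their invasion status), how many nodules are sequenced per
#' plant per site, which planted taxa each plant associates with (and how
#' strongly), and each taxon's major rhizobial clade.
#'
#' @param plants Tibble with columns `site`, `invasion_status`
#'   (`uninvaded`/`semi`/`heavy`), `plant_species`, `plant_status`
#'   (`native`/`invasive`), `nodules` (sequenced nodules, at least 1).
#' @param partners Tibble with `plant_species`, `taxon`, `weight`
#'   (relative interaction probability, positive; at least one partner per
#'   plant).
#' @param clades Tibble with `taxon`, `clade` (one of `beta-Burkholderia`,
#'   `alpha-Rhizobium`, `alpha-Bradyrhizobium`).
#' @return A `survey_design` list.
#' @export
survey_design <- function(plants, partners, clades) {
  plants <- tibble::as_tibble(plants)
  partners <- tibble::as_tibble(partners)
  clades <- tibble::as_tibble(clades)
  stopifnot(all(c("site", "invasion_status", "plant_species", "plant_status",
                  "nodules") %in% names(plants)),
            all(c("plant_species", "taxon", "weight") %in% names(partners)),
            all(c("taxon", "clade") %in% names(clades)))
  if (nrow(plants) && any(plants$nodules < 1)) {
    stop("every plant needs at least one nodule", call. = FALSE)
  }
  orphan <- setdiff(plants$plant_species, partners$plant_species)
  if (length(orphan)) {
    stop("plants without any partner taxon: ", orphan[[1L]], call. = FALSE)
  }
  if (nrow(partners) && any(partners$weight <= 0)) {
    stop("partner weights must be positive", call. = FALSE)
  }
  uncladed <- setdiff(partners$taxon, clades$taxon)
  if (length(uncladed)) {
    stop("taxa without a clade: ", uncladed[[1L]], call. = FALSE)
  }
  structure(list(plants = plants, partners = partners, clades = clades),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("<survey_design> %d sites, %d plant records, %d nodules planned\n",
              dplyr::n_distinct(x$plants$site), nrow(x$plants),
              sum(x$plants$nodules)))
  invisible(x)
}

#' Simulate a nodule survey from a design and a sequence community
#'
#' For every plant at every site, draws the design's number of nodules: each
#' nodule picks a partner taxon with probability proportional to the design
#' weights, then one of that taxon's genotypes uniformly, and emits a fresh
#' per-nodule sequence record (a copy of the genotype's aligned sequence
#' under a new id — each sequenced nodule yields its own accession, as in a
#' real survey).
#'
#' @param design A [survey_design()]. Its taxa must all exist in `truth`.
#' @param community An [aligned_seqs] of genotype sequences.
#' @param truth Tibble `sequence_id`, `taxon`, `genotype` mapping community
#'   sequences to planted taxa (from [gen_sequence_community()]).
#' @param seed Integer seed.
#' @return A list: `table` (nodule-record tibble with columns `sequence_id`,
#'   `site`, `invasion_status`, `plant_species`, `plant_status`, `clade`),
#'   `seqs` (per-nodule [aligned_seqs]), `truth` (per-nodule planted taxon
#'   and genotype), `seed`.
#' @export
gen_survey <- function(design, community, truth, seed = NULL) {
  stopifnot(inherits(design, "survey_design"))
  missing_taxa <- setdiff(design$partners$taxon, truth$taxon)
  if (length(missing_taxa)) {
    stop("design references taxa absent from the community: ",
         missing_taxa[[1L]], call. = FALSE)
  }
  clade_of <- stats::setNames(design$clades$clade, design$clades$taxon)
  seq_of_geno <- stats::setNames(community$sequence, truth$sequence_id)
  genos_of_taxon <- split(truth$sequence_id, truth$taxon)
  plants <- design$plants
  with_rng(seed, {
    rows <- purrr::pmap(plants, function(site, invasion_status, plant_species,
                                         plant_status, nodules, ...) {
      pd <- design$partners[design$partners$plant_species == plant_species, ]
      taxa <- sample(pd$taxon, nodules, replace = TRUE,
                     prob = pd$weight / sum(pd$weight))
      genos <- vapply(taxa, function(tx) {
        g <- genos_of_taxon[[tx]]
        g[[sample.int(length(g), 1L)]]
      }, character(1))
      tibble::tibble(site = site, invasion_status = invasion_status,
                     plant_species = plant_species,
                     plant_status = plant_status,
                     taxon = taxa, genotype = unname(genos))
    })
    recs <- dplyr::bind_rows(rows)
    recs$sequence_id <- sprintf("nod%04d", seq_len(nrow(recs)))
    recs$clade <- unname(clade_of[recs$taxon])
    table <- recs[c("sequence_id", "site", "invasion_status", "plant_species",
                    "plant_status", "clade")]
    seqs <- if (nrow(recs)) {
      aligned_seqs(recs$sequence_id, unname(seq_of_geno[recs$genotype]),
                   class_label = attr(community, "class_label"))
    } else NULL
    list(table = table, seqs = seqs,
         truth = recs[c("sequence_id", "taxon", "genotype")],
         seed = seed)
  })
}

#' Write a nodule-record table as TSV
#' @param table Nodule-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nodule_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a nodule-record TSV
#' @param path Path to a TSV with the [gen_survey()] table schema.
#' @return A tibble of nodule records.
#' @export
read_nodule_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Study-style survey scenarios
#'
#' Builds a [survey_design()] plus a matching planted sequence community
#' mimicking the field study's layout: three sites along an invasion
#' gradient; five legume species sampled at each; the uninvaded site holds
#' five natives, the invaded sites hold the two natives that persist along
#' the whole gradient plus three invasive acacia-like species; roughly 20
#' sequenced nodules per species (site totals 100, 97 and 99). Three
#' partner-structure scenarios:
#' * `"co-introduction"` — every species keeps a private pair of taxa
#'   (invaders arrive with their own symbionts); native taxa are mostly
#'   beta-Burkholderia, invasive taxa alpha-Bradyrhizobium.
#' * `"infiltration"` — invasives reuse the native taxon pool.
#' * `"random"` — every plant samples the full taxon pool uniformly.
#'
#' @param scenario One of `"co-introduction"`, `"infiltration"`, `"random"`.
#' @param seed Integer seed for the community generator.
#' @param genotypes_per_taxon Genotypes per planted taxon (default 3).
#' @param seq_length Alignment length (default 1200, near full-length 16S).
#' @return List: `design`, `community` (aligned seqs), `community_truth`.
#' @export
scenario_design <- function(scenario = c("co-introduction", "infiltration",
                                         "random"),
                            seed = NULL, genotypes_per_taxon = 3,
                            seq_length = 1200) {
  scenario <- match.arg(scenario)
  natives <- paste0("native_", LETTERS[1:5])
  shared <- natives[1:2]          # the two natives that persist when invaded
  invasives <- paste0("invasive_", c("X", "Y", "Z"))
  plants <- dplyr::bind_rows(
    tibble::tibble(site = "site_U", invasion_status = "uninvaded",
                   plant_species = natives, plant_status = "native",
                   nodules = c(20L, 20L, 20L, 20L, 20L)),
    tibble::tibble(site = "site_S", invasion_status = "semi",
                   plant_species = c(shared, invasives),
                   plant_status = rep(c("native", "invasive"), c(2L, 3L)),
                   nodules = c(20L, 20L, 20L, 19L, 18L)),
    tibble::tibble(site = "site_H", invasion_status = "heavy",
                   plant_species = c(shared, invasives),
                   plant_status = rep(c("native", "invasive"), c(2L, 3L)),
                   nodules = c(20L, 20L, 20L, 20L, 19L))
  )
  species <- c(natives, invasives)
  n_taxa <- 2L * length(species)
  comm <- gen_sequence_community(
    n_taxa = n_taxa, genotypes_per_taxon = genotypes_per_taxon,
    seq_length = seq_length, within_taxon_identity = 0.99,
    between_taxon_identity = 0.95, seed = seed)
  taxa <- sort(unique(comm$truth$taxon))
  own <- stats::setNames(split(taxa, rep(seq_along(species), each = 2L)),
                         species)
  native_pool <- unlist(own[natives], use.names = FALSE)
  partner_rows <- function(sp) {
    if (scenario == "random") {
      tibble::tibble(plant_species = sp, taxon = taxa,
                     weight = rep(1, length(taxa)))
    } else if (scenario == "infiltration" && startsWith(sp, "invasive")) {
      # invaders tap the native pool: the private taxa of two natives
      k <- match(sp, invasives)
      reuse <- c(own[[natives[k]]], own[[natives[k + 1L]]])
      tibble::tibble(plant_species = sp, taxon = reuse,
                     weight = c(0.4, 0.25, 0.2, 0.15))
    } else {
      tibble::tibble(plant_species = sp, taxon = own[[sp]],
                     weight = c(0.65, 0.35))
    }
  }
  partners <- dplyr::bind_rows(lapply(species, partner_rows))
  clade_of_species <- function(sp, which_taxon) {
    if (startsWith(sp, "invasive")) "alpha-Bradyrhizobium"
    else if (which_taxon == 1L) "beta-Burkholderia" else "alpha-Rhizobium"
  }
  clades <- dplyr::bind_rows(lapply(species, function(sp) {
    tibble::tibble(taxon = own[[sp]],
                   clade = vapply(1:2, function(k) clade_of_species(sp, k),
                                  character(1)))
  }))
  list(design = survey_design(plants, partners, clades),
       community = comm$seqs, community_truth = comm$truth)
}
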