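#' Run the full interaction-web analysis
#'
#' Orchestrates the whole analysis from aligned sequences and nodule records:
#' taxon delineation at the requested similarity levels, per-site and
#' combined web construction, network metrics, nestedness significance
#' against fixed-marginal nulls, the modularity search with its own null
#' test, species-level metrics with native-vs-invasive comparisons, and the
#' clade-level G-tests. All randomness derives from `seed` (each stage draws
#' a child seed from it, so stages are independently reproducible).
#'
#' @param seqs An [aligned_seqs] object or a list of them (one per bacterial
#'   class; each is delineated separately and the taxa unioned).
#' @param table Nodule-record tibble (see [gen_survey()] for the schema);
#'   every `sequence_id` must occur in exactly one alignment.
#' @param levels Delineation levels, a subset of
#'   `c("genotype", "0.99", "0.98", "0.95")`.
#' @param nestedness_nulls Null webs for the WNODF test (default 1000).
#' @param modularity_nulls Null webs for the modularity test (default 100).
#' @param runs,steps Module-search budget per web (defaults 5 runs of 1e6
#'   moves).
#' @param seed Master seed.
#' @param out_dir Optional directory: writes `report.json`, per-level metric
#'   TSVs, partition TSVs and web matrices.
#' @return An `analysis_report` list: `networks` (one row per site x level
#'   plus the combined web, with B, P, connectance, IE, WNODF + p, Q + z + p,
#'   module count, H2', Gp, Gb), `species` (per-species metrics),
#'   `species_tests`, `modules` (memberships), `composition` (G-tests and
#'   occupancy percentages), `config`.
#' @export
run_pipeline <- function(seqs, table, levels = c("genotype", "0.98"),
                         nestedness_nulls = 1000, modularity_nulls = 100,
                         runs = 5, steps = 1e6, seed = 1,
                         out_dir = NULL) {
  if (inherits(seqs, "aligned_seqs")) seqs <- list(seqs)
  table <- tibble::as_tibble(table)
  levels <- sort(as.character(levels), decreasing = TRUE)  # content is order-free
  ids <- unlist(lapply(seqs, function(s) s$id))
  if (anyDuplicated(ids)) stop("duplicate sequence ids across alignments",
                               call. = FALSE)
  stray <- setdiff(table$sequence_id, ids)
  if (length(stray)) {
    stop("nodule records without a sequence, e.g. ", stray[[1L]],
         call. = FALSE)
  }

  assignment <- dplyr::bind_rows(lapply(seqs, delineate_taxa, levels = levels))
  sites <- unique(table$site)

  networks <- list(); species <- list(); modules <- list()
  for (lv in levels) {
    asg <- dplyr::filter(assignment, .data$level == lv)
    site_webs <- lapply(sites, function(s) build_web(table, asg, sites = s))
    names(site_webs) <- sites
    webs <- c(site_webs, list(combined = combine_webs(site_webs)))
    for (wname in names(webs)) {
      w <- webs[[wname]]
      net <- network_metrics(w)
      nest <- zscore_and_p(null_distribution(
        w, wnodf, n = nestedness_nulls,
        seed = stage_seed(seed, paste("nest", lv, wname))), tail = "greater")
      part <- find_modules(w, n_runs = runs, n_steps = steps,
                           seed = stage_seed(seed, paste("mod", lv, wname)))
      msig <- modularity_significance(
        w, partition = part, n_null = modularity_nulls,
        n_runs = runs, n_steps = steps,
        seed = stage_seed(seed, paste("modnull", lv, wname)))
      networks[[paste(lv, wname)]] <- dplyr::bind_cols(
        tibble::tibble(level = lv, web = wname), net,
        tibble::tibble(wnodf_z = nest$z, wnodf_p = nest$p,
                       Q = attr(part, "Q"), Q_z = msig$z, Q_p = msig$p,
                       n_modules = attr(part, "n_modules")))
      species[[paste(lv, wname)]] <- dplyr::bind_cols(
        tibble::tibble(level = lv, web = wname), species_metrics(w))
      modules[[paste(lv, wname)]] <- dplyr::bind_cols(
        tibble::tibble(level = lv, web = wname), tibble::as_tibble(part))
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_web_tsv(w, file.path(out_dir,
                                   sprintf("web_%s_%s.tsv", lv, wname)))
      }
    }
  }
  networks <- dplyr::bind_rows(networks)
  species <- dplyr::bind_rows(species)
  modules <- dplyr::bind_rows(modules)

  species_tests <- species_metric_tests(species, sites)
  composition <- composition_report(table)

  report <- structure(list(
    networks = networks, species = species, species_tests = species_tests,
    modules = modules, composition = composition,
    config = list(levels = levels, nestedness_nulls = nestedness_nulls,
                  modularity_nulls = modularity_nulls, runs = runs,
                  steps = steps, seed = seed,
                  version = as.character(utils::packageVersion("rhizoweb")))),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# native-vs-invasive and across-site comparisons of plant-level metrics,
# averaging species over sites first (per-site webs only, not the combined)
species_metric_tests <- function(species, sites) {
  plants <- dplyr::filter(species, .data$side == "plant",
                          .data$web %in% sites)
  out <- list()
  for (metric in c("degree", "effective_partners", "dprime")) {
    if ("group" %in% names(plants) &&
        dplyr::n_distinct(plants$group) >= 2L) {
      out[[paste("status", metric)]] <- purrr::possibly(
        function() dplyr::bind_cols(
          tibble::tibble(comparison = "native_vs_invasive"),
          compare_species_metrics(plants, metric, "group")),
        otherwise = NULL)()
    }
    if (dplyr::n_distinct(plants$web) >= 2L) {
      out[[paste("site", metric)]] <- purrr::possibly(
        function() dplyr::bind_cols(
          tibble::tibble(comparison = "across_sites"),
          compare_species_metrics(plants, metric, "web")),
        otherwise = NULL)()
    }
  }
  dplyr::bind_rows(out)
}

composition_report <- function(table) {
  gtests <- list()
  for (gr in c("status_at_invaded", "gradient_for_shared_natives")) {
    res <- tryCatch({
      ct <- clade_table(table, gr)
      dplyr::bind_cols(tibble::tibble(grouping = gr), g_test(ct))
    }, error = function(e) NULL)
    if (!is.null(res)) gtests[[gr]] <- res
  }
  list(g_tests = dplyr::bind_rows(gtests),
       occupancy = clade_occupancy(table))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d network rows (levels: %s), seed %s\n",
              nrow(x$networks), paste(x$config$levels, collapse = ", "),
              format(x$config$seed)))
  print(x$networks, ...)
  invisible(x)
}

#' @export
tidy.analysis_report <- function(x, ...) x$networks

#' @export
glance.analysis_report <- function(x, ...) {
  tibble::tibble(levels = length(x$config$levels),
                 webs = nrow(x$networks),
                 seed = x$config$seed)
}

#' Write an analysis report to disk
#'
#' `report.json` carries everything (networks, species metrics and tests,
#' module memberships, composition tests, config); the network and species
#' tables are also written as TSVs.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    networks = report$networks,
    species = report$species,
    species_tests = if (nrow(report$species_tests)) {
      dplyr::select(report$species_tests, -dplyr::any_of("group_summary"))
    } else report$species_tests,
    modules = report$modules,
    g_tests = report$composition$g_tests,
    occupancy = report$composition$occupancy,
    config = report$config)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$networks, file.path(out_dir, "networks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$species, file.path(out_dir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$modules, file.path(out_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Simulate a study-style survey and analyse it end to end
#'
#' Builds the three-site invasion-gradient design of [scenario_design()],
#' simulates the sequence community and nodule survey, and runs
#' [run_pipeline()] on the result. The planted truth is attached to the
#' report so recovery can be checked.
#'
#' @param scenario `"co-introduction"`, `"infiltration"` or `"random"`.
#' @param seed Master seed for community, survey and analysis.
#' @param ... Passed on to [run_pipeline()] (levels, null counts, budgets).
#' @return An `analysis_report` with extra elements `table` (the simulated
#'   records), `planted` (per-nodule true taxon/genotype) and `scenario`.
#' @export
simulate_and_run <- function(scenario = c("co-introduction", "infiltration",
                                          "random"),
                             seed = 1, ...) {
  scenario <- match.arg(scenario)
  sc <- scenario_design(scenario, seed = stage_seed(seed, "community"))
  survey <- gen_survey(sc$design, sc$community, sc$community_truth,
                       seed = stage_seed(seed, "survey"))
  report <- run_pipeline(survey$seqs, survey$table, seed = seed, ...)
  report$table <- survey$table
  report$planted <- survey$truth
  report$scenario <- scenario
  report
}
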