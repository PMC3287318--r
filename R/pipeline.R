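#' Run the full diversification / community-structure analysis
#'
#' Orchestrates the complete analysis on a chronogram plus an occurrence
#' table: fits and compares the diversification model suite, computes the
#' LTT curve with a simulation envelope and per-window rates, runs the
#' Pi_ST partial-randomization profiles at the regional scale (island
#' species pools) and at the local scale (inner-reef versus outer-slope
#' lists within each island), summarises community structure, and writes
#' every table plus a machine-readable JSON manifest to `out_dir`.
#'
#' Any occurrence species absent from the tree is a hard error listing the
#' offenders — species are never dropped silently. Without a sea-level
#' interval table the covariate model is skipped with a warning.
#'
#' @param tree a [chronogram] or path to a Newick file.
#' @param occurrence an [occurrence_matrix] or path to a wide csv.
#' @param metadata optional path to a `site,island,habitat` csv (needed when
#'   `occurrence` is a path and site metadata is wanted).
#' @param intervals optional [sea_level_intervals] or path to a csv.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it, so a rerun with the same inputs is byte-identical.
#' @param regional_thresholds,local_thresholds Pi_ST threshold grids (Myr).
#' @param replicates randomizations per Pi_ST test (default 999).
#' @param envelope_reps simulated trees for the LTT envelope (default 200).
#' @param window_width LTT window width in Myr (default 10).
#' @param grid_resolution breakpoint search resolution in Myr (default 0.1).
#' @param max_breakpoints largest breakpoint count fitted (default 2).
#' @return (invisibly) a list with every computed table.
#' @export
run_analysis <- function(tree, occurrence, metadata = NULL, intervals = NULL,
                         out_dir, seed = 1,
                         regional_thresholds = seq(5, 50, by = 5),
                         local_thresholds = seq(10, 50, by = 10),
                         replicates = 999, envelope_reps = 200,
                         window_width = 10, grid_resolution = 0.1,
                         max_breakpoints = 2) {
  if (is.character(tree)) tree <- read_chronogram(tree)
  stopifnot(inherits(tree, "chronogram"))
  if (is.character(occurrence))
    occurrence <- read_occurrence(occurrence, metadata_file = metadata)
  stopifnot(inherits(occurrence, "occurrence_matrix"))
  if (is.character(intervals)) intervals <- read_sea_levels(intervals)

  unknown <- setdiff(occ_species(occurrence), tree$phy$tip.label)
  if (length(unknown))
    stop("occurrence species absent from the tree: ",
         paste(unknown, collapse = ", "))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  message("fitting diversification models (n = ", tree$n, ")")
  if (is.null(intervals))
    warning("no sea-level intervals given: covariate model skipped")
  models <- model_comparison(tree, intervals,
                             max_breakpoints = max_breakpoints,
                             grid_resolution = grid_resolution)
  tsv(models, "model_comparison.tsv")

  message("LTT envelope: ", envelope_reps, " conditioned simulations")
  fits <- attr(models, "fits")
  env <- ltt_envelope(tree, fits$yule, reps = envelope_reps,
                      seed = derive_seed(seed, 1))
  tsv(env, "ltt_envelope.tsv")
  wr <- window_rates(tree, width = window_width)
  tsv(wr, "window_rates.tsv")

  message("Pi_ST regional profile: ", length(regional_thresholds),
          " thresholds x ", replicates, " randomizations")
  regional <- NULL
  local_profiles <- list()
  if (!is.null(occurrence$metadata)) {
    pools <- pool_sites(occurrence, by = "island")
    regional <- pist_profile(pools, tree, regional_thresholds,
                             reps = replicates, seed = derive_seed(seed, 2))
    tsv(regional, "pist_regional.tsv")
    md <- occurrence$metadata
    for (isl in unique(md$island)) {
      loc <- occ_subset(occurrence, md$site[md$island == isl])
      if (length(unique(loc$metadata$habitat)) < 2) {
        message("island ", isl, ": a single habitat, local profile skipped")
        next
      }
      lists <- pool_sites(loc, by = "habitat")
      message("Pi_ST local profile: ", isl)
      p <- pist_profile(lists, tree, local_thresholds, reps = replicates,
                        seed = derive_seed(seed, 3 + match(isl, unique(md$island))))
      local_profiles[[isl]] <- p
      tsv(p, sprintf("pist_local_%s.tsv", gsub("[^A-Za-z0-9]", "_", isl)))
    }
    summary_tab <- community_summary(occurrence)
    tsv(summary_tab, "community_summary.tsv")
  } else {
    summary_tab <- NULL
    warning("no site metadata: Pi_ST profiles and the community summary ",
            "need island/habitat information and were skipped")
  }

  manifest <- list(
    package = "reefdiv",
    version = as.character(utils::packageVersion("reefdiv")),
    r_version = R.version.string,
    seed = seed,
    n_tips = tree$n,
    root_age = tree$root_age,
    n_sites = ncol(occurrence$presence),
    n_species = nrow(occurrence$presence),
    replicates = replicates,
    envelope_reps = envelope_reps,
    regional_thresholds = regional_thresholds,
    local_thresholds = local_thresholds,
    window_width = window_width,
    grid_resolution = grid_resolution,
    max_breakpoints = max_breakpoints,
    best_model = models$model[models$best],
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(models = models, ltt = env, windows = wr,
                 regional = regional, local = local_profiles,
                 summary = summary_tab, manifest = manifest))
}
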