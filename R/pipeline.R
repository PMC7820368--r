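#' Pipeline run configuration
#'
#' Collects the input locations and analysis parameters for one end-to-end
#' run. The input directory must follow the bundle layout written by
#' [synth_bundle()] (and mirrored by field data once arranged the same
#' way): \code{manifest.csv} + \code{spectra/}, \code{background.csv},
#' \code{irradiance.csv}, \code{communities.csv}, \code{guilds.csv},
#' \code{transects.csv}, \code{seep_dims.csv}, \code{tree.nwk}.
#'
#' @param input_dir bundle directory.
#' @param n_iter null-model iterations per community (default 10000).
#' @param seed master integer seed for all randomisation.
#' @param min_guild_members minimum guild members for a community to enter
#'   a guild-restricted scenario (default 3).
#' @param grid_step wavelength grid step in nm (default 1).
#' @param null_pool \code{"restricted"} (guild scenarios sample nulls from
#'   the guild-restricted pool; default) or \code{"full"}.
#' @param vision_systems named list of [visual_system()] objects; default
#'   the template bee trichromat and fly tetrachromat.
#' @param out_dir optional directory to write result CSVs and a JSON run
#'   manifest.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(input_dir, n_iter = 10000, seed = 1L,
                       min_guild_members = 3, grid_step = 1,
                       null_pool = c("restricted", "full"),
                       vision_systems = NULL, out_dir = NULL) {
  null_pool <- match.arg(null_pool)
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(vision_systems))
    vision_systems <- list(bee = synth_bee_system(step = grid_step),
                           fly = synth_fly_system(step = grid_step))
  structure(list(input_dir = input_dir, n_iter = n_iter,
                 seed = as.integer(seed),
                 min_guild_members = min_guild_members,
                 grid_step = grid_step, null_pool = null_pool,
                 vision_systems = vision_systems, out_dir = out_dir),
            class = "run_config")
}

read_bundle <- function(cfg) {
  dir <- cfg$input_dir
  need <- c("manifest.csv", "background.csv", "irradiance.csv",
            "communities.csv", "guilds.csv", "transects.csv",
            "seep_dims.csv", "tree.nwk")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop(sprintf("missing required input file(s): %s",
                 paste(missing, collapse = ", ")))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  measurements <- lapply(manifest$measurement, function(m) {
    resample_spectrum(read_spectrum(file.path(dir, "spectra",
                                              paste0(m, ".csv"))),
                      step = cfg$grid_step)
  })
  names(measurements) <- manifest$measurement
  flowers <- species_composites(measurements, manifest)
  background <- resample_spectrum(
    read_spectrum(file.path(dir, "background.csv")), step = cfg$grid_step)
  irradiance <- resample_spectrum(
    read_spectrum(file.path(dir, "irradiance.csv"), kind = "irradiance"),
    step = cfg$grid_step)
  list(flowers = flowers, background = background, irradiance = irradiance,
       communities = utils::read.csv(file.path(dir, "communities.csv")),
       guilds = utils::read.csv(file.path(dir, "guilds.csv")),
       transects = utils::read.csv(file.path(dir, "transects.csv")),
       dims = utils::read.csv(file.path(dir, "seep_dims.csv")),
       tree = ape::read.tree(file.path(dir, "tree.nwk")))
}

scenario_dispersion <- function(communities, d, index_scores, n_iter, seed) {
  disp <- community_dispersion(communities, d, n_iter = n_iter, seed = seed)
  idx <- index_scores[as.character(disp$seep_id)]
  tbl <- rbind(
    data.frame(seep_id = disp$seep_id, community_type = "observed",
               mean_disparity = disp$observed_mean, seep_index = idx),
    data.frame(seep_id = disp$seep_id, community_type = "null",
               mean_disparity = disp$null_grand_mean, seep_index = idx))
  list(per_seep = disp, dispersion_table = tbl)
}

#' Run the full floral-color community analysis
#'
#' Orchestrates all stages from one configuration: composite per-species
#' spectra, habitat metrics and seep index, pairwise chromatic distance
#' matrices per visual system, the four dispersion scenarios (bee/all,
#' fly/all, bee/bee-visited, fly/fly-visited) with richness-matched
#' nulls, ANCOVA and Moran's I per scenario, and the phylogenetic (MPD)
#' analysis. Species listed in communities but lacking spectra are
#' excluded from every analysis with a warning naming them. The run is
#' deterministic given the seed.
#'
#' @param cfg a [run_config()].
#' @return list of class \code{"chromacomm_run"} with elements
#'   \code{metrics} (seep metrics + index), \code{seep_index},
#'   \code{distance_matrices}, \code{scenarios} (per-seep tables, ANCOVA,
#'   Moran's I for each of the four scenarios), \code{phylo} (MPD table,
#'   ANCOVA, Moran's I), \code{exclusions}, \code{params}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  b <- read_bundle(cfg)
  pool <- names(b$flowers)
  comm_sp <- unique(b$communities$species)
  unmeasured <- setdiff(comm_sp, pool)
  if (length(unmeasured)) {
    warning(sprintf("excluding %d species without spectra: %s",
                    length(unmeasured), paste(unmeasured, collapse = ", ")))
    b$communities <- b$communities[!b$communities$species %in% unmeasured, ,
                                   drop = FALSE]
  }
  if (nrow(b$communities) == 0L) stop("empty pool after exclusions")

  metrics <- seep_metrics(b$transects, b$dims)
  si <- seep_index(metrics)
  metrics$seep_index <- si$scores[as.character(metrics$seep_id)]
  coords <- as.matrix(metrics[, c("x", "y")])
  rownames(coords) <- metrics$seep_id

  dmats <- lapply(cfg$vision_systems, function(vs)
    color_distance_matrix(b$flowers, b$background, b$irradiance, vs))

  scen_def <- list(
    bee_all = list(vision = "bee", guild = NA),
    fly_all = list(vision = "fly", guild = NA),
    bee_visited = list(vision = "bee", guild = "bee"),
    fly_visited = list(vision = "fly", guild = "fly"))

  run_one <- function(sdef, stream) {
    comm <- b$communities
    d <- dmats[[sdef$vision]]
    if (!is.na(sdef$guild)) {
      comm <- guild_restrict(comm, b$guilds, guild = sdef$guild,
                             min_members = cfg$min_guild_members)
      if (cfg$null_pool == "restricted") {
        col <- paste0(sdef$guild, "_visited")
        gp <- intersect(pool, b$guilds$species[as.logical(b$guilds[[col]])])
        if (length(gp) >= 2L) d <- d[gp, gp]
      }
    }
    if (length(unique(comm$seep_id)) < 3L)
      return(list(per_seep = NULL, note = "fewer than 3 communities; skipped"))
    sc <- scenario_dispersion(comm, d, si$scores, cfg$n_iter,
                              substream_seed(cfg$seed, 0L, stream))
    anc <- dispersion_ancova(sc$dispersion_table)
    ids <- names(anc$residuals_by_seep)
    mor <- morans_i(as.numeric(anc$residuals_by_seep), coords[ids, ])
    c(sc, list(ancova = anc, morans = mor))
  }
  scenarios <- lapply(seq_along(scen_def),
                      function(i) run_one(scen_def[[i]], i))
  names(scenarios) <- names(scen_def)

  tree_pool <- intersect(b$tree$tip.label, unique(b$communities$species))
  ptree <- ape::keep.tip(b$tree, tree_pool)
  pd <- patristic_matrix(ptree)
  mpd <- mpd_dispersion(b$communities, pd, n_iter = cfg$n_iter,
                        seed = substream_seed(cfg$seed, 0L, 99L))
  mtbl <- rbind(
    data.frame(seep_id = mpd$seep_id, community_type = "observed",
               mean_disparity = mpd$observed_mpd,
               seep_index = si$scores[as.character(mpd$seep_id)]),
    data.frame(seep_id = mpd$seep_id, community_type = "null",
               mean_disparity = mpd$null_mean,
               seep_index = si$scores[as.character(mpd$seep_id)]))
  manc <- dispersion_ancova(mtbl)
  mmor <- morans_i(as.numeric(manc$residuals_by_seep),
                   coords[names(manc$residuals_by_seep), ])

  res <- structure(list(metrics = metrics, seep_index = si,
                        distance_matrices = dmats, scenarios = scenarios,
                        phylo = list(per_seep = mpd, ancova = manc,
                                     morans = mmor),
                        exclusions = unmeasured,
                        params = list(n_iter = cfg$n_iter, seed = cfg$seed,
                                      min_guild_members = cfg$min_guild_members,
                                      grid_step = cfg$grid_step,
                                      null_pool = cfg$null_pool)),
                   class = "chromacomm_run")
  if (!is.null(cfg$out_dir)) write_run(res, cfg$out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$metrics, file.path(out_dir, "seep_metrics.csv"),
                   row.names = FALSE)
  for (nm in names(res$distance_matrices))
    utils::write.csv(res$distance_matrices[[nm]],
                     file.path(out_dir, paste0("delta_s_", nm, ".csv")))
  for (nm in names(res$scenarios)) {
    ps <- res$scenarios[[nm]]$per_seep
    if (!is.null(ps))
      utils::write.csv(ps, file.path(out_dir, paste0("dispersion_", nm, ".csv")),
                       row.names = FALSE)
  }
  utils::write.csv(res$phylo$per_seep, file.path(out_dir, "dispersion_mpd.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(params = res$params, exclusions = res$exclusions,
         pc1_variance_explained = res$seep_index$variance_explained,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.chromacomm_run <- function(x, ...) {
  cat("chromacomm pipeline run\n")
  cat(sprintf("  pool: %d species with spectra; %d excluded\n",
              nrow(x$distance_matrices[[1]]), length(x$exclusions)))
  cat(sprintf("  seeps: %d; PC1 variance explained: %.1f%%\n",
              nrow(x$metrics), 100 * x$seep_index$variance_explained))
  for (nm in names(x$scenarios)) {
    s <- x$scenarios[[nm]]
    if (is.null(s$per_seep)) {
      cat(sprintf("  %-12s %s\n", nm, s$note)); next
    }
    cat(sprintf("  %-12s mean z = %+.2f; overall F(%d,%d) = %.2f; interaction p = %.4g\n",
                nm, mean(s$per_seep$z), s$ancova$overall$df1,
                s$ancova$overall$df2, s$ancova$overall$F,
                s$ancova$terms$p[s$ancova$terms$term == "community_type:seep_index"]))
  }
  cat(sprintf("  phylo (MPD)  mean z = %+.2f; overall F(%d,%d) = %.2f\n",
              mean(x$phylo$per_seep$z), x$phylo$ancova$overall$df1,
              x$phylo$ancova$overall$df2, x$phylo$ancova$overall$F))
  invisible(x)
}
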