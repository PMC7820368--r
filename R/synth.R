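#' Configuration for the synthetic metacommunity generator
#'
#' Defaults emulate the study system this package targets: a regional pool
#' of 55 co-flowering species, 14 seep communities with 6-20 species each,
#' flower colors drawn from five archetypes (UV-reflecting white, blue,
#' yellow, UV-absorbing white, purple), neutral (random) assembly, visitor
#' guilds with bees commoner than flies, seeps tens of metres long
#' surveyed at 0.25 m point intercepts, and a pure-birth phylogeny over
#' the pool.
#'
#' @param seed master integer seed; every downstream draw derives from it.
#' @param n_pool regional pool size.
#' @param n_seeps number of seep communities.
#' @param richness_range inclusive range of community richness.
#' @param assembly \code{"random"}, \code{"overdispersed"} or
#'   \code{"clustered"}.
#' @param strength assembly bias strength (0 = random; softmax
#'   temperature on standardised selection scores).
#' @param archetype_weights mixture weights over the five color
#'   archetypes.
#' @param guild_p named probabilities that a pool species is bee- /
#'   fly-visited.
#' @param length_range,width_range seep geometry ranges in metres.
#' @param density_range range of plant cover fraction along transects.
#' @param extent_km side of the square region in which seeps are placed.
#' @param birth_rate pure-birth speciation rate for the synthetic tree.
#' @param grid_step wavelength grid step in nm.
#' @return a validated list of class \code{"synth_config"}.
#' @export
synth_config <- function(seed = 1L, n_pool = 55L, n_seeps = 14L,
                         richness_range = c(6L, 20L),
                         assembly = c("random", "overdispersed", "clustered"),
                         strength = 0,
                         archetype_weights = rep(1 / 5, 5),
                         guild_p = c(bee = 0.85, fly = 0.55),
                         length_range = c(20, 100),
                         width_range = c(1, 5),
                         density_range = c(0.2, 0.8),
                         extent_km = 14, birth_rate = 1, grid_step = 1) {
  assembly <- match.arg(assembly)
  stopifnot(n_pool >= 3, n_seeps >= 1, length(richness_range) == 2,
            richness_range[1] >= 2, richness_range[2] <= n_pool,
            richness_range[1] <= richness_range[2],
            strength >= 0, length(archetype_weights) == 5,
            all(archetype_weights >= 0), sum(archetype_weights) > 0,
            all(guild_p >= 0 & guild_p <= 1), birth_rate > 0,
            grid_step > 0)
  structure(list(seed = as.integer(seed), n_pool = as.integer(n_pool),
                 n_seeps = as.integer(n_seeps),
                 richness_range = as.integer(richness_range),
                 assembly = assembly, strength = strength,
                 archetype_weights = archetype_weights / sum(archetype_weights),
                 guild_p = guild_p, length_range = length_range,
                 width_range = width_range, density_range = density_range,
                 extent_km = extent_km, birth_rate = birth_rate,
                 grid_step = grid_step),
            class = "synth_config")
}

#' Visual-pigment absorbance template sensitivity
#'
#' Generates a photoreceptor spectral sensitivity from the alpha band of
#' the standard A1 visual-pigment absorbance template, normalised to
#' peak 1 on the analysis grid: strictly positive, unimodal, peaked at
#' \code{lambda_max}. A template stand-in for measured sensitivities,
#' adequate for testing the modeling chain (the ultraviolet beta band is
#' omitted to keep the curves unimodal).
#'
#' @param lambda_max peak wavelength in nm (within the grid).
#' @param step,lower,upper grid definition in nm.
#' @return a sensitivity [spectrum()].
#' @export
pigment_sensitivity <- function(lambda_max, step = 1, lower = 300, upper = 700) {
  if (lambda_max < lower || lambda_max > upper)
    stop("lambda_max outside the wavelength grid")
  alpha_band <- function(wl, lmax) {
    x <- lmax / wl
    a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
  }
  # the raw template's maximum sits ~1 nm off its nominal peak; recenter
  # numerically so the realised argmax is lambda_max
  fine <- seq(max(lower - 50, 200), upper + 50, by = 0.05)
  adj <- lambda_max
  for (i in 1:2) {
    peak <- fine[which.max(alpha_band(fine, adj))]
    adj <- adj + (lambda_max - peak)
  }
  wl <- seq(lower, upper, by = step)
  alpha <- alpha_band(wl, adj)
  spectrum(wl, alpha / max(alpha), kind = "sensitivity")
}

#' Template visual systems
#'
#' Builds a [visual_system()] from pigment-template sensitivities at the
#' given peak wavelengths. \code{synth_bee_system()} is a honeybee-like
#' trichromat (peaks 344, 436, 544 nm; Weber 0.05; abundances
#' 2.125:1:9.375 anchored on G); \code{synth_fly_system()} a
#' hoverfly-like tetrachromat (peaks 350, 425, 450, 550 nm; Weber 0.05;
#' abundances 1:2.33:1:2.33 anchored on R7y).
#'
#' @param lambda_max named numeric vector of receptor peak wavelengths.
#' @param weber Weber fraction.
#' @param abundances named relative abundances.
#' @param reference reference receptor (default: most abundant).
#' @param step grid step in nm.
#' @return a [visual_system()].
#' @export
synth_visual_system <- function(lambda_max, weber, abundances,
                                reference = NULL, step = 1) {
  if (is.null(names(lambda_max)))
    names(lambda_max) <- paste0("r", seq_along(lambda_max))
  sens <- lapply(lambda_max, pigment_sensitivity, step = step)
  visual_system(sens, weber = weber, abundances = abundances,
                reference = reference)
}

#' @rdname synth_visual_system
#' @export
synth_bee_system <- function(step = 1) {
  synth_visual_system(c(UV = 344, B = 436, G = 544), weber = 0.05,
                      abundances = c(UV = 2.125, B = 1, G = 9.375),
                      reference = "G", step = step)
}

#' @rdname synth_visual_system
#' @export
synth_fly_system <- function(step = 1) {
  synth_visual_system(c(R7p = 350, R7y = 425, R8p = 450, R8y = 550),
                      weber = 0.05,
                      abundances = c(R7p = 1, R7y = 2.33, R8p = 1, R8y = 2.33),
                      reference = "R7y", step = step)
}

# five flower-color archetypes as smooth functions on the grid
flower_archetypes <- function(wl) {
  list(
    uv_white   = 0.55 + 0.25 * stats::plogis((wl - 340) / 40),
    blue       = 0.05 + 0.60 * exp(-((wl - 450) / 35)^2),
    yellow     = 0.05 + 0.75 * stats::plogis((wl - 520) / 12),
    white_uvabs = 0.04 + 0.80 * stats::plogis((wl - 400) / 15),
    purple     = 0.08 + 0.45 * exp(-((wl - 430) / 40)^2) +
                 0.50 * stats::plogis((wl - 600) / 15)
  )
}

smooth_perturbation <- function(wl, n_bumps = 3, amp_sd = 0.04) {
  p <- numeric(length(wl))
  for (b in seq_len(n_bumps)) {
    p <- p + stats::rnorm(1, 0, amp_sd) *
      exp(-((wl - stats::runif(1, 300, 700)) / stats::runif(1, 25, 80))^2)
  }
  p
}

#' Generate synthetic reflectance spectra, background and illuminant
#'
#' Flower spectra are drawn from the archetype mixture with smooth
#' per-species perturbations, clipped to \[0.001, 1\]; the foliage
#' background is a low-reflectance curve with a green bump near 550 nm;
#' the illuminant is a smooth daylight-like photon-flux curve (5800 K
#' black-body), positive over the whole grid.
#'
#' @param cfg a [synth_config()].
#' @return list with \code{flowers} (named list of reflectance spectra),
#'   \code{archetype} (named assignment), \code{background},
#'   \code{irradiance}.
#' @export
synth_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(substream_seed(cfg$seed, 1L, stream = 1L))
  wl <- seq(300, 700, by = cfg$grid_step)
  arch <- flower_archetypes(wl)
  species <- sprintf("sp%02d", seq_len(cfg$n_pool))
  assign <- sample(names(arch), cfg$n_pool, replace = TRUE,
                   prob = cfg$archetype_weights)
  names(assign) <- species
  flowers <- lapply(species, function(sp) {
    v <- arch[[assign[[sp]]]] + smooth_perturbation(wl)
    spectrum(wl, pmin(pmax(v, 0.001), 1), kind = "reflectance")
  })
  names(flowers) <- species
  background <- spectrum(wl, 0.04 + 0.08 * exp(-((wl - 550) / 35)^2) +
                               0.02 * stats::plogis((wl - 680) / 10),
                         kind = "reflectance")
  bb <- 1.43877e7 / (wl * 5800)
  irr <- wl^-4 / (exp(bb) - 1)
  irradiance <- spectrum(wl, irr / max(irr), kind = "irradiance")
  list(flowers = flowers, archetype = assign, background = background,
       irradiance = irradiance)
}

# one biased community draw: greedy softmax selection on a score
assemble_community <- function(pool, k, d, rule, strength) {
  if (rule == "random" || strength == 0)
    return(sample(pool, k))
  sel <- sample(pool, 1L)
  while (length(sel) < k) {
    cand <- setdiff(pool, sel)
    score <- vapply(cand, function(sp) {
      dd <- d[sp, sel]
      if (rule == "overdispersed") min(dd) else -mean(dd)
    }, numeric(1))
    s <- stats::sd(score)
    z <- if (is.na(s) || s == 0) rep(0, length(score)) else
      (score - mean(score)) / s
    pr <- exp(strength * z)
    sel <- c(sel, sample(cand, 1L, prob = pr / sum(pr)))
  }
  sel
}

#' Generate a full synthetic metacommunity input bundle
#'
#' Given the pool disparity matrix (which the biased assembly rules act
#' on), draws community memberships for each seep under the configured
#' assembly rule, visitor-guild labels, transect survey records whose
#' summary recovers each seep's realised richness exactly, seep
#' dimensions and coordinates, and a pure-birth ultrametric phylogeny
#' over the pool.
#'
#' @param cfg a [synth_config()].
#' @param d symmetric disparity matrix over the pool (species dimnames).
#' @return list with \code{communities}, \code{guilds}, \code{transects},
#'   \code{dims} (data.frames) and \code{tree} (ape \code{phylo}).
#' @export
synth_metacommunity <- function(cfg, d) {
  stopifnot(inherits(cfg, "synth_config"))
  pool <- rownames(d)
  if (length(pool) < cfg$richness_range[2])
    stop("richness range exceeds pool size")
  set.seed(substream_seed(cfg$seed, 1L, stream = 2L))
  seeps <- sprintf("seep%02d", seq_len(cfg$n_seeps))
  # a latent seep-size factor couples geometry, plant cover and richness:
  # larger seeps are denser and more species-rich, the correlation
  # structure that makes a single habitat axis (PC1) meaningful
  u <- stats::runif(cfg$n_seeps)
  blend <- function(uu, sd) pmin(pmax(uu + stats::rnorm(cfg$n_seeps, 0, sd),
                                      0), 1)
  rvals <- seq(cfg$richness_range[1], cfg$richness_range[2])
  rich <- rvals[pmax(1L, ceiling(blend(u, 0.15) * length(rvals)))]
  communities <- do.call(rbind, lapply(seq_along(seeps), function(i) {
    data.frame(seep_id = seeps[i],
               species = assemble_community(pool, rich[i], d,
                                            cfg$assembly, cfg$strength))
  }))
  guilds <- data.frame(species = pool,
                       bee_visited = stats::runif(length(pool)) < cfg$guild_p[["bee"]],
                       fly_visited = stats::runif(length(pool)) < cfg$guild_p[["fly"]])
  dims <- data.frame(seep_id = seeps,
                     length_m = cfg$length_range[1] + blend(u, 0.1) *
                       diff(cfg$length_range))
  for (j in 1:5)
    dims[[paste0("width", j)]] <- cfg$width_range[1] + blend(u, 0.2) *
      diff(cfg$width_range)
  dens_target <- cfg$density_range[1] + blend(u, 0.15) *
    diff(cfg$density_range)
  # non-coincident coordinates (km)
  repeat {
    dims$x <- stats::runif(cfg$n_seeps, 0, cfg$extent_km)
    dims$y <- stats::runif(cfg$n_seeps, 0, cfg$extent_km)
    if (cfg$n_seeps < 2L ||
        min(stats::dist(cbind(dims$x, dims$y))) > 0.05) break
  }
  transects <- do.call(rbind, lapply(seq_along(seeps), function(i) {
    members <- communities$species[communities$seep_id == seeps[i]]
    n_pts <- floor(min(dims$length_m[i], 100) / 0.25) + 1L
    dens <- dens_target[i]
    make_transect <- function(tname, with_all_species) {
      n_plant <- max(if (with_all_species) length(members) else 1L,
                     round(dens * n_pts))
      n_plant <- min(n_plant, n_pts)
      sp <- character(n_pts)
      contact <- rep("bare", n_pts)
      slots <- sample.int(n_pts, n_plant)
      contact[slots] <- "plant"
      fill <- if (with_all_species)
        c(members, sample(members, n_plant - length(members), replace = TRUE))
      else sample(members, n_plant, replace = TRUE)
      sp[slots] <- fill
      data.frame(seep_id = seeps[i], transect = tname,
                 position_m = (seq_len(n_pts) - 1L) * 0.25,
                 contact = contact, species = sp)
    }
    rbind(make_transect("center", TRUE), make_transect("edge", FALSE))
  }))
  tree <- ape::rphylo(length(pool), birth = cfg$birth_rate, death = 0)
  tree$tip.label <- sample(pool)
  list(communities = communities, guilds = guilds, transects = transects,
       dims = dims, tree = tree)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates spectra and a metacommunity under one configuration and
#' writes them in exactly the file layout [run_pipeline()] reads:
#' per-measurement spectrum CSVs plus a manifest, background and
#' irradiance CSVs, community, guild, transect and seep-dimension CSVs,
#' and a Newick tree. The assembly rules act on the bee-view disparity
#' matrix.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @param n_missing number of extra species listed in communities but
#'   lacking spectra (exercises the pipeline's exclusion path; default 0).
#' @return \code{dir}, invisibly.
#' @export
synth_bundle <- function(cfg, dir, n_missing = 0L) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "spectra"), showWarnings = FALSE)
  sp <- synth_spectra(cfg)
  bee <- synth_bee_system(step = cfg$grid_step)
  d <- color_distance_matrix(sp$flowers, sp$background, sp$irradiance, bee)
  meta <- synth_metacommunity(cfg, d)
  manifest <- do.call(rbind, lapply(names(sp$flowers), function(s) {
    data.frame(measurement = paste0(s, "_m1"), species = s,
               component = "whole", area_weight = 1)
  }))
  for (i in seq_len(nrow(manifest))) {
    fl <- sp$flowers[[manifest$species[i]]]
    utils::write.csv(data.frame(wl = fl$wl, reflectance = fl$value * 100),
                     file.path(dir, "spectra",
                               paste0(manifest$measurement[i], ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(wl = sp$background$wl,
                              reflectance = sp$background$value * 100),
                   file.path(dir, "background.csv"), row.names = FALSE)
  utils::write.csv(data.frame(wl = sp$irradiance$wl,
                              irradiance = sp$irradiance$value),
                   file.path(dir, "irradiance.csv"), row.names = FALSE)
  communities <- meta$communities
  if (n_missing > 0L) {
    extra <- sprintf("unmeasured%02d", seq_len(n_missing))
    seeps <- unique(communities$seep_id)
    set.seed(substream_seed(cfg$seed, 1L, stream = 3L))
    communities <- rbind(communities,
                         data.frame(seep_id = sample(seeps, n_missing,
                                                     replace = TRUE),
                                    species = extra))
  }
  utils::write.csv(communities, file.path(dir, "communities.csv"),
                   row.names = FALSE)
  utils::write.csv(meta$guilds, file.path(dir, "guilds.csv"),
                   row.names = FALSE)
  utils::write.csv(meta$transects, file.path(dir, "transects.csv"),
                   row.names = FALSE)
  utils::write.csv(meta$dims, file.path(dir, "seep_dims.csv"),
                   row.names = FALSE)
  ape::write.tree(meta$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
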