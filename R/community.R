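#' Mean pairwise disparity of a community
#'
#' The mean of all unordered pairwise distances among a community's
#' members, taken from a symmetric disparity matrix (chromatic distances
#' or patristic distances). Undefined for fewer than two members.
#'
#' @param members character vector of member species (>= 2, all present in
#'   the matrix).
#' @param d symmetric disparity matrix with species dimnames.
#' @return the mean over the \eqn{k(k-1)/2} unordered pairs.
#' @export
mean_pairwise_disparity <- function(members, d) {
  members <- unique(as.character(members))
  k <- length(members)
  if (k < 2L)
    stop("undefined mean disparity: community has fewer than two members")
  absent <- setdiff(members, rownames(d))
  if (length(absent))
    stop(sprintf("species absent from the disparity matrix: %s",
                 paste(absent, collapse = ", ")))
  sub <- d[members, members]
  sum(sub) / (k * (k - 1))
}

#' Richness-matched null distribution of community mean disparity
#'
#' Draws \code{n_iter} random communities of the given richness from the
#' regional pool (uniformly, without replacement within each draw),
#' computes each random community's mean pairwise disparity, and
#' summarises the null distribution. When an observed value is supplied a
#' standardised effect size z = (observed - null mean) / null SD is
#' attached; |z| > ~2 flags over- (positive) or underdispersion
#' (negative) relative to random assembly.
#'
#' @param richness community size to sample (2 <= richness <= pool size).
#' @param d symmetric disparity matrix over the regional pool.
#' @param n_iter number of random communities (default 10000).
#' @param seed optional integer seed for reproducible draws.
#' @param observed optional observed community mean disparity.
#' @return object of class \code{"null_summary"}: list with
#'   \code{n_iter}, \code{null_means}, \code{grand_mean}, \code{sd},
#'   \code{ci95}, \code{observed}, \code{z}.
#' @export
null_disparity <- function(richness, d, n_iter = 10000, seed = NULL,
                           observed = NULL) {
  pool <- nrow(d)
  if (is.null(pool) || pool < 2L) stop("disparity matrix too small")
  if (richness < 2L) stop("richness must be at least 2")
  if (richness > pool)
    stop(sprintf("richness %d exceeds pool size %d", richness, pool))
  if (n_iter < 1L) stop("n_iter must be positive")
  if (!is.null(seed)) set.seed(seed)
  denom <- richness * (richness - 1)
  if (richness == pool) {
    warning("richness equals pool size: degenerate null (sd = 0, z = 0)")
    m <- sum(d) / denom
    means <- rep(m, n_iter)
  } else {
    means <- vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(pool, richness)
      sum(d[idx, idx]) / denom
    }, numeric(1))
  }
  summarise_null(means, n_iter, observed)
}

summarise_null <- function(means, n_iter, observed = NULL) {
  gm <- mean(means)
  s <- stats::sd(means)
  z <- NULL
  if (!is.null(observed)) {
    z <- if (s == 0) {
      if (abs(observed - gm) > 1e-12)
        warning("null distribution is degenerate; z reported as 0")
      0
    } else (observed - gm) / s
  }
  structure(list(n_iter = n_iter, null_means = means, grand_mean = gm,
                 sd = s,
                 ci95 = stats::quantile(means, c(0.025, 0.975), names = FALSE),
                 observed = observed, z = z),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary: %d iterations, grand mean %.4f, sd %.4f, 95%% CI [%.4f, %.4f]%s>\n",
              x$n_iter, x$grand_mean, x$sd, x$ci95[1], x$ci95[2],
              if (!is.null(x$z)) sprintf(", observed %.4f, z = %.3f",
                                         x$observed, x$z) else ""))
  invisible(x)
}

#' Restrict communities to one visitor guild
#'
#' Intersects each community's membership with the set of species recorded
#' as visited by the chosen guild (bees or flies). Species missing from
#' the visitation table count as not visited. Communities left with fewer
#' than \code{min_members} guild species are dropped (with a message), the
#' generalisation of excluding communities too small for a meaningful
#' within-guild disparity.
#'
#' @param communities data.frame with columns \code{seep_id},
#'   \code{species}.
#' @param visitation data.frame with columns \code{species},
#'   \code{bee_visited}, \code{fly_visited} (logical or 0/1).
#' @param guild \code{"bee"} or \code{"fly"}.
#' @param min_members minimum guild members per retained community
#'   (default 3).
#' @return filtered community data.frame (same columns).
#' @export
guild_restrict <- function(communities, visitation, guild = c("bee", "fly"),
                           min_members = 3) {
  guild <- match.arg(guild)
  col <- paste0(guild, "_visited")
  if (!col %in% names(visitation))
    stop(sprintf("visitation table lacks column '%s'", col))
  visited <- visitation$species[as.logical(visitation[[col]])]
  keep <- communities[communities$species %in% visited, , drop = FALSE]
  sizes <- table(keep$seep_id)
  small <- names(sizes)[sizes < min_members]
  lost <- setdiff(unique(communities$seep_id), unique(keep$seep_id))
  drop <- union(small, lost)
  if (length(drop))
    message(sprintf("guild_restrict(%s): dropped %d communit%s with < %d %s-visited species: %s",
                    guild, length(drop), if (length(drop) == 1) "y" else "ies",
                    min_members, guild, paste(sort(drop), collapse = ", ")))
  keep[!keep$seep_id %in% small, , drop = FALSE]
}

#' Per-community dispersion table against a richness-matched null
#'
#' Convenience wrapper running [mean_pairwise_disparity()] and
#' [null_disparity()] for every community in a membership table. Per-seep
#' random substreams are derived deterministically from the master seed so
#' results do not depend on analysis order.
#'
#' @inheritParams guild_restrict
#' @param d disparity matrix over the sampling pool.
#' @param n_iter null iterations per community.
#' @param seed master integer seed.
#' @return data.frame with one row per community: \code{seep_id},
#'   \code{richness}, \code{observed_mean}, \code{null_grand_mean},
#'   \code{null_sd}, \code{ci_lo}, \code{ci_hi}, \code{z}.
#' @export
community_dispersion <- function(communities, d, n_iter = 10000, seed = NULL) {
  seeps <- sort(unique(communities$seep_id))
  rows <- lapply(seq_along(seeps), function(i) {
    members <- communities$species[communities$seep_id == seeps[i]]
    members <- unique(members)
    obs <- mean_pairwise_disparity(members, d)
    ns <- null_disparity(length(members), d, n_iter = n_iter,
                         seed = substream_seed(seed, i), observed = obs)
    data.frame(seep_id = seeps[i], richness = length(members),
               observed_mean = obs, null_grand_mean = ns$grand_mean,
               null_sd = ns$sd, ci_lo = ns$ci95[1], ci_hi = ns$ci95[2],
               z = ns$z)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deterministic per-unit substream seeds below 2^31
substream_seed <- function(master, i, stream = 0L) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) + 104729 * stream + 7919 * i) %% 2147483629)
}
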