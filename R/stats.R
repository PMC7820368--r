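#' ANCOVA of community mean disparity on type and habitat index
#'
#' Fits \code{mean_disparity ~ community_type * seep_index} where
#' community_type distinguishes each seep's observed community from its
#' richness-matched null expectation. A significant type effect indicates
#' over- or underdispersion overall; a significant type-by-index
#' interaction indicates that the degree of dispersion changes along the
#' habitat gradient. Reported are the overall model F (on 3 and 2k-4 df
#' for k seeps), partial (Type-III-style, sum-to-zero contrasts) tests per
#' term, adjusted means per type at the mean index with 95% CIs, and
#' within-type slopes with t tests on the residual df.
#'
#' @param tbl data.frame with columns \code{seep_id},
#'   \code{community_type} (\code{"observed"}/\code{"null"}),
#'   \code{mean_disparity}, \code{seep_index}; one observed and one null
#'   row per seep.
#' @return object of class \code{"dispersion_ancova"}: list with
#'   \code{model} (the lm fit), \code{overall} (F, df, p),
#'   \code{terms} (partial tests), \code{adjusted_means},
#'   \code{slopes}, and \code{residuals_by_seep} (per-seep mean of
#'   internally studentized residuals, for spatial diagnostics).
#' @export
dispersion_ancova <- function(tbl) {
  need <- c("seep_id", "community_type", "mean_disparity", "seep_index")
  if (!all(need %in% names(tbl)))
    stop("table must have columns seep_id, community_type, mean_disparity, seep_index")
  tbl$community_type <- factor(tbl$community_type,
                               levels = c("observed", "null"))
  if (any(is.na(tbl$community_type)) || nlevels(droplevels(tbl$community_type)) < 2L)
    stop("both community types ('observed', 'null') must be present")
  if (length(unique(tbl$seep_id)) < 3L) stop("at least 3 seeps required")
  if (stats::sd(tbl$seep_index) == 0)
    stop("singular design: seep_index is constant")
  fit <- stats::lm(mean_disparity ~ community_type * seep_index, data = tbl,
                   contrasts = list(community_type = "contr.sum"))
  fs <- summary(fit)$fstatistic
  overall <- list(F = unname(fs[1L]), df1 = unname(fs[2L]),
                  df2 = unname(fs[3L]),
                  p = unname(stats::pf(fs[1L], fs[2L], fs[3L],
                                       lower.tail = FALSE)))
  a3 <- tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
  if (is.null(a3)) {
    # zero residual variance (noise-free interpolation): partial tests
    # are undefined, estimates below remain exact
    terms <- data.frame(term = c("community_type", "seep_index",
                                 "community_type:seep_index"),
                        df = 1L, F = NA_real_, p = NA_real_)
  } else {
    terms <- data.frame(term = rownames(a3), df = a3$Df, F = a3$`F value`,
                        p = a3$`Pr(>F)`)
    terms <- terms[!terms$term %in% c("(Intercept)", "Residuals"), ,
                   drop = FALSE]
    rownames(terms) <- NULL
  }
  # adjusted means at the covariate mean are the intended summary here,
  # so emmeans' interaction caveat is expected and silenced
  emm <- suppressMessages(summary(emmeans::emmeans(fit, "community_type"),
                                  level = 0.95))
  adjusted <- data.frame(community_type = as.character(emm$community_type),
                         mean = emm$emmean, se = emm$SE,
                         ci_lo = emm$lower.CL, ci_hi = emm$upper.CL)
  trends <- emmeans::emtrends(fit, "community_type", var = "seep_index")
  tr <- summary(trends, infer = c(FALSE, TRUE))
  slopes <- data.frame(community_type = as.character(tr$community_type),
                       slope = tr$seep_index.trend, se = tr$SE,
                       t = tr$t.ratio, p = tr$p.value)
  sdiff <- summary(emmeans::contrast(trends, "pairwise"),
                   infer = c(FALSE, TRUE))
  rs <- stats::rstandard(fit)
  res_by_seep <- tapply(rs, tbl$seep_id, mean)
  structure(list(model = fit, overall = overall, terms = terms,
                 adjusted_means = adjusted, slopes = slopes,
                 slope_difference = data.frame(estimate = sdiff$estimate,
                                               se = sdiff$SE,
                                               t = sdiff$t.ratio,
                                               p = sdiff$p.value),
                 residuals_by_seep = res_by_seep),
            class = "dispersion_ancova")
}

#' @export
print.dispersion_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA: mean disparity ~ community type * seep index\n"))
  cat(sprintf("  overall model: F(%d, %d) = %.2f, p = %.4g\n",
              x$overall$df1, x$overall$df2, x$overall$F, x$overall$p))
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %-28s F(%d) = %.2f, p = %.4g\n", x$terms$term[i],
                x$terms$df[i], x$terms$F[i], x$terms$p[i]))
  cat("  adjusted means (covariate at mean):\n")
  for (i in seq_len(nrow(x$adjusted_means)))
    cat(sprintf("    %-9s %.3f  95%% CI [%.3f, %.3f]\n",
                x$adjusted_means$community_type[i], x$adjusted_means$mean[i],
                x$adjusted_means$ci_lo[i], x$adjusted_means$ci_hi[i]))
  cat("  within-type slopes:\n")
  for (i in seq_len(nrow(x$slopes)))
    cat(sprintf("    %-9s %+.4f (t = %.2f, p = %.4g)\n",
                x$slopes$community_type[i], x$slopes$slope[i],
                x$slopes$t[i], x$slopes$p[i]))
  invisible(x)
}

#' Moran's I spatial autocorrelation with inverse-distance weights
#'
#' Computes Moran's I for one value per location with weights
#' \eqn{w_{ij} = 1 / d_{ij}} (zero diagonal, not row-standardised), its
#' analytic expectation \eqn{-1/(n-1)}, and a two-sided p value from the
#' normal approximation; a permutation p value is available as an
#' alternative. Used to screen regression residuals for residual spatial
#' structure among seeps.
#'
#' @param x numeric vector of values (e.g., per-seep residuals), length
#'   >= 4.
#' @param coords two-column matrix or data.frame of coordinates.
#' @param method \code{"normal"} (default) or \code{"permutation"}.
#' @param nperm permutations when \code{method = "permutation"}.
#' @param seed optional seed for the permutation draw.
#' @return list with \code{I}, \code{expected}, \code{sd}, \code{p},
#'   \code{method}.
#' @export
morans_i <- function(x, coords, method = c("normal", "permutation"),
                     nperm = 999, seed = NULL) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- length(x)
  if (n < 4L) stop("at least 4 locations required")
  if (nrow(coords) != n) stop("coords must have one row per value")
  dd <- as.matrix(stats::dist(coords))
  off <- dd[upper.tri(dd)]
  if (any(off == 0)) stop("coincident points (zero pairwise distance)")
  w <- 1 / dd
  diag(w) <- 0
  mi <- ape::Moran.I(x, w, alternative = "two.sided")
  p <- mi$p.value
  if (method == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    obs <- mi$observed
    perm <- vapply(seq_len(nperm), function(i)
      ape::Moran.I(sample(x), w)$observed, numeric(1))
    p <- (1 + sum(abs(perm - mi$expected) >= abs(obs - mi$expected))) /
      (nperm + 1)
  }
  list(I = mi$observed, expected = mi$expected, sd = mi$sd, p = p,
       method = method)
}
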