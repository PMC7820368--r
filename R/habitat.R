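#' Summarise transect survey records for one seep
#'
#' Point-intercept summary: at every 0.25 m mark along the center and edge
#' transects the record states whether the tape was over bare ground or in
#' contact with a plant (identified to species). Species richness is the
#' number of distinct species contacted; plant density is the fraction of
#' points in contact with a plant.
#'
#' @param records data.frame for one seep with columns \code{transect}
#'   (\code{"center"}/\code{"edge"}), \code{position_m}, \code{contact}
#'   (\code{"bare"}/\code{"plant"}), \code{species} (name when
#'   \code{contact == "plant"}, otherwise empty/NA).
#' @return list with \code{richness} (integer) and \code{density}
#'   (fraction in \[0, 1\]).
#' @export
transect_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty transect record set")
  if (!all(c("contact", "species") %in% names(records)))
    stop("records need columns 'contact' and 'species'")
  plant <- records$contact == "plant"
  sp <- records$species[plant]
  sp <- sp[!is.na(sp) & sp != ""]
  if (sum(plant) != length(sp))
    stop("species must be recorded exactly for plant contacts")
  list(richness = length(unique(sp)), density = mean(plant))
}

#' Seep area from length and repeated width measurements
#'
#' Seep area is approximated as transect length times the arithmetic mean
#' of the width measurements taken at several points along the length.
#'
#' @param length_m seep length in metres (> 0).
#' @param widths_m numeric vector of width measurements in metres (> 0).
#' @return area in square metres.
#' @export
seep_area <- function(length_m, widths_m) {
  if (!is.numeric(length_m) || length(length_m) != 1L || length_m <= 0)
    stop("length must be a single positive number")
  if (!length(widths_m) || any(widths_m <= 0))
    stop("widths must be positive")
  length_m * mean(widths_m)
}

#' Composite habitat index from seep metrics (PC1)
#'
#' Seep area, plant density and species richness tend to be strongly
#' positively correlated across seeps, so they are consolidated into one
#' "seep index": the first principal component of the correlation matrix
#' (variables standardised, since their units are incommensurate). The
#' component is oriented so that richness loads positively — high index
#' means a larger, denser, more species-rich seep.
#'
#' @param metrics data.frame with one row per seep and columns
#'   \code{seep_id}, \code{area}, \code{density}, \code{richness}.
#' @return list with \code{scores} (named PC1 score per seep),
#'   \code{loadings} (PC1 loadings), \code{variance_explained} (fraction
#'   of total variance on PC1), and \code{correlations} (pairwise
#'   correlation matrix of the three inputs).
#' @export
seep_index <- function(metrics) {
  need <- c("seep_id", "area", "density", "richness")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns seep_id, area, density, richness")
  if (nrow(metrics) < 3L) stop("at least 3 seeps required for the PCA")
  vars <- metrics[, c("area", "density", "richness")]
  const <- vapply(vars, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    stop(sprintf("constant variable(s): %s",
                 paste(names(vars)[const], collapse = ", ")))
  p <- stats::prcomp(vars, center = TRUE, scale. = TRUE)
  load1 <- p$rotation[, 1L]
  scores <- p$x[, 1L]
  if (load1[["richness"]] < 0) {   # orient PC1 so richness loads positively
    load1 <- -load1
    scores <- -scores
  }
  names(scores) <- metrics$seep_id
  list(scores = scores, loadings = load1,
       variance_explained = p$sdev[1L]^2 / sum(p$sdev^2),
       correlations = stats::cor(vars))
}

#' Seep metrics table from survey files
#'
#' Combines per-seep transect summaries with measured seep dimensions and
#' coordinates into the metrics table consumed by [seep_index()] and the
#' spatial diagnostics.
#'
#' @param transects data.frame with columns \code{seep_id},
#'   \code{transect}, \code{position_m}, \code{contact}, \code{species}.
#' @param dims data.frame with columns \code{seep_id}, \code{length_m},
#'   width columns \code{width1}..\code{width5} (any number >= 1), and
#'   coordinates \code{x}, \code{y}.
#' @return data.frame with columns \code{seep_id}, \code{area},
#'   \code{density}, \code{richness}, \code{x}, \code{y}.
#' @export
seep_metrics <- function(transects, dims) {
  wcols <- grep("^width", names(dims), value = TRUE)
  if (!length(wcols)) stop("dims must contain width columns (width1, ...)")
  rows <- lapply(seq_len(nrow(dims)), function(i) {
    id <- dims$seep_id[i]
    ts <- transect_summary(transects[transects$seep_id == id, , drop = FALSE])
    data.frame(seep_id = id,
               area = seep_area(dims$length_m[i], as.numeric(dims[i, wcols])),
               density = ts$density, richness = ts$richness,
               x = dims$x[i], y = dims$y[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
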