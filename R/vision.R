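#' Define a receptor-noise-limited visual system
#'
#' Bundles the photoreceptor spectral sensitivities, the Weber fraction of
#' the reference receptor channel, and the relative receptor abundances
#' that together determine chromatic discrimination under the
#' receptor-noise-limited (RNL) model. The honeybee is the canonical
#' trichromat (UV, B, G receptors, Weber fraction 0.05, abundances
#' 2.125:1:9.375 anchored on G); hoverflies are modeled as tetrachromats
#' (R7p, R7y, R8p, R8y; abundances 1:2.33:1:2.33, Weber 0.05 anchored on
#' the most abundant class).
#'
#' @param sensitivities named list of sensitivity [spectrum()] objects, one
#'   per receptor, in receptor order, all on one wavelength grid.
#' @param weber Weber fraction of the reference receptor (unitless).
#' @param abundances named positive numeric vector of relative receptor
#'   abundances, names matching \code{sensitivities}.
#' @param reference name of the receptor whose channel noise the Weber
#'   fraction describes; defaults to the most abundant receptor.
#' @return an object of class \code{"visual_system"}.
#' @export
visual_system <- function(sensitivities, weber, abundances, reference = NULL) {
  nm <- names(sensitivities)
  if (is.null(nm) || any(nm == ""))
    stop("sensitivities must be a named list")
  n <- length(nm)
  if (n < 2L)
    stop("at least two receptor classes required")
  if (!all(vapply(sensitivities, is_spectrum, logical(1))))
    stop("sensitivities must be spectrum objects")
  wl <- sensitivities[[1L]]$wl
  for (s in sensitivities) {
    if (length(s$wl) != length(wl) || any(s$wl != wl))
      stop("receptor sensitivities on mismatched grids")
    if (any(s$value < 0)) stop("negative sensitivity values")
  }
  if (!is.numeric(weber) || length(weber) != 1L || weber <= 0)
    stop("weber must be a single positive number")
  if (is.null(names(abundances))) names(abundances) <- nm
  if (!setequal(names(abundances), nm))
    stop("abundance names do not match receptor names")
  abundances <- abundances[nm]
  if (any(abundances <= 0)) stop("nonpositive abundances")
  if (is.null(reference)) reference <- nm[which.max(abundances)]
  if (!reference %in% nm)
    stop(sprintf("reference receptor '%s' not among receptors", reference))
  structure(list(receptors = nm, sensitivities = sensitivities,
                 weber = weber, abundances = abundances,
                 reference = reference, wl = wl),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system: %d receptors (%s), Weber %.3g on %s>\n",
              length(x$receptors), paste(x$receptors, collapse = ","),
              x$weber, x$reference))
  invisible(x)
}

#' Receptor channel noise from Weber fraction and abundances
#'
#' The noise standard deviation of receptor channel i is
#' \eqn{\omega_i = W \sqrt{\eta_{ref} / \eta_i}}, so that the reference
#' channel has \eqn{\omega_{ref} = W}: rarer receptor classes are noisier
#' in inverse proportion to the square root of their relative abundance.
#'
#' @param vs a [visual_system()].
#' @return named numeric vector of per-receptor noise values.
#' @export
receptor_noise <- function(vs) {
  stopifnot(inherits(vs, "visual_system"))
  eta <- vs$abundances
  vs$weber * sqrt(eta[[vs$reference]] / eta)
}

#' Quantum catches and adapted receptor signals
#'
#' For each receptor i, the quantum catch is the Riemann sum
#' \eqn{Q_i = \sum_\lambda S_i(\lambda) R(\lambda) D(\lambda) \Delta\lambda}
#' over the analysis grid, with R the stimulus reflectance and D the
#' illuminant. von Kries adaptation divides each catch by the catch of the
#' adapting background, \eqn{q_i = Q_i / Q_i^{bkg}}, which makes the
#' signals invariant to uniform scaling of the illuminant; the transduced
#' signal is \eqn{f_i = \ln q_i}.
#'
#' @param reflectance stimulus reflectance [spectrum()] on the grid.
#' @param background adapting background reflectance [spectrum()].
#' @param irradiance illuminant [spectrum()] (photon flux).
#' @param vs a [visual_system()] on the same grid.
#' @return list with named vectors \code{Q} (raw catches), \code{q}
#'   (adapted catches) and \code{f} (log signals).
#' @export
receptor_signals <- function(reflectance, background, irradiance, vs) {
  stopifnot(inherits(vs, "visual_system"))
  wl <- vs$wl
  for (s in list(reflectance, background, irradiance)) {
    if (!is_spectrum(s)) stop("spectra must be spectrum objects")
    if (length(s$wl) != length(wl) || any(s$wl != wl))
      stop("spectra must share the visual system's wavelength grid")
  }
  dl <- wl[2L] - wl[1L]
  catch <- function(refl) {
    vapply(vs$sensitivities,
           function(s) sum(s$value * refl$value * irradiance$value) * dl,
           numeric(1))
  }
  Q <- catch(reflectance)
  Qb <- catch(background)
  if (any(Qb <= 0))
    stop(sprintf("zero background quantum catch in receptor(s): %s",
                 paste(vs$receptors[Qb <= 0], collapse = ", ")))
  if (any(Q <= 0))
    stop(sprintf("zero stimulus quantum catch in receptor(s): %s",
                 paste(vs$receptors[Q <= 0], collapse = ", ")))
  q <- Q / Qb
  list(Q = Q, q = q, f = log(q))
}

#' Chromatic distance between two stimuli (RNL model)
#'
#' The pairwise chromatic distance \eqn{\Delta S} between two stimuli with
#' log receptor signals fA and fB, in units of standard deviations of
#' receptor noise. Closed forms are used for di-, tri- and tetrachromatic
#' systems; for higher receptor counts the equivalent noise-scaled
#' projection form is used (signals scaled by 1/omega, achromatic
#' direction projected out, Euclidean norm taken).
#'
#' @param fA,fB numeric vectors of log receptor signals, equal length.
#' @param omega numeric vector of receptor noise values, same length.
#' @return the non-negative chromatic distance, in noise SD units.
#' @export
delta_s <- function(fA, fB, omega) {
  n <- length(omega)
  if (length(fA) != n || length(fB) != n)
    stop("fA, fB and omega must have the same length")
  if (n < 2L) stop("at least two receptor channels required")
  df <- as.numeric(fA) - as.numeric(fB)
  w2 <- omega^2
  ds2 <- switch(as.character(n),
    "2" = (df[1L] - df[2L])^2 / (w2[1L] + w2[2L]),
    "3" = (w2[1L] * (df[3L] - df[2L])^2 +
           w2[2L] * (df[3L] - df[1L])^2 +
           w2[3L] * (df[1L] - df[2L])^2) /
          (w2[1L] * w2[2L] + w2[1L] * w2[3L] + w2[2L] * w2[3L]),
    "4" = {
      num <- w2[1L] * w2[2L] * (df[4L] - df[3L])^2 +
             w2[1L] * w2[3L] * (df[4L] - df[2L])^2 +
             w2[1L] * w2[4L] * (df[3L] - df[2L])^2 +
             w2[2L] * w2[3L] * (df[4L] - df[1L])^2 +
             w2[2L] * w2[4L] * (df[3L] - df[1L])^2 +
             w2[3L] * w2[4L] * (df[2L] - df[1L])^2
      den <- w2[1L] * w2[2L] * w2[3L] + w2[1L] * w2[2L] * w2[4L] +
             w2[1L] * w2[3L] * w2[4L] + w2[2L] * w2[3L] * w2[4L]
      num / den
    },
    {
      # general n: project the noise-scaled signal difference off the
      # achromatic direction (1/omega_1, ..., 1/omega_n)
      x <- df / omega
      u <- 1 / omega
      max(0, sum(x^2) - sum(x * u)^2 / sum(u^2))
    })
  sqrt(ds2)
}

#' Pairwise chromatic distance matrix over a species pool
#'
#' Runs every species' composite reflectance through [receptor_signals()]
#' and fills the symmetric matrix of pairwise [delta_s()] values: the
#' color-disparity matrix used by the community null models.
#'
#' @param spectra named list of reflectance [spectrum()] objects (one per
#'   species) on the visual system's grid.
#' @inheritParams receptor_signals
#' @return symmetric numeric matrix with species dimnames, zero diagonal.
#' @export
color_distance_matrix <- function(spectra, background, irradiance, vs) {
  sp <- names(spectra)
  if (is.null(sp)) stop("spectra must be a named list")
  omega <- receptor_noise(vs)
  f <- vapply(spectra, function(s)
    receptor_signals(s, background, irradiance, vs)$f,
    numeric(length(vs$receptors)))
  n <- length(sp)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- delta_s(f[, i], f[, j], omega)
    }
  }
  d
}

#' Chromaticity coordinates in the color simplex
#'
#' Maps adapted quantum catches to relative stimulation values
#' \eqn{e_i = q_i / \sum_j q_j} and then to coordinates in the standard
#' chromaticity diagram: a segment for dichromats, the Maxwell triangle
#' for trichromats, and a regular tetrahedron for tetrachromats.
#'
#' @param q positive numeric vector of adapted catches (2-4 receptors).
#' @return list with \code{relative} (the barycentric weights, summing to
#'   one) and \code{coords} (Cartesian coordinates in the simplex).
#' @export
chromaticity <- function(q) {
  n <- length(q)
  if (n < 2L || n > 4L) stop("2-4 receptor catches supported")
  if (any(!is.finite(q)) || any(q <= 0)) stop("nonpositive quantum catch")
  e <- q / sum(q)
  vertices <- switch(as.character(n),
    "2" = matrix(c(-0.5, 0.5), ncol = 1),
    "3" = rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
    "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / 2)
  coords <- drop(crossprod(vertices, e))
  list(relative = e, coords = coords)
}
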