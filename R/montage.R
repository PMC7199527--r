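# Idealized extended 10-20 montage on a unit sphere.
#
# Positions are constructed geometrically: midline electrodes sit on the
# anterior-posterior great circle at multiples of 22.5 degrees from the vertex,
# the outer (10%) ring at 90 degrees polar angle, and intermediate electrodes
# on great-circle arcs (slerp) between their row's midline anchor and its
# outer-ring electrode. This reproduces the topology of a BioSemi 64-channel
# cap (neighbourhood structure, left/right symmetry, frontal vs occipital
# separation) without copying any vendor coordinate file; the pipeline uses
# positions only for nearest-neighbour interpolation and parametric
# topographies, never for source modelling.

sph_point <- function(polar_deg, azim_deg) {
  th <- polar_deg * pi / 180; ph <- azim_deg * pi / 180
  c(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}

slerp <- function(u, v, f) {
  w <- acos(max(-1, min(1, sum(u * v))))
  if (w < 1e-12) return(u)
  (sin((1 - f) * w) * u + sin(f * w) * v) / sin(w)
}

# Azimuth convention: 0 = anterior midline, positive toward the right ear,
# +/-180 = posterior midline. Polar angle measured from the vertex (Cz).
biosemi64_coords <- function() {
  midline <- list(
    Fpz = c(90, 0), AFz = c(67.5, 0), Fz = c(45, 0), FCz = c(22.5, 0),
    Cz = c(0, 0), CPz = c(22.5, 180), Pz = c(45, 180), POz = c(67.5, 180),
    Oz = c(90, 180), Iz = c(112.5, 180))
  # rows: midline anchor label, outer-ring azimuth (left, negative),
  # member labels from inner to outer with arc fractions.
  rows <- list(
    list(anchor = "Fpz",  ring_az = -18,  members = c(Fp1 = 1)),
    list(anchor = "AFz",  ring_az = -36,  members = c(AF3 = 0.5, AF7 = 1)),
    list(anchor = "Fz",   ring_az = -54,
         members = c(F1 = 0.25, F3 = 0.5, F5 = 0.75, F7 = 1)),
    list(anchor = "FCz",  ring_az = -72,
         members = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75, FT7 = 1)),
    list(anchor = "Cz",   ring_az = -90,
         members = c(C1 = 0.25, C3 = 0.5, C5 = 0.75, T7 = 1)),
    list(anchor = "CPz",  ring_az = -108,
         members = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75, TP7 = 1)),
    list(anchor = "Pz",   ring_az = -126,
         members = c(P1 = 0.25, P3 = 0.5, P5 = 0.75, P7 = 1)),
    list(anchor = "POz",  ring_az = -144, members = c(PO3 = 0.5, PO7 = 1)),
    list(anchor = "Oz",   ring_az = -162, members = c(O1 = 1)))
  pos <- list()
  for (lab in names(midline)) pos[[lab]] <- sph_point(midline[[lab]][1], midline[[lab]][2])
  mirror <- function(lab) {
    # odd -> even electrode numbering across the midline
    num <- as.integer(gsub("[^0-9]", "", lab))
    sub("[0-9]+$", num + 1, lab)
  }
  for (row in rows) {
    u <- pos[[row$anchor]]
    ring <- sph_point(90, row$ring_az)
    for (lab in names(row$members)) {
      p <- slerp(u, ring, row$members[[lab]])
      pos[[lab]] <- p
      pos[[mirror(lab)]] <- c(p[1], -p[2], p[3])
    }
  }
  # Inferior posterior pair flanking Iz, below the 10% ring.
  pos[["P9"]] <- sph_point(112.5, -126)
  pos[["P10"]] <- sph_point(112.5, 126)
  pos
}

#' Construct an extended 10-20 EEG montage
#'
#' Returns a 64-channel BioSemi-style montage with unit-sphere electrode
#' positions, or a named subset of it. All electrodes used by the default
#' regions of interest (`Iz, Oz, POz`, `O1, PO7, P7, P9`, `O2, PO8, P8, P10`)
#' are included.
#'
#' @param channels Optional character vector restricting the montage to a
#'   subset of channels (order preserved as given). Useful for fast
#'   simulations that only need the ROI and frontal electrodes.
#' @return An object of class `ft_montage`: a data.frame with columns `label`,
#'   `x`, `y`, `z` (unit-sphere coordinates).
#' @examples
#' m <- biosemi_montage()
#' nrow(m)  # 64
#' @export
biosemi_montage <- function(channels = NULL) {
  pos <- biosemi64_coords()
  labs <- names(pos)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labs)
    if (length(missing))
      ft_stop("unknown channel label(s): %s", "ft_montage_error",
              paste(missing, collapse = ", "))
    labs <- channels
  }
  m <- do.call(rbind, lapply(pos[labs], function(p) as.data.frame(t(p))))
  m <- data.frame(label = labs, m, row.names = NULL, stringsAsFactors = FALSE)
  # normalize (defensive; slerp keeps unit norm)
  nrm <- sqrt(m$x^2 + m$y^2 + m$z^2)
  m$x <- m$x / nrm; m$y <- m$y / nrm; m$z <- m$z / nrm
  structure(m, class = c("ft_montage", "data.frame"))
}

montage_positions <- function(montage, labels = montage$label) {
  i <- match(labels, montage$label)
  if (anyNA(i))
    ft_stop("channel(s) not in montage: %s", "ft_montage_error",
            paste(labels[is.na(i)], collapse = ", "))
  as.matrix(montage[i, c("x", "y", "z")])
}

# Great-circle (angular) distance between a channel and a reference point.
angular_dist <- function(P, q) {
  d <- P %*% q
  acos(pmax(-1, pmin(1, d)))
}

#' Default regions of interest for face/house frequency tagging
#'
#' Medial occipital (MO), left and right occipito-temporal (LOT, ROT)
#' electrode sets over which responses are averaged.
#'
#' @return Named list of character vectors of electrode labels.
#' @export
roi_definitions <- function() {
  list(MO = c("Iz", "Oz", "POz"),
       LOT = c("O1", "PO7", "P7", "P9"),
       ROT = c("O2", "PO8", "P8", "P10"))
}
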