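#' Niche height in cell diameters
#'
#' The 95th percentile of the wall-arc coordinate over stem cells, divided
#' by the cell diameter (a robust estimate of the stem-compartment
#' boundary along the wall, insensitive to single outlier cells during
#' division); zero when no stem cells exist. Measured along the wall arc,
#' the default-threshold compartment spans roughly four cell diameters.
#'
#' @param state a \code{crypt_state} (or supply \code{arcs} and
#'   \code{types} directly).
#' @param arcs optional per-cell wall-arc coordinates, um.
#' @param types optional per-cell type codes.
#' @param cell_diameter cell diameter, um.
#' @return Niche height in cell diameters.
#' @export
niche_height <- function(state = NULL, arcs = NULL, types = NULL,
                         cell_diameter = 10) {
  if (!is.null(state)) {
    arcs <- wall_height(state$surface, .cell_centroids(state)$centroid)
    types <- state$cells$type
    cell_diameter <- state$config$cell_diameter
  }
  stem <- arcs[types == CELL_TYPES["STEM"]]
  if (!length(stem)) return(0)
  as.numeric(stats::quantile(stem, 0.95)) / cell_diameter
}

#' Cell-type composition
#'
#' Fractions of stem, Paneth, enterocyte and Goblet cells among live cells.
#'
#' @param cells a \code{crypt_state}, a cell table, or a vector of type
#'   codes/labels.
#' @return Named numeric vector summing to 1.
#' @export
composition <- function(cells) {
  types <- if (inherits(cells, "crypt_state")) cells$cells$type
  else if (is.data.frame(cells)) .type_code(cells$type)
  else .type_code(cells)
  if (!length(types)) stop("composition undefined for an empty crypt")
  counts <- tabulate(types, nbins = 4)
  stats::setNames(counts / sum(counts),
                  c("stem", "paneth", "enterocyte", "goblet"))
}

#' Stem and Paneth density along the wall arc
#'
#' Binned counts of stem and Paneth cells by wall-arc coordinate, in cell
#' diameters.
#'
#' @param state a \code{crypt_state}.
#' @param bin_cd bin width in cell diameters.
#' @return Data frame with \code{arc_cd} (bin midpoints), \code{n_stem},
#'   \code{n_paneth}.
#' @export
z_density <- function(state, bin_cd = 1) {
  cd <- state$config$cell_diameter
  arcs <- wall_height(state$surface, .cell_centroids(state)$centroid) / cd
  total <- total_arc(state$surface) / cd
  breaks <- seq(0, ceiling(total / bin_cd) * bin_cd, by = bin_cd)
  mids <- breaks[-1] - bin_cd / 2
  bin <- cut(arcs, breaks, include.lowest = TRUE, labels = FALSE)
  stem <- tabulate(bin[state$cells$type == CELL_TYPES["STEM"]],
                   nbins = length(mids))
  pan <- tabulate(bin[state$cells$type == CELL_TYPES["PANETH"]],
                  nbins = length(mids))
  data.frame(arc_cd = mids, n_stem = stem, n_paneth = pan)
}

#' Classify the stability of a niche-height trajectory
#'
#' "dies" when the final stem count is zero; "unstable" when the niche
#' height reaches the occupancy fraction of the total wall arc or its
#' trailing-window slope exceeds the threshold; "stable" otherwise. The
#' three labels are mutually exclusive and exhaustive, and the
#' classification is deterministic given the series.
#'
#' @param time_h recording times, hours (must span at least 2 simulated
#'   days).
#' @param height_cd niche heights, cell diameters.
#' @param stem_counts stem-cell counts.
#' @param total_arc_cd total wall arc in cell diameters.
#' @param slope_thresh trailing slope flagged unstable, cd/h.
#' @param occupancy fraction of the total arc flagged unstable.
#' @param window_h trailing window for the slope, hours.
#' @return One of "stable", "unstable", "dies".
#' @export
classify_stability <- function(time_h, height_cd, stem_counts, total_arc_cd,
                               slope_thresh = 0.1, occupancy = 0.9,
                               window_h = 24) {
  if (max(time_h) - min(time_h) < 48 - 1e-6)
    stop("stability classification needs at least 2 simulated days")
  if (stem_counts[length(stem_counts)] == 0) return("dies")
  if (max(height_cd) >= occupancy * total_arc_cd) return("unstable")
  recent <- time_h >= max(time_h) - window_h
  slope <- stats::coef(stats::lm(height_cd[recent] ~ time_h[recent]))[2]
  if (is.finite(slope) && slope > slope_thresh) return("unstable")
  "stable"
}
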