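#' 64-channel 10-10 sensor layout
#'
#' Returns the 64 electrode labels of the extended international 10-10
#' arrangement (the standard 64-channel montage: Fp1...Iz, including Oz
#' and Cz) with schematic 2-D head-projected coordinates. Rows run from
#' frontal-polar (y = +0.9) to inion (y = -1.05); lateral positions are
#' scaled by the head outline so temporal channels sit near the rim.
#' Coordinates are in head-radius units and are used for searchlight
#' neighborhoods and for the spatial correlation of simulated noise;
#' posterior channels are identifiable by the O/PO/P label prefixes.
#'
#' @return data frame with columns `name`, `x`, `y` (64 rows).
#' @examples
#' lay <- make_layout()
#' subset(lay, name %in% c("Oz", "Cz"))
#' @export
make_layout <- function() {
  rows <- list(
    list(y = 0.90, ch = c(`Fp1` = -0.35, `Fpz` = 0, `Fp2` = 0.35)),
    list(y = 0.72, ch = c(`AF7` = -0.70, `AF3` = -0.30, `AFz` = 0,
                          `AF4` = 0.30, `AF8` = 0.70)),
    list(y = 0.54, ch = c(`F7` = -1.00, `F5` = -0.75, `F3` = -0.50,
                          `F1` = -0.25, `Fz` = 0, `F2` = 0.25, `F4` = 0.50,
                          `F6` = 0.75, `F8` = 1.00)),
    list(y = 0.28, ch = c(`FT7` = -1.05, `FC5` = -0.78, `FC3` = -0.52,
                          `FC1` = -0.26, `FCz` = 0, `FC2` = 0.26,
                          `FC4` = 0.52, `FC6` = 0.78, `FT8` = 1.05)),
    list(y = 0.00, ch = c(`T7` = -1.08, `C5` = -0.81, `C3` = -0.54,
                          `C1` = -0.27, `Cz` = 0, `C2` = 0.27, `C4` = 0.54,
                          `C6` = 0.81, `T8` = 1.08)),
    list(y = -0.28, ch = c(`TP7` = -1.05, `CP5` = -0.78, `CP3` = -0.52,
                           `CP1` = -0.26, `CPz` = 0, `CP2` = 0.26,
                           `CP4` = 0.52, `CP6` = 0.78, `TP8` = 1.05)),
    list(y = -0.54, ch = c(`P9` = -1.20, `P7` = -1.00, `P5` = -0.75,
                           `P3` = -0.50, `P1` = -0.25, `Pz` = 0,
                           `P2` = 0.25, `P4` = 0.50, `P6` = 0.75,
                           `P8` = 1.00, `P10` = 1.20)),
    list(y = -0.72, ch = c(`PO7` = -0.70, `PO3` = -0.30, `POz` = 0,
                           `PO4` = 0.30, `PO8` = 0.70)),
    list(y = -0.90, ch = c(`O1` = -0.35, `Oz` = 0, `O2` = 0.35)),
    list(y = -1.05, ch = c(`Iz` = 0)))
  out <- do.call(rbind, lapply(rows, function(r) {
    w <- sqrt(pmax(1.45 - r$y^2, 0.15))
    data.frame(name = names(r$ch), x = unname(r$ch) * w, y = r$y)
  }))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 64L, !anyDuplicated(out$name))
  out
}

# pairwise Euclidean distances between layout positions
layout_dist <- function(layout) {
  as.matrix(stats::dist(cbind(layout$x, layout$y)))
}

#' Sensor searchlight neighborhoods
#'
#' For every channel, its `size`-sensor neighborhood: the channel itself
#' plus its `size - 1` nearest neighbors by Euclidean distance in the 2-D
#' layout, distance ties broken by alphabetical label order.
#'
#' @param layout a [make_layout()] data frame.
#' @param size neighborhood size (default 4).
#' @return named list of integer channel-index vectors.
#' @export
sensor_neighborhoods <- function(layout, size = 4L) {
  if (size > nrow(layout)) stop("neighborhood size exceeds channel count")
  D <- layout_dist(layout)
  nb <- lapply(seq_len(nrow(layout)), function(i) {
    ord <- order(D[i, ], layout$name)
    sort(ord[seq_len(size)])
  })
  names(nb) <- layout$name
  nb
}
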