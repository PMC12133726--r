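#' Standard 32-channel 10/20 montage
#'
#' Schematic 2-D scalp positions (nose up, unit head radius) for the
#' 32-channel international 10/20 layout used throughout the package.
#' Coordinates are the conventional flattened projection used for
#' topographic maps, not digitised electrode positions.
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' montage_1020()
#' @export
montage_1020 <- function() {
  tibble::tribble(
    ~channel, ~x, ~y,
    "FP1", -0.31,  0.95,
    "FP2",  0.31,  0.95,
    "F7",  -0.81,  0.59,
    "F3",  -0.40,  0.60,
    "Fz",   0.00,  0.60,
    "F4",   0.40,  0.60,
    "F8",   0.81,  0.59,
    "FT7", -0.85,  0.31,
    "FC3", -0.40,  0.30,
    "FCz",  0.00,  0.30,
    "FC4",  0.40,  0.30,
    "FT8",  0.85,  0.31,
    "T7",  -1.00,  0.00,
    "C3",  -0.40,  0.00,
    "Cz",   0.00,  0.00,
    "C4",   0.40,  0.00,
    "T8",   1.00,  0.00,
    "TP7", -0.85, -0.31,
    "CP3", -0.40, -0.30,
    "CPz",  0.00, -0.30,
    "CP4",  0.40, -0.30,
    "TP8",  0.85, -0.31,
    "P7",  -0.81, -0.59,
    "P3",  -0.40, -0.60,
    "Pz",   0.00, -0.60,
    "P4",   0.40, -0.60,
    "P8",   0.81, -0.59,
    "PO3", -0.31, -0.80,
    "POz",  0.00, -0.82,
    "PO4",  0.31, -0.80,
    "O1",  -0.31, -0.95,
    "O2",   0.31, -0.95
  )
}

#' Electrode adjacency from 2-D montage positions
#'
#' Builds the neighbourhood graph used by [cluster_perm_channels()]:
#' two electrodes are adjacent when their flattened scalp distance is at
#' most `threshold`. With the default montage and threshold this links
#' each electrode to its immediate grid neighbours (mean degree about 4)
#' and yields a single connected component.
#'
#' @param montage A tibble with `channel`, `x`, `y` (default
#'   [montage_1020()]).
#' @param threshold Maximum scalp distance (same units as the montage
#'   coordinates) for two electrodes to count as neighbours.
#' @return A tibble edge list with columns `from` and `to`
#'   (each undirected pair appears once), with the montage stored in the
#'   `"montage"` attribute.
#' @export
electrode_adjacency <- function(montage = montage_1020(), threshold = 0.46) {
  stopifnot(all(c("channel", "x", "y") %in% names(montage)), threshold > 0)
  if (anyDuplicated(montage$channel))
    stop("duplicate channel labels in montage")
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  idx <- which(d <= threshold & upper.tri(d), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = montage$channel[idx[, 1]],
    to = montage$channel[idx[, 2]]
  )
  attr(edges, "montage") <- montage
  edges
}

# igraph object over all montage electrodes (isolated nodes kept)
.adjacency_graph <- function(edges, channels) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = channels))
  g
}
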