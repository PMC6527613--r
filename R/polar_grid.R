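#' Polar-map sampling grid
#'
#' The left-ventricular polar map is sampled on 460 nodes arranged as 20
#' concentric rings of 23 angular sectors each. Ring 0 is the apex, ring 19
#' the base; sector 0 starts at the anterior wall (angle 0) and sectors
#' proceed counterclockwise as viewed from the apex. Every node carries an
#' AHA 17-segment assignment and, through it, a coronary vessel territory
#' (LAD, RCA or LCX).
#'
#' Segments follow the AHA convention: basal 1-6 (rings 15-19), mid 7-12
#' (rings 10-14), apical 13-16 (rings 5-9), apical cap 17 (rings 0-4).
#' Within a band a node belongs to the segment whose angular span contains
#' the node's angular center (six 60-degree spans for basal/mid bands, four
#' 90-degree spans for the apical band; spans are centered on the anterior
#' wall).
#'
#' @return An object of class `polar_grid`: a list with elements `n_rings`,
#'   `n_sectors`, `n_nodes`, and per-node integer vectors `ring`, `sector`
#'   (0-based), `segment` (1-17) and factor `territory` (LAD/RCA/LCX).
#' @examples
#' g <- polar_grid()
#' table(g$segment)
#' @export
polar_grid <- function() {
  n_rings <- 20L
  n_sectors <- 23L
  ring <- rep(0:(n_rings - 1L), each = n_sectors)
  sector <- rep(0:(n_sectors - 1L), times = n_rings)
  segment <- assign_segments(ring, sector, n_sectors)
  terr <- territory_of_segment(segment)
  structure(
    list(
      n_rings = n_rings, n_sectors = n_sectors,
      n_nodes = n_rings * n_sectors,
      ring = ring, sector = sector,
      segment = segment, territory = terr
    ),
    class = "polar_grid"
  )
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf(
    "polar_grid: %d rings x %d sectors = %d nodes, 17 AHA segments, 3 territories\n",
    x$n_rings, x$n_sectors, x$n_nodes
  ))
  invisible(x)
}

#' @export
as.data.frame.polar_grid <- function(x, ...) {
  data.frame(
    node = seq_len(x$n_nodes) - 1L,
    ring = x$ring,
    sector = x$sector,
    segment = x$segment,
    territory = as.character(x$territory),
    stringsAsFactors = FALSE
  )
}

#' Node index of a (ring, sector) position
#'
#' Maps the 0-based (ring, sector) coordinates to the 0-based node index
#' `ring * 23 + sector`, a bijection onto 0..459.
#'
#' @param ring Integer ring in 0..19 (0 = apex).
#' @param sector Integer sector in 0..22 (0 = anterior wall).
#' @return 0-based node index (vectorized over inputs).
#' @export
node_index <- function(ring, sector) {
  if (any(ring < 0L | ring >= 20L)) {
    stop("ring out of range 0..19", call. = FALSE)
  }
  if (any(sector < 0L | sector >= 23L)) {
    stop("sector out of range 0..22", call. = FALSE)
  }
  as.integer(ring) * 23L + as.integer(sector)
}

#' AHA segment assignment for grid nodes
#'
#' @param ring,sector 0-based grid coordinates (vectorized).
#' @param n_sectors Sectors per ring (23).
#' @return Integer segment ids in 1..17.
#' @keywords internal
assign_segments <- function(ring, sector, n_sectors = 23L) {
  angle <- (sector + 0.5) / n_sectors * 360 # angular center, degrees
  six <- function(a) as.integer(floor(((a + 30) %% 360) / 60)) # 0..5
  four <- function(a) as.integer(floor(((a + 45) %% 360) / 90)) # 0..3
  seg <- integer(length(ring))
  cap <- ring <= 4L
  api <- ring >= 5L & ring <= 9L
  mid <- ring >= 10L & ring <= 14L
  bas <- ring >= 15L
  seg[cap] <- 17L
  seg[api] <- 13L + four(angle[api])
  seg[mid] <- 7L + six(angle[mid])
  seg[bas] <- 1L + six(angle[bas])
  seg
}

#' Coronary territory of an AHA segment
#'
#' Standard Cerqueira attribution of the 17 AHA segments to the three main
#' coronary beds: LAD takes segments 1, 2, 7, 8, 13, 14 and the apical
#' cap 17; RCA takes 3, 4, 9, 10, 15; LCX takes 5, 6, 11, 12, 16.
#'
#' @param seg Integer segment id(s) in 1..17.
#' @return Factor with levels `LAD`, `RCA`, `LCX`.
#' @examples
#' territory_of_segment(17) # LAD
#' territory_of_segment(4)  # RCA
#' @export
territory_of_segment <- function(seg) {
  if (any(seg < 1L | seg > 17L | seg != round(seg))) {
    stop("segment id outside 1..17", call. = FALSE)
  }
  map <- rep(NA_character_, 17)
  map[c(1, 2, 7, 8, 13, 14, 17)] <- "LAD"
  map[c(3, 4, 9, 10, 15)] <- "RCA"
  map[c(5, 6, 11, 12, 16)] <- "LCX"
  factor(map[as.integer(seg)], levels = c("LAD", "RCA", "LCX"))
}

#' Names of the three coronary territories, in canonical order
#' @keywords internal
territory_levels <- function() c("LAD", "RCA", "LCX")

#' Reshape a polar map to the 23 x 20 raster used by the 2-D CNN
#'
#' Element (r, c) of the raster (1-based in R) is `values[(c-1)*23 + r]`,
#' so flattening the raster column-major recovers the original 460-vector.
#'
#' @param pm A [polar_map] or a numeric vector of length 460.
#' @return A 23 x 20 numeric matrix.
#' @export
reshape_to_raster <- function(pm) {
  v <- if (inherits(pm, "polar_map")) pm$values else pm
  stopifnot(length(v) == 460L)
  matrix(v, nrow = 23L, ncol = 20L)
}
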