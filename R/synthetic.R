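#' Synthetic polar-map cohort configuration
#'
#' The generator emulates the statistical structure the classifier relies
#' on: a smooth normal uptake pattern near the maximum, multiplicative
#' acquisition noise, and perfusion defects confined to contiguous AHA
#' segments of a single coronary territory. Default cohort sizes mirror the
#' clinical cohorts (rest: 266 normal / 237 abnormal; stress: 237 normal /
#' 206 abnormal).
#'
#' @param condition `"rest"` or `"stress"`; also selects default sizes.
#' @param n_normal,n_abnormal Cohort sizes (`NULL` = per-condition default).
#' @param base_level Mean normal uptake relative to the maximum (0.85).
#' @param smoothness Number of neighbour-averaging passes defining the
#'   spatial correlation length of the per-patient deviation field (in
#'   nodes; default 3).
#' @param regional_sd Standard deviation of the smooth per-patient
#'   deviation from the population uptake template, as a fraction of the
#'   template level (default 0.05; normal polar maps are stereotyped across
#'   patients).
#' @param noise_sd Multiplicative per-node noise scale (default 0.05).
#' @param defect_severity Fractional uptake reduction at the lesion core,
#'   in (0, 1) (default 0.5).
#' @param defect_extent Candidate numbers of contiguous lesion segments;
#'   one value is drawn per abnormal map and clipped to the territory size
#'   (default 1:3).
#' @param territory_weights Sampling weights over LAD/RCA/LCX (default
#'   equal).
#' @param seed Mandatory seed for cohort generation.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(condition = c("rest", "stress"),
                             n_normal = NULL, n_abnormal = NULL,
                             base_level = 0.85, smoothness = 3L,
                             regional_sd = 0.05, noise_sd = 0.05,
                             defect_severity = 0.5, defect_extent = 1:3,
                             territory_weights = c(1, 1, 1), seed = 0L) {
  condition <- match.arg(condition)
  if (is.null(n_normal)) n_normal <- if (condition == "rest") 266L else 237L
  if (is.null(n_abnormal)) n_abnormal <- if (condition == "rest") 237L else 206L
  stopifnot(
    n_normal >= 0L, n_abnormal >= 0L,
    base_level > 0, smoothness >= 0L, regional_sd >= 0, noise_sd >= 0,
    defect_severity >= 0, defect_severity < 1,
    all(defect_extent >= 1L), all(defect_extent <= 4L),
    length(territory_weights) == 3L, all(territory_weights >= 0),
    sum(territory_weights) > 0, !is.null(seed)
  )
  structure(
    list(
      condition = condition, n_normal = as.integer(n_normal),
      n_abnormal = as.integer(n_abnormal), base_level = base_level,
      smoothness = as.integer(smoothness), regional_sd = regional_sd,
      noise_sd = noise_sd, defect_severity = defect_severity,
      defect_extent = as.integer(defect_extent),
      territory_weights = territory_weights, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# iterated neighbour-averaging of a node signal over the polar graph
smooth_field <- function(x, passes, grid) {
  if (passes < 1L) {
    return(x)
  }
  A <- polar_adjacency_sparse(grid)
  deg <- Matrix::rowSums(A)
  for (i in seq_len(passes)) {
    x <- (x + as.numeric(A %*% x) / deg) / 2
  }
  x
}

# Deterministic population uptake template. Normal polar maps are highly
# stereotyped across patients; the template carries the two classic
# systematic features of SPECT polar maps: inferior-wall attenuation
# (centered at angle 180 from the anterior wall, ramping toward the base)
# and mild apical thinning.
population_template <- function(grid) {
  angle <- (grid$sector + 0.5) / grid$n_sectors * 360
  d180 <- pmin(abs(angle - 180), 360 - abs(angle - 180))
  inferior <- 0.12 * exp(-(d180 / 50)^2) * (0.3 + 0.7 * grid$ring / 19)
  apical <- 0.06 * exp(-(grid$ring / 5)^2)
  1 - inferior - apical
}

# anatomically contiguous segment chains within each territory
territory_chain <- function(territory) {
  switch(territory,
    LAD = c(1L, 7L, 13L, 17L, 14L, 8L, 2L),
    RCA = c(3L, 9L, 15L, 10L, 4L),
    LCX = c(5L, 11L, 16L, 12L, 6L)
  )
}

#' Draw one synthetic normal polar map
#'
#' Uptake is `base_level` times the deterministic population template
#' (inferior-wall attenuation plus mild apical thinning, shared by all
#' patients) times a smooth per-patient deviation field (iterated
#' neighbour-averaged Gaussian noise, sd `regional_sd`) times
#' multiplicative per-node noise, clipped at zero and max-normalized. All
#' 17 truth flags are zero. Draws consume the current R random-number
#' state.
#'
#' @param cfg A [synthetic_config].
#' @param grid A [polar_grid()].
#' @return A labeled, normalized [polar_map] with `segment_truth`.
#' @export
generate_normal <- function(cfg, grid = polar_grid()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- smooth_field(stats::rnorm(grid$n_nodes), cfg$smoothness, grid)
  s <- s / stats::sd(s)
  field <- population_template(grid) * (1 + cfg$regional_sd * s)
  noise <- 1 + stats::rnorm(grid$n_nodes, 0, cfg$noise_sd)
  uptake <- pmax(cfg$base_level * field * noise, 0)
  normalize_map(polar_map(uptake,
    condition = cfg$condition, label = "normal",
    segment_truth = integer(17)
  ))
}

#' Draw one synthetic abnormal polar map
#'
#' Starts from a normal draw, samples a coronary territory and a run of
#' contiguous segments within it, and attenuates uptake there by
#' `defect_severity` with a smooth falloff at the lesion border. The
#' attenuated segments are flagged in `segment_truth`, so the lesion always
#' lies in a single territory.
#'
#' @inheritParams generate_normal
#' @return A labeled, normalized [polar_map] with `segment_truth`.
#' @export
generate_abnormal <- function(cfg, grid = polar_grid()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  pm <- generate_normal(cfg, grid)
  terr <- sample(territory_levels(), 1L, prob = cfg$territory_weights)
  chain <- territory_chain(terr)
  extent <- min(
    if (length(cfg$defect_extent) == 1L) {
      cfg$defect_extent
    } else {
      sample(cfg$defect_extent, 1L)
    },
    length(chain)
  )
  start <- sample.int(length(chain) - extent + 1L, 1L)
  lesion <- chain[start:(start + extent - 1L)]
  core <- as.numeric(grid$segment %in% lesion)
  w <- smooth_field(core, 2L, grid)
  w <- w / max(w)
  pm$values <- pm$values * (1 - cfg$defect_severity * w)
  pm <- normalize_map(pm)
  pm$label <- "abnormal"
  pm$segment_truth <- as.integer(1:17 %in% lesion)
  pm
}

#' Territory-level ground truth from segment flags
#'
#' @param segment_truth 17 binary flags.
#' @return Named integer vector of 3 flags (LAD, RCA, LCX).
#' @export
territory_truth <- function(segment_truth) {
  aggregate_territories(segment_truth)
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_normal` normal and `n_abnormal` abnormal maps with the given
#' seed, shuffles their order and assigns sequential sample ids. With equal
#' seeds the output (including its CSV serialization) is byte-identical
#' across runs.
#'
#' @param cfg A [synthetic_config].
#' @param grid A [polar_grid()].
#' @return List of [polar_map] objects of length `n_normal + n_abnormal`.
#' @export
generate_cohort <- function(cfg, grid = polar_grid()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_normal + cfg$n_abnormal
  if (n < 1L) stop("cohort must contain at least one sample", call. = FALSE)
  .with_seed(cfg$seed, {
    maps <- c(
      lapply(seq_len(cfg$n_normal), function(i) generate_normal(cfg, grid)),
      lapply(seq_len(cfg$n_abnormal), function(i) generate_abnormal(cfg, grid))
    )
    maps <- maps[sample.int(n)]
    for (i in seq_len(n)) {
      maps[[i]]$sample_id <- sprintf("%s_%04d", cfg$condition, i)
    }
    maps
  })
}
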