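#' Segment-wise mean uptake of the normal population
#'
#' For each AHA segment, the mean of all node values inside the segment
#' pooled across all supplied normal maps. These per-condition means are the
#' replacement values used by the occlusion procedure and must come from
#' training normals only.
#'
#' @param normal_maps Nonempty list of normalized normal [polar_map]s.
#' @param grid A [polar_grid()].
#' @return Numeric vector of 17 segment means, class `segment_means`.
#' @export
compute_segment_means <- function(normal_maps, grid = polar_grid()) {
  if (length(normal_maps) == 0L) {
    stop("need at least one normal map", call. = FALSE)
  }
  V <- as_value_matrix(normal_maps) # n_maps x 460
  means <- vapply(
    1:17,
    function(s) mean(V[, grid$segment == s, drop = FALSE]),
    numeric(1)
  )
  structure(means, class = "segment_means")
}

#' Occlude one segment with its normal-population mean
#'
#' Returns a copy of the map in which every node of segment `seg` is
#' replaced by `means[seg]`; all other nodes are untouched. The operation
#' is idempotent.
#'
#' @param pm A [polar_map].
#' @param seg Segment id in 1..17.
#' @param means A [compute_segment_means] result (or numeric vector of 17).
#' @param grid A [polar_grid()].
#' @return The occluded [polar_map].
#' @export
occlude_segment <- function(pm, seg, means, grid = polar_grid()) {
  stopifnot(inherits(pm, "polar_map"), length(means) == 17L)
  if (length(seg) != 1L || seg < 1L || seg > 17L || seg != round(seg)) {
    stop("segment id must be a single integer in 1..17", call. = FALSE)
  }
  pm$values[grid$segment == seg] <- as.numeric(means)[seg]
  pm
}

#' Occlusion heatmap of per-segment abnormality probabilities
#'
#' For each of the 17 segments, the segment is replaced by its
#' normal-population mean and the modified map is fed to the trained
#' classifier; the recorded abnormal-class probability is the heatmap entry
#' for that segment. Occluding a truly pathological segment "heals" the
#' map, so on a well-trained model the lesion segment tends to carry the
#' minimum probability.
#'
#' @param model A trained `polargcn_model`.
#' @param pm The (abnormal) [polar_map] to explain.
#' @param means [compute_segment_means] of the training normals.
#' @param grid A [polar_grid()].
#' @return Numeric vector of 17 probabilities in [0, 1], with attribute
#'   `node_heatmap` rendering the per-node version (460 values).
#' @export
localization_heatmap <- function(model, pm, means, grid = polar_grid()) {
  stopifnot(inherits(model, "polargcn_model"))
  if (!isTRUE(model$trained)) {
    stop("localization requires a trained model", call. = FALSE)
  }
  occluded <- t(vapply(
    1:17,
    function(s) occlude_segment(pm, s, means, grid)$values,
    numeric(460)
  ))
  seg_prob <- as.numeric(predict(model, occluded, type = "prob")[, "abnormal"])
  attr(seg_prob, "node_heatmap") <- seg_prob[grid$segment]
  seg_prob
}

#' Threshold segment probabilities into pathological calls
#'
#' A segment is called pathological when its occlusion probability crosses
#' the threshold (default 0.4, the published operating point). With
#' `polarity = "high"` (default, the literal reading of the recorded
#' abnormal probability) a segment is called when `prob >= threshold`;
#' `polarity = "low"` implements the healing interpretation and calls a
#' segment when `prob < threshold`.
#'
#' @param seg_prob 17 probabilities from [localization_heatmap].
#' @param threshold Decision threshold (default 0.4; boundary values count
#'   as pathological under `"high"` polarity).
#' @param polarity `"high"` or `"low"` (see above).
#' @return Integer vector of 17 binary calls.
#' @export
call_segments <- function(seg_prob, threshold = 0.4,
                          polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  stopifnot(length(seg_prob) == 17L)
  if (polarity == "high") {
    as.integer(seg_prob >= threshold)
  } else {
    as.integer(seg_prob < threshold)
  }
}

#' Aggregate segment calls to coronary-territory calls
#'
#' A territory (LAD, RCA, LCX) is called pathological when any of its
#' segments is called.
#'
#' @param seg_call 17 binary segment calls (or truth flags).
#' @param grid Unused placeholder for interface symmetry.
#' @return Named integer vector of 3 territory calls (LAD, RCA, LCX).
#' @export
aggregate_territories <- function(seg_call, grid = NULL) {
  stopifnot(length(seg_call) == 17L)
  terr <- territory_of_segment(1:17)
  out <- vapply(
    territory_levels(),
    function(t) as.integer(any(seg_call[terr == t] == 1L)),
    integer(1)
  )
  names(out) <- territory_levels()
  out
}

#' Full occlusion localization of one polar map
#'
#' @inheritParams localization_heatmap
#' @inheritParams call_segments
#' @return An object of class `localization_result` with `seg_prob` (17),
#'   `seg_call` (17), `territory_call` (3, named LAD/RCA/LCX), `threshold`
#'   and `polarity`.
#' @export
localize <- function(model, pm, means, threshold = 0.4,
                     polarity = c("high", "low"), grid = polar_grid()) {
  polarity <- match.arg(polarity)
  seg_prob <- localization_heatmap(model, pm, means, grid)
  seg_call <- call_segments(seg_prob, threshold, polarity)
  structure(
    list(
      seg_prob = as.numeric(seg_prob), seg_call = seg_call,
      territory_call = aggregate_territories(seg_call),
      threshold = threshold, polarity = polarity,
      sample_id = pm$sample_id
    ),
    class = "localization_result"
  )
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "localization_result '%s': segments called {%s}; territories %s (threshold %.2f, %s polarity)\n",
    x$sample_id,
    paste(which(x$seg_call == 1L), collapse = ","),
    paste(names(x$territory_call)[x$territory_call == 1L], collapse = ","),
    x$threshold, x$polarity
  ))
  invisible(x)
}

seg_calls_of <- function(r) {
  if (inherits(r, "localization_result")) r$seg_call else as.integer(r)
}

#' Evaluate localization against per-segment ground truth
#'
#' Decisions are pooled (micro-averaged) across maps: the 17-segment report
#' pools all 17 x N segment decisions, the territory report pools all 3 x N
#' territory decisions (territory truth = any flagged segment in the
#' territory), and per-vessel reports evaluate each territory's N decisions
#' separately.
#'
#' @param results List of `localization_result`s or 17-flag call vectors.
#' @param truths List of 17-flag ground-truth vectors.
#' @return List with `segment`, `territory` (both [evaluate] reports) and
#'   `per_vessel` (named list of per-territory reports).
#' @export
evaluate_localization <- function(results, truths) {
  if (length(results) == 0L || length(results) != length(truths)) {
    stop("results and truths must be nonempty and of equal length",
      call. = FALSE
    )
  }
  if (any(vapply(truths, is.null, logical(1)))) {
    stop("missing segment ground truth", call. = FALSE)
  }
  calls <- lapply(results, seg_calls_of)
  truths <- lapply(truths, as.integer)
  stopifnot(all(lengths(calls) == 17L), all(lengths(truths) == 17L))
  seg_pred <- unlist(calls)
  seg_true <- unlist(truths)
  terr_pred <- t(vapply(calls, aggregate_territories, integer(3)))
  terr_true <- t(vapply(truths, aggregate_territories, integer(3)))
  per_vessel <- lapply(seq_along(territory_levels()), function(t) {
    evaluate(terr_pred[, t], terr_true[, t])
  })
  names(per_vessel) <- territory_levels()
  list(
    segment = evaluate(seg_pred, seg_true),
    territory = evaluate(as.vector(terr_pred), as.vector(terr_true)),
    per_vessel = per_vessel
  )
}

#' Per-segment detection/annotation frequencies over a cohort
#'
#' @param flags List of 17-flag vectors (ground truth or calls).
#' @return Integer vector of 17 per-segment counts.
#' @export
frequency_heatmap <- function(flags) {
  if (length(flags) == 0L) {
    return(integer(17))
  }
  flags <- lapply(flags, seg_calls_of)
  stopifnot(all(lengths(flags) == 17L))
  as.integer(Reduce(`+`, flags))
}
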