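#' Construct a polar-map sample
#'
#' A polar map is a vector of 460 nonnegative relative tracer-uptake values
#' defined on the nodes of [polar_grid()], tagged with the acquisition
#' condition (rest or stress) and, optionally, an expert label
#' (normal/abnormal) and per-segment ground-truth flags.
#'
#' @param values Numeric vector of length 460, all nonnegative.
#' @param condition `"rest"` or `"stress"`.
#' @param label Optional, `"normal"` or `"abnormal"` (or `NA`).
#' @param segment_truth Optional integer/logical vector of 17 binary flags
#'   (1 = segment annotated pathological), or `NULL`.
#' @param sample_id Opaque identifier string.
#' @return An object of class `polar_map`.
#' @export
polar_map <- function(values, condition = c("rest", "stress"), label = NULL,
                      segment_truth = NULL, sample_id = "") {
  condition <- match.arg(condition)
  values <- as.numeric(values)
  if (length(values) != 460L) {
    stop("a polar map holds exactly 460 values, got ", length(values),
      call. = FALSE
    )
  }
  if (anyNA(values) || any(values < 0)) {
    stop("polar-map values must be nonnegative and non-missing", call. = FALSE)
  }
  if (!is.null(label) && !is.na(label)) {
    if (!label %in% c("normal", "abnormal")) {
      stop("label must be 'normal' or 'abnormal'", call. = FALSE)
    }
  } else {
    label <- NA_character_
  }
  if (!is.null(segment_truth)) {
    segment_truth <- as.integer(segment_truth)
    if (length(segment_truth) != 17L ||
      any(!segment_truth %in% c(0L, 1L), na.rm = TRUE)) {
      stop("segment_truth must be 17 binary flags", call. = FALSE)
    }
  }
  structure(
    list(
      values = values, condition = condition, label = label,
      segment_truth = segment_truth, sample_id = as.character(sample_id)
    ),
    class = "polar_map"
  )
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf(
    "polar_map '%s' (%s, %s): 460 values in [%.3g, %.3g]%s\n",
    x$sample_id, x$condition,
    ifelse(is.na(x$label), "unlabeled", x$label),
    min(x$values), max(x$values),
    if (!is.null(x$segment_truth)) {
      sprintf(", %d flagged segment(s)", sum(x$segment_truth))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Normalize a polar map by its maximum uptake
#'
#' Divides every value by the per-map maximum so that the brightest node
#' equals 1 exactly. The operation is idempotent and invariant to positive
#' rescaling of the input.
#'
#' @param pm A [polar_map].
#' @return The normalized [polar_map].
#' @export
normalize_map <- function(pm) {
  stopifnot(inherits(pm, "polar_map"))
  m <- max(pm$values)
  if (m <= 0) {
    stop("degenerate polar map: all values are zero, cannot normalize",
      call. = FALSE
    )
  }
  pm$values <- pm$values / m
  pm
}

seg_cols <- function() sprintf("seg%02d", 1:17)
val_cols <- function() sprintf("v%03d", 0:459)

#' Read / write polar-map tables
#'
#' The on-disk format is CSV with a mandatory header and one sample per row:
#' `sample_id`, `condition` (rest|stress), `label` (normal|abnormal|NA),
#' `seg01`..`seg17` (0/1/NA ground-truth flags) and `v000`..`v459` (uptake
#' values). The round trip is lossless for labels, flags and values (to
#' text-float precision).
#'
#' @param path File path.
#' @return `read_polarmap_table` returns a list of [polar_map] objects
#'   (empty list for an empty file).
#' @export
read_polarmap_table <- function(path) {
  n_fields <- 3L + 17L + 460L
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0L) {
    return(list())
  }
  counts <- utils::count.fields(path, sep = ",")
  bad <- which(counts != n_fields)
  if (length(bad)) {
    stop(sprintf(
      "parse error at line %d of '%s': expected %d fields, found %d",
      bad[1], path, n_fields, counts[bad[1]]
    ), call. = FALSE)
  }
  df <- utils::read.csv(path,
    stringsAsFactors = FALSE,
    na.strings = "NA", check.names = FALSE
  )
  expected <- c("sample_id", "condition", "label", seg_cols(), val_cols())
  if (!identical(names(df), expected)) {
    stop("parse error: header does not match the polar-map table schema",
      call. = FALSE
    )
  }
  if (nrow(df) == 0L) {
    return(list())
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L # header occupies line 1
    cond <- df$condition[i]
    if (!cond %in% c("rest", "stress")) {
      stop(sprintf(
        "parse error at line %d: unknown condition token '%s'", line, cond
      ), call. = FALSE)
    }
    lab <- df$label[i]
    if (!is.na(lab) && !lab %in% c("normal", "abnormal")) {
      stop(sprintf(
        "parse error at line %d: unknown label token '%s'", line, lab
      ), call. = FALSE)
    }
    vals <- as.numeric(df[i, val_cols()])
    if (anyNA(vals) || any(vals < 0)) {
      stop(sprintf(
        "parse error at line %d: missing or negative uptake value", line
      ), call. = FALSE)
    }
    flags <- as.integer(df[i, seg_cols()])
    if (all(is.na(flags))) flags <- NULL
    out[[i]] <- polar_map(vals,
      condition = cond, label = lab,
      segment_truth = flags, sample_id = df$sample_id[i]
    )
  }
  out
}

#' @param maps List of [polar_map] objects.
#' @rdname read_polarmap_table
#' @export
write_polarmap_table <- function(maps, path) {
  stopifnot(all(vapply(maps, inherits, logical(1), "polar_map")))
  n <- length(maps)
  vals <- t(vapply(maps, function(m) m$values, numeric(460)))
  flags <- t(vapply(maps, function(m) {
    if (is.null(m$segment_truth)) rep(NA_integer_, 17L) else m$segment_truth
  }, integer(17)))
  df <- data.frame(
    sample_id = vapply(maps, function(m) m$sample_id, character(1)),
    condition = vapply(maps, function(m) m$condition, character(1)),
    label = vapply(maps, function(m) m$label, character(1)),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    df <- df[0, , drop = FALSE]
    vals <- matrix(numeric(0), 0, 460)
    flags <- matrix(integer(0), 0, 17)
  }
  colnames(flags) <- seg_cols()
  colnames(vals) <- val_cols()
  df <- cbind(df, as.data.frame(flags), as.data.frame(vals))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
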