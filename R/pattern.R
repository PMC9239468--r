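#' Rectangular observation window
#'
#' An axis-aligned rectangle, in microns, inside which a cell pattern was
#' observed. The window area enters every intensity estimate, so an explicit
#' window from the imaging platform should be preferred over the inferred one.
#'
#' @param xmin,xmax,ymin,ymax Window limits in microns; `xmax > xmin` and
#'   `ymax > ymin` are required.
#' @return An object of class `obs_window` with fields `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @export
obs_window <- function(xmin, xmax, ymin, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(xmax), is.numeric(ymin), is.numeric(ymax))
  if (!(xmax > xmin && ymax > ymin)) {
    stop("invalid window: need xmax > xmin and ymax > ymin", call. = FALSE)
  }
  structure(list(xmin = as.numeric(xmin), xmax = as.numeric(xmax),
                 ymin = as.numeric(ymin), ymax = as.numeric(ymax)),
            class = "obs_window")
}

#' Window area in squared microns
#' @param w An `obs_window`.
#' @return Numeric scalar, `(xmax - xmin) * (ymax - ymin)`.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "obs_window"))
  (w$xmax - w$xmin) * (w$ymax - w$ymin)
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf("window [%g, %g] x [%g, %g] (area %g)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, window_area(x)))
  invisible(x)
}

# Bounding box expanded by 1% of each side's range. A tight bounding box is
# a biased (too small) window for intensity estimation; the expansion is the
# package's declared stand-in when no window is supplied by the platform.
.infer_window <- function(x, y) {
  rx <- range(x); ry <- range(y)
  dx <- diff(rx); dy <- diff(ry)
  # degenerate (collinear / single point) patterns still need a valid window
  if (dx <= 0) dx <- max(diff(ry), 1)
  if (dy <= 0) dy <- max(diff(rx), 1)
  obs_window(rx[1] - 0.01 * dx, rx[2] + 0.01 * dx,
             ry[1] - 0.01 * dy, ry[2] + 0.01 * dy)
}

#' Marked point pattern
#'
#' A set of cell centroids inside an observation window, each carrying a
#' categorical type (e.g. tumor / stroma) and optionally named continuous
#' marks (e.g. marker intensities). Coordinates are real-valued microns; no
#' grid snapping is performed and duplicated coordinates are permitted (cells
#' can abut) but reported via a message.
#'
#' @param x,y Numeric coordinate vectors (microns).
#' @param type Character or factor vector of cell types, one per point.
#' @param marks Optional data frame (or named list) of numeric marks, one row
#'   per point. Non-finite mark values are kept in the pattern and excluded
#'   only by operations that need that mark.
#' @param window An [obs_window()], or `NULL` to infer the expanded bounding
#'   box of the points.
#' @param subject_id,image_id Identifiers carried through the pipeline.
#' @param type_levels Declared label set; defaults to the observed labels.
#' @return An object of class `mpp` with fields `x`, `y`, `type` (factor),
#'   `marks` (data frame), `window`, `subject_id`, `image_id`.
#' @export
mpp <- function(x, y, type, marks = NULL, window = NULL,
                subject_id = NA_character_, image_id = NA_character_,
                type_levels = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n, length(type) == n)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite coordinates; filter rows before constructing a pattern",
         call. = FALSE)
  }
  if (is.null(type_levels)) type_levels <- unique(as.character(type))
  type <- factor(as.character(type), levels = type_levels)
  if (anyNA(type)) stop("types outside the declared label set", call. = FALSE)
  if (is.null(window)) {
    window <- if (n > 0) .infer_window(x, y) else obs_window(0, 1, 0, 1)
  }
  stopifnot(inherits(window, "obs_window"))
  inside <- x >= window$xmin & x <= window$xmax &
            y >= window$ymin & y <= window$ymax
  if (!all(inside)) {
    stop(sprintf("%d point(s) lie outside the observation window", sum(!inside)),
         call. = FALSE)
  }
  if (is.null(marks)) {
    marks <- as.data.frame(matrix(nrow = n, ncol = 0))
  } else {
    marks <- as.data.frame(marks)
    stopifnot(nrow(marks) == n)
    if (!all(vapply(marks, is.numeric, logical(1)))) {
      stop("marks must be numeric", call. = FALSE)
    }
  }
  if (n > 1 && anyDuplicated(cbind(x, y))) {
    message(sprintf("pattern %s/%s: %d duplicated coordinate pair(s) retained",
                    subject_id, image_id, sum(duplicated(cbind(x, y)))))
  }
  structure(list(x = x, y = y, type = type, marks = marks, window = window,
                 subject_id = as.character(subject_id),
                 image_id = as.character(image_id)),
            class = "mpp")
}

#' Number of points in a pattern
#' @param p An `mpp`.
#' @param type Optional type label; if given, counts points of that type.
#' @return Integer count.
#' @export
npoints <- function(p, type = NULL) {
  stopifnot(inherits(p, "mpp"))
  if (is.null(type)) length(p$x) else sum(p$type == type)
}

#' @export
print.mpp <- function(x, ...) {
  cat(sprintf("marked point pattern: %d points (subject %s, image %s)\n",
              npoints(x), x$subject_id, x$image_id))
  if (npoints(x) > 0) print(table(x$type))
  if (ncol(x$marks) > 0)
    cat("marks:", paste(names(x$marks), collapse = ", "), "\n")
  print(x$window)
  invisible(x)
}

# subset a pattern by point index, keeping window and ids
.subset_mpp <- function(p, idx) {
  mpp(p$x[idx], p$y[idx], as.character(p$type[idx]),
      marks = p$marks[idx, , drop = FALSE], window = p$window,
      subject_id = p$subject_id, image_id = p$image_id,
      type_levels = levels(p$type))
}

#' Collapse pixel-level segmentation output to cell centroids
#'
#' Each cell, identified by `cell_id`, is represented by the arithmetic mean
#' of its pixel coordinates; the cell's type must be unique across its pixels.
#'
#' @param pixel_table Data frame with columns `pixel_x`, `pixel_y`, `cell_id`,
#'   `type`.
#' @param window Optional [obs_window()]; inferred from centroids otherwise.
#' @param subject_id,image_id Identifiers for the resulting pattern.
#' @return An [mpp()] with one point per distinct `cell_id`.
#' @export
pixels_to_centroids <- function(pixel_table, window = NULL,
                                subject_id = NA_character_,
                                image_id = NA_character_) {
  req <- c("pixel_x", "pixel_y", "cell_id", "type")
  miss <- setdiff(req, names(pixel_table))
  if (length(miss) > 0) {
    stop("pixel table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(pixel_table$cell_id)
  ntypes <- tapply(as.character(pixel_table$type), pixel_table$cell_id,
                   function(t) length(unique(t)))
  if (any(ntypes > 1)) {
    bad <- names(ntypes)[ntypes > 1]
    stop("conflicting type labels for cell_id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cx <- tapply(pixel_table$pixel_x, pixel_table$cell_id, mean)
  cy <- tapply(pixel_table$pixel_y, pixel_table$cell_id, mean)
  ty <- tapply(as.character(pixel_table$type), pixel_table$cell_id, `[`, 1)
  ids <- names(cx)  # tapply ordering
  mpp(as.numeric(cx), as.numeric(cy), as.character(ty), window = window,
      subject_id = subject_id, image_id = image_id)
}

#' Pick the representative image for a subject
#'
#' Sparse fields of view carry little spatial information, so each subject is
#' represented by their densest image: the one with the maximum number of
#' cells. Ties are broken by the lexicographically smallest `image_id` so the
#' choice is deterministic and permutation-invariant.
#'
#' @param patterns A list of [mpp()] objects belonging to one subject.
#' @return The selected pattern.
#' @export
select_representative_image <- function(patterns) {
  if (length(patterns) == 0) stop("no images supplied", call. = FALSE)
  stopifnot(all(vapply(patterns, inherits, logical(1), "mpp")))
  ns <- vapply(patterns, npoints, integer(1))
  ids <- vapply(patterns, function(p) p$image_id, character(1))
  cand <- which(ns == max(ns))
  patterns[[cand[order(ids[cand])[1]]]]
}

#' Dichotomize a subject by the positive fraction of a marker
#'
#' Classifies a pattern as `"hi"` when the fraction of cells of `type_label`
#' with `mark > threshold_value` strictly exceeds `fraction` (default 5%),
#' else `"lo"`. This mirrors the common practice of splitting cohorts into
#' marker-high and marker-low groups (e.g. MHCII-high vs MHCII-low tumors).
#'
#' @param pattern An [mpp()].
#' @param type_label Cell type whose positivity is assessed.
#' @param mark Name of the mark column.
#' @param threshold_value Positivity cut: a cell is positive when its mark
#'   strictly exceeds this value.
#' @param fraction Positive-fraction cut, default `0.05`.
#' @return `"hi"` or `"lo"`.
#' @export
dichotomize_by_positive_fraction <- function(pattern, type_label, mark,
                                             threshold_value, fraction = 0.05) {
  stopifnot(inherits(pattern, "mpp"))
  if (!mark %in% names(pattern$marks)) {
    stop("unknown mark: ", mark, call. = FALSE)
  }
  sel <- pattern$type == type_label
  if (!any(sel)) {
    stop("no cells of type '", type_label, "' in pattern", call. = FALSE)
  }
  v <- pattern$marks[[mark]][sel]
  v <- v[is.finite(v)]  # missing marks excluded from this operation only
  if (length(v) == 0) stop("no finite '", mark, "' values for type '",
                           type_label, "'", call. = FALSE)
  if (mean(v > threshold_value) > fraction) "hi" else "lo"
}
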