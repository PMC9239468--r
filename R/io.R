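#' Read a cell table into a list of marked point patterns
#'
#' Reads a delimited text table with one row per cell and splits it into one
#' pattern per (subject, image). Canonical columns are
#' `subject_id,image_id,x,y,cell_type,<mark columns>`; other layouts are
#' handled through `column_map`. Rows with non-finite coordinates are dropped
#' with a message stating the count.
#'
#' @param path Path to a CSV file.
#' @param column_map Named list mapping roles to column names:
#'   `x`, `y`, `type`, `subject`, `image` (mandatory roles) and `marks`
#'   (character vector of mark columns, possibly empty). See
#'   [read_column_map()] for loading the mapping from a YAML config.
#' @param window Optional [obs_window()] shared by all images; inferred per
#'   image otherwise.
#' @param sep Field separator, default comma.
#' @return Named list of [mpp()] objects, keyed `"<subject>.<image>"`.
#' @export
read_cell_table <- function(path, column_map = default_column_map(),
                            window = NULL, sep = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  roles <- c(x = "x", y = "y", type = "type", subject = "subject", image = "image")
  for (role in names(roles)) {
    if (is.null(column_map[[role]])) {
      stop("column_map must name the '", role, "' column", call. = FALSE)
    }
  }
  need <- unlist(column_map[names(roles)], use.names = FALSE)
  marks <- column_map$marks %||% character()
  miss <- setdiff(c(need, marks), names(df))
  if (length(miss) > 0) {
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty cell table: ", path, call. = FALSE)
    return(structure(list(), names = character()))
  }
  xs <- as.numeric(df[[column_map$x]])
  ys <- as.numeric(df[[column_map$y]])
  bad <- !is.finite(xs) | !is.finite(ys)
  if (any(bad)) {
    message(sprintf("dropped %d row(s) with non-finite coordinates", sum(bad)))
    df <- df[!bad, , drop = FALSE]
    xs <- xs[!bad]; ys <- ys[!bad]
  }
  type_levels <- unique(as.character(df[[column_map$type]]))
  key <- interaction(df[[column_map$subject]], df[[column_map$image]],
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(df)), key)
  out <- lapply(idx, function(ii) {
    mpp(xs[ii], ys[ii], as.character(df[[column_map$type]][ii]),
        marks = if (length(marks) > 0) df[ii, marks, drop = FALSE] else NULL,
        window = window,
        subject_id = as.character(df[[column_map$subject]][ii][1]),
        image_id = as.character(df[[column_map$image]][ii][1]),
        type_levels = type_levels)
  })
  out
}

#' Default column mapping for the canonical cell-table schema
#' @param marks Character vector of mark column names.
#' @return A named list usable as `column_map` in [read_cell_table()].
#' @export
default_column_map <- function(marks = character()) {
  list(x = "x", y = "y", type = "cell_type",
       subject = "subject_id", image = "image_id", marks = marks)
}

#' Load a column mapping from a YAML config file
#'
#' The config must contain keys `x`, `y`, `type`, `subject`, `image` and
#' optionally `marks` (a sequence). Requires the `yaml` package.
#'
#' @param path Path to a YAML file.
#' @return A named list usable as `column_map` in [read_cell_table()].
#' @export
read_column_map <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  cfg$marks <- as.character(cfg$marks %||% character())
  cfg
}

#' Read a subject-level survival table
#'
#' Expects columns `subject_id,time,event,<scalar covariates>`. Subjects with
#' missing survival time or event indicator are dropped with a message (the
#' explicit-filter policy for missing outcomes).
#'
#' @param path Path to a CSV file.
#' @return Data frame with `subject_id` as character, `time` numeric (> 0)
#'   and `event` in {0, 1}.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "time", "event"), names(df))
  if (length(miss) > 0) {
    stop("survival table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(df$time) | !is.finite(df$event)
  if (any(bad)) {
    message(sprintf("dropped %d subject(s) with missing survival outcome",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (any(df$time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

# full-precision numeric formatting so a write/read cycle is bit-for-bit
.fmt17 <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
}

#' Write a cohort of patterns to the canonical CSV pair
#'
#' Writes `cells.csv` (canonical columns, full `%.17g` precision so that
#' re-reading reproduces coordinates and marks bit-for-bit) and `windows.csv`
#' (per-image window limits) into `dir`.
#'
#' @param patterns List of [mpp()] objects.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(patterns, dir) {
  stopifnot(length(patterns) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mark_names <- unique(unlist(lapply(patterns, function(p) names(p$marks))))
  rows <- lapply(patterns, function(p) {
    base <- data.frame(subject_id = rep(p$subject_id, npoints(p)),
                       image_id = rep(p$image_id, npoints(p)),
                       x = .fmt17(p$x), y = .fmt17(p$y),
                       cell_type = as.character(p$type),
                       stringsAsFactors = FALSE)
    for (m in mark_names) {
      base[[m]] <- if (m %in% names(p$marks)) .fmt17(p$marks[[m]])
                   else rep(NA_character_, npoints(p))
    }
    base
  })
  cells <- do.call(rbind, rows)
  wins <- do.call(rbind, lapply(patterns, function(p) {
    data.frame(subject_id = p$subject_id, image_id = p$image_id,
               xmin = .fmt17(p$window$xmin), xmax = .fmt17(p$window$xmax),
               ymin = .fmt17(p$window$ymin), ymax = .fmt17(p$window$ymax),
               stringsAsFactors = FALSE)
  }))
  cp <- file.path(dir, "cells.csv"); wp <- file.path(dir, "windows.csv")
  utils::write.csv(cells, cp, row.names = FALSE, quote = FALSE)
  utils::write.csv(wins, wp, row.names = FALSE, quote = FALSE)
  invisible(c(cells = cp, windows = wp))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cells.csv` and `windows.csv`.
#' @param marks Character vector of mark columns to attach; defaults to every
#'   non-canonical column present.
#' @return Named list of [mpp()] objects.
#' @export
read_cohort <- function(dir, marks = NULL) {
  cp <- file.path(dir, "cells.csv"); wp <- file.path(dir, "windows.csv")
  header <- names(utils::read.csv(cp, nrows = 1))
  if (is.null(marks)) {
    marks <- setdiff(header, c("subject_id", "image_id", "x", "y", "cell_type"))
  }
  pats <- read_cell_table(cp, default_column_map(marks = marks))
  if (file.exists(wp)) {
    wins <- utils::read.csv(wp, stringsAsFactors = FALSE)
    for (k in seq_along(pats)) {
      p <- pats[[k]]
      row <- which(wins$subject_id == p$subject_id &
                   wins$image_id == p$image_id)
      if (length(row) == 1) {
        w <- obs_window(wins$xmin[row], wins$xmax[row],
                        wins$ymin[row], wins$ymax[row])
        pats[[k]] <- mpp(p$x, p$y, as.character(p$type), marks = p$marks,
                         window = w, subject_id = p$subject_id,
                         image_id = p$image_id, type_levels = levels(p$type))
      }
    }
  }
  pats
}

`%||%` <- function(a, b) if (is.null(a)) b else a
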