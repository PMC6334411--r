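#' Rectangular regions of interest
#'
#' ROIs are axis-aligned rectangles in nm. Membership is half-open:
#' a localization belongs to a ROI iff `x_min <= x < x_max` and
#' `y_min <= y < y_max`, so abutting ROIs partition the plane without
#' double-counting boundary points.
#'
#' @param name character labels, one per ROI.
#' @param x_min,y_min,x_max,y_max rectangle bounds in nm with
#'   `x_min < x_max`, `y_min < y_max`.
#' @return A data frame of class `roi_set`.
#' @export
roi_set <- function(name, x_min, y_min, x_max, y_max) {
  rois <- data.frame(name = as.character(name),
                     x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                     x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                     stringsAsFactors = FALSE)
  if (any(rois$x_min >= rois$x_max) || any(rois$y_min >= rois$y_max))
    stop("invalid ROI: require x_min < x_max and y_min < y_max")
  if (anyDuplicated(rois$name)) stop("ROI names must be unique")
  class(rois) <- c("roi_set", "data.frame")
  rois
}

#' Read ROI rectangles from a delimited file
#'
#' Expects a header with columns `name,x_min,y_min,x_max,y_max` (nm).
#'
#' @param path CSV/TSV file (separator by extension, `.tsv`/`.txt` = tab).
#' @return A `roi_set`.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("name", "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("ROI file is missing column(s): ", paste(miss, collapse = ", "))
  roi_set(df$name, df$x_min, df$y_min, df$x_max, df$y_max)
}

#' Write ROI rectangles to CSV
#' @param rois a `roi_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  utils::write.table(as.data.frame(rois), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Split a localization table into regions of interest
#'
#' Assigns each localization to every ROI containing it (half-open bounds;
#' overlapping ROIs duplicate shared localizations into each). Coordinates
#' in each per-ROI table are re-expressed relative to the ROI origin
#' `(x_min, y_min)`, so `0 <= x < width` and `0 <= y < height` hold in
#' every emitted table. Row order and ids are preserved.
#'
#' @param tab a `loc_table`.
#' @param rois a `roi_set` (or data frame with the same columns).
#' @return A `roi_collection`: list with elements `rois` (the `roi_set`)
#'   and `tables` (named list of `loc_table`, one per ROI, in ROI order).
#' @export
split_rois <- function(tab, rois) {
  validate_loc_table(tab)
  if (!inherits(rois, "roi_set"))
    rois <- roi_set(rois$name, rois$x_min, rois$y_min, rois$x_max, rois$y_max)
  tables <- vector("list", nrow(rois))
  names(tables) <- rois$name
  for (i in seq_len(nrow(rois))) {
    keep <- tab$x >= rois$x_min[i] & tab$x < rois$x_max[i] &
      tab$y >= rois$y_min[i] & tab$y < rois$y_max[i]
    sub <- tab[keep, , drop = FALSE]
    sub$x <- sub$x - rois$x_min[i]
    sub$y <- sub$y - rois$y_min[i]
    rownames(sub) <- NULL
    class(sub) <- c("loc_table", "data.frame")
    tables[[i]] <- sub
  }
  structure(list(rois = rois, tables = tables), class = "roi_collection")
}

#' @export
print.roi_collection <- function(x, ...) {
  cat(sprintf("<roi_collection> %d ROIs, %s localizations\n",
              length(x$tables),
              paste(vapply(x$tables, nrow, 0L), collapse = "/")))
  invisible(x)
}
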