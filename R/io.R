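# Reduced-data and mask I/O.  Reduced data are tab-separated text with a
# header (columns id, x, y, I; '#' starts a comment), one table per
# diffraction image.

#' Read a reduced-data table
#'
#' Validates the observed spot list: required columns `id, x, y, I`;
#' rows with non-positive intensity are rejected (with their row
#' numbers); a `sigI` column, if present, is parsed but ignored with a
#' warning (observation weights are derived from the intensities
#' instead).
#'
#' @param path Tab-separated file with header.
#' @return `data.frame` with columns `id, x, y, I` (extra columns
#'   preserved).
#' @export
read_reduced_data <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "x", "y", "I")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("reduced data %s: missing required column(s) %s",
                 path, paste(miss, collapse = ", ")))
  if ("sigI" %in% names(df))
    warning("sigI column present but ignored: weights are derived from intensities")
  bad <- which(!(df$I > 0))
  if (length(bad)) {
    warning(sprintf("rejected %d row(s) with non-positive intensity: %s",
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
  }
  if (anyDuplicated(df$id))
    stop("spot ids are not unique within the image")
  rownames(df) <- NULL
  df$id <- as.character(df$id)
  df
}

#' Write a reduced-data table
#' @param spots `data.frame` with columns `id, x, y, I`.
#' @param path Output path (tab-separated, with header).
#' @export
write_reduced_data <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Detector mask
#'
#' Region specifications for excluding unreliable detector areas (e.g.
#' the beamstop shadow).  Supported kinds: a filled circle, a rectangle,
#' an 8-bit PNG aligned to the image grid (nonzero = masked), or a union
#' of masks.
#'
#' @param kind `"circle"`, `"rect"`, `"png"` or `"union"`.
#' @param center,radius Circle spec (pixels).
#' @param xlim,ylim Rectangle spec (pixels).
#' @param file PNG file for a bitmap mask.
#' @param members List of masks for a union.
#' @return A `detector_mask`.
#' @export
detector_mask <- function(kind = c("circle", "rect", "png", "union"),
                          center = NULL, radius = NULL,
                          xlim = NULL, ylim = NULL, file = NULL,
                          members = NULL) {
  kind <- match.arg(kind)
  m <- switch(kind,
    circle = { stopifnot(length(center) == 2, radius > 0)
               list(kind = kind, center = center, radius = radius) },
    rect = { stopifnot(length(xlim) == 2, length(ylim) == 2)
             list(kind = kind, xlim = sort(xlim), ylim = sort(ylim)) },
    png = { img <- png::readPNG(file)
            if (length(dim(img)) == 3) img <- img[, , 1]
            list(kind = kind, bitmap = img > 0) },
    union = { stopifnot(length(members) >= 1)
              list(kind = kind, members = members) })
  structure(m, class = "detector_mask")
}

#' Test points against a detector mask
#' @param mask A [detector_mask()] (or `NULL`: nothing is masked).
#' @param x,y Pixel coordinates (0-based, pixel-center).
#' @return Logical vector: `TRUE` where masked.
#' @export
mask_contains <- function(mask, x, y) {
  if (is.null(mask)) return(rep(FALSE, length(x)))
  switch(mask$kind,
    circle = (x - mask$center[1])^2 + (y - mask$center[2])^2 <= mask$radius^2,
    rect = x >= mask$xlim[1] & x <= mask$xlim[2] &
           y >= mask$ylim[1] & y <= mask$ylim[2],
    png = {
      nr <- nrow(mask$bitmap); nc <- ncol(mask$bitmap)
      i <- round(y) + 1L; j <- round(x) + 1L
      ok <- i >= 1L & i <= nr & j >= 1L & j <= nc
      out <- rep(TRUE, length(x))              # off-detector counts as masked
      out[ok] <- mask$bitmap[cbind(i[ok], j[ok])]
      out
    },
    union = {
      out <- rep(FALSE, length(x))
      for (m in mask$members) out <- out | mask_contains(m, x, y)
      out
    })
}
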