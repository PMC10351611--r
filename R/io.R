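# Readers and writers for the standard on-disk formats: grayscale PNG
# images, CSV manifests and ground-truth boxes, JSON-lines detections.
# Coordinate convention throughout: x = column, y = row, origin top-left,
# 0-based half-open boxes (x_min, y_min, x_max, y_max).

#' Bounding box
#'
#' 0-based, half-open pixel box: a pixel `(x, y)` is inside iff
#' `x_min <= x < x_max` and `y_min <= y < y_max`, so the area is
#' `(x_max - x_min) * (y_max - y_min)` with no off-by-one ambiguity.
#'
#' @param x_min,y_min,x_max,y_max pixel coordinates with `x_min < x_max`,
#'   `y_min < y_max`.
#' @return list of class `bounding_box`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  v <- c(x_min, y_min, x_max, y_max)
  if (any(!is.finite(v)) || x_min >= x_max || y_min >= y_max)
    stop(sprintf("degenerate box (%s)", paste(v, collapse = ",")),
         call. = FALSE)
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "bounding_box")
}

box_area <- function(b) (b$x_max - b$x_min) * (b$y_max - b$y_min)

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale PNG and rescales intensities to
#' `[0, 1]` (8-bit: /255; 16-bit: /65535 -- the png reader performs this
#' scaling).  Multi-channel PNGs are collapsed by channel averaging.
#' DICOM input is not supported by this build and raises an error.
#'
#' @param path file path.
#' @param target_size optional side length; the image is resized by
#'   bilinear interpolation.
#' @return H x W matrix of intensities in `[0, 1]`.
#' @export
read_image <- function(path, target_size = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    stop("DICOM input is not supported; convert ", path,
         " to 16-bit grayscale PNG", call. = FALSE)
  if (ext != "png")
    stop("unknown image format '", ext, "' for ", path, call. = FALSE)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("corrupt PNG file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])),
                                               drop = FALSE], c(1, 2), mean)
  if (!is.null(target_size) && !all(dim(img) == target_size))
    img <- resize_bilinear(img, target_size, target_size)
  img
}

# plain bilinear resampling with half-pixel centres
resize_bilinear <- function(x, h, w) {
  map <- function(n_out, n_in) {
    src <- pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out - 0.5, 0),
                n_in - 1)
    i0 <- floor(src)
    list(i0 = i0 + 1, i1 = pmin(i0 + 2, n_in), w = src - i0)
  }
  r <- map(h, nrow(x)); cc <- map(w, ncol(x))
  a <- x[r$i0, , drop = FALSE] * (1 - r$w) + x[r$i1, , drop = FALSE] * r$w
  a[, cc$i0, drop = FALSE] * rep(1 - cc$w, each = h) +
    a[, cc$i1, drop = FALSE] * rep(cc$w, each = h)
}

#' Read a dataset manifest
#'
#' @param csv_path CSV with header `image_id,path,label`; labels must be 0
#'   or 1 and image ids unique.  Relative image paths are resolved against
#'   the manifest's directory.
#' @return `data.frame` with columns `image_id`, `path`, `label`, row order
#'   preserved.
#' @export
read_manifest <- function(csv_path) {
  m <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("image_id", "path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns image_id,path,label", call. = FALSE)
  m <- m[, need]
  m$image_id <- as.character(m$image_id)
  m$path <- as.character(m$path)
  bad <- which(!(m$label %in% c(0, 1)))
  if (length(bad))
    stop("manifest row ", bad[1], ": label must be 0 or 1, got '",
         m$label[bad[1]], "'", call. = FALSE)
  dup <- which(duplicated(m$image_id))
  if (length(dup))
    stop("manifest row ", dup[1], ": duplicate image_id '",
         m$image_id[dup[1]], "'", call. = FALSE)
  m$label <- as.integer(m$label)
  rel <- !file.exists(m$path) & !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(csv_path), m$path[rel])
  m
}

#' Read ground-truth boxes
#'
#' @param csv_path CSV with columns
#'   `image_id,x_min,y_min,x_max,y_max` (0-based half-open); one row per
#'   image.
#' @return named list mapping `image_id` to [bounding_box()].
#' @export
read_boxes <- function(csv_path) {
  b <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(b)))
    stop("boxes file must have columns image_id,x_min,y_min,x_max,y_max",
         call. = FALSE)
  b$image_id <- as.character(b$image_id)
  for (cc in need[-1]) b[[cc]] <- as.numeric(b[[cc]])
  dup <- which(duplicated(b$image_id))
  if (length(dup))
    stop("boxes row ", dup[1], ": duplicate image_id '", b$image_id[dup[1]],
         "'", call. = FALSE)
  out <- vector("list", nrow(b))
  names(out) <- b$image_id
  for (i in seq_len(nrow(b)))
    out[[i]] <- tryCatch(
      bounding_box(b$x_min[i], b$y_min[i], b$x_max[i], b$y_max[i]),
      error = function(e) stop("boxes row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  out
}

#' Write detection records
#'
#' One JSON object per line with fields `image_id`, `score` and `box`
#' (`null` when no box was predicted); losslessly re-readable with
#' [read_detections()].
#'
#' @param records list of detection records (as returned by [detect()]).
#' @param path output file.
#' @export
write_detections <- function(records, path) {
  lines <- vapply(records, function(r) {
    box <- if (is.null(r$box)) NULL else
      list(x_min = r$box$x_min, y_min = r$box$y_min,
           x_max = r$box$x_max, y_max = r$box$y_max)
    jsonlite::toJSON(list(image_id = r$image_id, score = r$score, box = box),
                     auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write detections to ", path, call. = FALSE)
  invisible(path)
}

#' Read detection records
#'
#' @param path JSON-lines file written by [write_detections()].
#' @return list of detection records.
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    box <- if (is.null(x$box)) NULL else
      bounding_box(x$box$x_min, x$box$y_min, x$box$x_max, x$box$y_max)
    detection_record(x$image_id, x$score, box)
  })
}

detection_record <- function(image_id, score, box = NULL) {
  if (!is.finite(score) || score < 0 || score > 1)
    stop("detection score must be in [0, 1]", call. = FALSE)
  structure(list(image_id = image_id, score = score, box = box),
            class = "detection_record")
}
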