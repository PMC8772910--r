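#' Read a pseudo-color image
#'
#' Reads an 8-bit-per-channel raster image into a pseudocolor image object:
#' a list of three integer matrices `r`, `g`, `b` in 0..255 (row-major,
#' rows = image height). PNG is read natively; JPEG and TIFF are read through
#' EBImage when it is installed. Any alpha channel is discarded; grayscale
#' images are expanded to R = G = B.
#'
#' @param path path to a PNG/JPEG/TIFF file.
#' @return object of class `pseudocolor_image`: list with integer matrices
#'   `r`, `g`, `b` and dimensions `height` x `width`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading ", ext, " requires the EBImage package: ", path)
    }
    img <- EBImage::readImage(path)
    # EBImage stores x,y (width, height); transpose to row = image row
    arr <- aperm(EBImage::imageData(img), if (length(dim(img)) == 3) c(2, 1, 3) else c(2, 1))
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  pseudocolor_from_array(arr)
}

pseudocolor_from_array <- function(arr) {
  to_plane <- function(m) {
    storage.mode(m) <- "integer"
    m
  }
  if (length(dim(arr)) == 2) {
    plane <- to_plane(round(arr * 255))
    planes <- list(r = plane, g = plane, b = plane)
  } else {
    planes <- list(
      r = to_plane(round(arr[, , 1] * 255)),
      g = to_plane(round(arr[, , 2] * 255)),
      b = to_plane(round(arr[, , 3] * 255))
    )
  }
  structure(planes, class = "pseudocolor_image")
}

#' Assemble a pseudocolor image from three channel matrices
#'
#' @param r,g,b integer matrices in 0..255 with identical dimensions.
#' @return a `pseudocolor_image`.
#' @export
pseudocolor_image <- function(r, g, b) {
  stopifnot(identical(dim(r), dim(g)), identical(dim(r), dim(b)))
  planes <- lapply(list(r = r, g = g, b = b), function(m) {
    m <- as.matrix(m)
    if (any(m < 0 | m > 255)) stop("channel values must lie in 0..255")
    storage.mode(m) <- "integer"
    m
  })
  structure(planes, class = "pseudocolor_image")
}

#' @export
dim.pseudocolor_image <- function(x) dim(x$r)

#' Write a pseudocolor image to PNG
#'
#' @param image a `pseudocolor_image`.
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  arr <- array(0, c(dim(image$r), 3))
  arr[, , 1] <- image$r / 255
  arr[, , 2] <- image$g / 255
  arr[, , 3] <- image$b / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read / write a temperature field
#'
#' A temperature field is a plain numeric matrix of surface temperatures in
#' degrees Celsius, stored on disk as a headerless CSV grid (one image row per
#' line). Ragged rows or non-numeric cells raise a parse error naming the
#' offending row.
#'
#' @param path path to a CSV matrix.
#' @return numeric matrix of temperatures (degC).
#' @export
read_temperature_field <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty temperature field file: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[[i]], ",")[[1]]))
    if (anyNA(v)) stop("non-numeric cell in temperature field row ", i, ": ", path)
    v
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    stop("ragged temperature field at row ", which(ncols != ncols[1])[1], ": ", path)
  }
  do.call(rbind, rows)
}

#' @rdname read_temperature_field
#' @param field numeric matrix (degC).
#' @export
write_temperature_field <- function(field, path) {
  utils::write.table(field, path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Decompose a pseudo-color image into R, G, B component planes
#'
#' Each plane carries exactly one color channel, unmodified, as an 8-bit
#' grayscale image; texture analysis operates on these planes.
#'
#' @param image a `pseudocolor_image`.
#' @return named list of integer matrices `R`, `G`, `B`.
#' @export
decompose_components <- function(image) {
  stopifnot(inherits(image, "pseudocolor_image"))
  list(R = image$r, G = image$g, B = image$b)
}

#' ROI masks
#'
#' An ROI mask is a logical matrix aligned with the image, `TRUE` for member
#' pixels, with a numeric label (1-4) and an anatomical name. `roi_rect`
#' builds an axis-aligned rectangular mask from inclusive pixel bounds
#' (1-based row/col); `roi_mask` wraps an arbitrary logical matrix.
#'
#' @param membership logical matrix, at least one `TRUE`.
#' @param label ROI label, 1-4 in the study layout.
#' @param name anatomical name.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(membership, label = 1L, name = "") {
  membership <- as.matrix(membership)
  mode(membership) <- "logical"
  if (!any(membership)) stop("ROI mask has no member pixels")
  structure(
    list(membership = membership, label = as.integer(label), name = name),
    class = "roi_mask"
  )
}

#' @rdname roi_mask
#' @param nrow,ncol image dimensions.
#' @param rows,cols inclusive 1-based pixel index ranges (length-2 vectors).
#' @export
roi_rect <- function(nrow, ncol, rows, cols, label = 1L, name = "") {
  m <- matrix(FALSE, nrow, ncol)
  m[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  roi_mask(m, label, name)
}

#' Extract ROI member pixels
#'
#' Returns the member-pixel values of a component plane or temperature field,
#' together with a masked 2-D view in which non-member pixels are `NA` (never
#' zero, so fill values cannot leak into statistics).
#'
#' @param x numeric/integer matrix (component plane or temperature field).
#' @param mask a `roi_mask` with matching dimensions.
#' @return list with `values` (vector of member pixels, column-major order)
#'   and `view` (matrix with non-members set to `NA`).
#' @export
extract_roi_pixels <- function(x, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(x), dim(mask$membership))) {
    stop("mask dimensions do not match image dimensions")
  }
  view <- x
  view[!mask$membership] <- NA
  list(values = x[mask$membership], view = view)
}

#' Conventional thermal features of an ROI
#'
#' The three features returned by conventional thermographic software for a
#' region: average (Taver), maximal (Tmax) and minimal (Tmin) temperature in
#' degrees Celsius. Taver is the plain arithmetic mean over member pixels.
#'
#' @param field numeric temperature matrix (degC).
#' @param mask a `roi_mask`.
#' @return named numeric vector `c(Taver=, Tmax=, Tmin=)`.
#' @export
conventional_features <- function(field, mask) {
  v <- extract_roi_pixels(field, mask)$values
  c(Taver = mean(v), Tmax = max(v), Tmin = min(v))
}

#' Read / write ROI mask geometry as JSON
#'
#' Masks are serialised as a list of rectangles (label, name, row/col bounds),
#' the format emitted by the synthetic-study generator.
#'
#' @param masks list of `roi_mask` objects built by [roi_rect()].
#' @param path JSON path.
#' @param nrow,ncol image dimensions used to rasterise on read.
#' @return `read_roi_masks` returns a named list of `roi_mask`.
#' @export
write_roi_masks <- function(masks, path) {
  geom <- lapply(masks, function(m) {
    rr <- range(which(apply(m$membership, 1, any)))
    cc <- range(which(apply(m$membership, 2, any)))
    list(label = m$label, name = m$name, rows = rr, cols = cc)
  })
  jsonlite::write_json(geom, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_masks
#' @export
read_roi_masks <- function(path, nrow, ncol) {
  geom <- jsonlite::read_json(path)
  masks <- lapply(geom, function(g) {
    roi_rect(nrow, ncol,
      rows = unlist(g$rows), cols = unlist(g$cols),
      label = g$label, name = g$name
    )
  })
  names(masks) <- paste0("ROI", vapply(masks, `[[`, integer(1), "label"))
  masks
}
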