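# File I/O: 8-bit PNG/TIFF images, 16-bit label maps, multi-page truth
# masks, plain key=value configuration files.

#' Read an 8-bit RGB or grayscale image
#'
#' PNG and TIFF are supported (chosen by extension). Grayscale files come
#' back as a matrix, color files as an `H x W x 3` array; an alpha channel,
#' if present, is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Matrix or array of intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  img <- round(raw * 255)
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L) {
    img[, , 1:3, drop = FALSE]
  } else if (length(d) == 3L) {
    img[, , 1, drop = TRUE]
  } else {
    img
  }
}

#' Write an image as 8-bit PNG
#'
#' @param img Matrix or `H x W x 3` array of intensities in `[0, 255]`.
#' @param path Output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Write a label map as 16-bit TIFF
#'
#' Labels are stored as 16-bit gray values so up to 65535 cells per image
#' round-trip exactly.
#'
#' @param labels Integer label matrix.
#' @param path Output path.
#' @export
write_labels_tiff <- function(labels, path) {
  assert_labels(labels)
  if (max(labels) > 65535) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit label map written by [write_labels_tiff()]
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write ground-truth cell masks as a multi-page TIFF
#'
#' One binary page per cell; an image with no cells produces a single
#' empty page so the file always exists.
#'
#' @param truth List of cell masks (index vectors with a `dim_full`
#'   attribute, or logical matrices).
#' @param dims Canvas dimensions `c(H, W)` (required when `truth` is
#'   empty).
#' @param path Output path.
#' @export
write_truth_tiff <- function(truth, path, dims = NULL) {
  pages <- lapply(truth, function(m) {
    idx <- truth_indices(m)
    d <- attr(idx, "dim_full")
    pg <- matrix(0, d[1], d[2])
    pg[as.integer(idx)] <- 1
    pg
  })
  if (length(pages) == 0) {
    if (is.null(dims)) stop("`dims` required for empty truth", call. = FALSE)
    pages <- list(matrix(0, dims[1], dims[2]))
    attr(pages, "empty") <- TRUE
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read ground-truth cell masks from a multi-page TIFF
#'
#' @param path TIFF path written by [write_truth_tiff()].
#' @return List of index-vector masks; a single all-zero page is read as
#'   an empty list (a control image).
#' @export
read_truth_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  masks <- lapply(pages, function(p) {
    structure(which(p > 0.5), dim_full = dim(p))
  })
  masks <- Filter(function(m) length(m) > 0, masks)
  masks
}

#' Write / read a pipeline configuration as plain key=value text
#'
#' @param config A [pipeline_config()].
#' @param path Text file path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns a `pipeline_config` that round-trips exactly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fmt <- function(v) {
    if (is.logical(v)) {
      if (v) "true" else "false"
    } else {
      paste(format(v, digits = 15, scientific = FALSE), collapse = ",")
    }
  }
  lines <- vapply(names(config),
                  function(nm) paste0(nm, " = ", fmt(config[[nm]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  parse_val <- function(v) {
    if (v %in% c("true", "false")) return(v == "true")
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) v else num
  }
  args <- stats::setNames(lapply(vals, parse_val), keys)
  do.call(pipeline_config, args[names(args) %in%
                                  names(formals(pipeline_config))])
}
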