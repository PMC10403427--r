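#' @include AllClasses.R AllGenerics.R
NULL

#' Read a serial-section stack
#'
#' Sections are ordered by page index (multipage TIFF) or by lexicographic
#' filename (image sequence); intensities are normalised so that the storage
#' dtype's full range maps onto [0, 1] (the r-tiff/r-png readers already
#' return this normalisation for integer data).
#'
#' @param path file (multipage TIFF) or directory (image sequence).
#' @param format one of "tiff_multipage", "image_sequence". The "hdf5"
#'   volume layout is recognised but not supported by this build.
#' @param pixelSizeNm,thicknessNm optional metadata attached to the stack.
#' @return A \linkS4class{SectionStack}.
#' @export
readStack <- function(path, format = c("tiff_multipage", "image_sequence",
                                       "hdf5"),
                      pixelSizeNm = c(NA_real_, NA_real_),
                      thicknessNm = NA_real_) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 volumes are not supported by this build; ",
         "convert the dataset to a multipage TIFF or an image sequence")
  if (!file.exists(path))
    stop("path does not exist: ", path)
  pages <- switch(format,
    tiff_multipage = {
      p <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
      if (!is.list(p)) p <- list(p)
      lapply(p, .asGray)
    },
    image_sequence = {
      files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (length(files) == 0L)
        stop("no PNG/TIFF files found in ", path)
      .checkPadding(basename(files))
      files <- files[order(basename(files))]
      lapply(files, function(f) {
        if (grepl("\\.png$", f, ignore.case = TRUE))
          .asGray(png::readPNG(f))
        else .asGray(tiff::readTIFF(f, as.is = FALSE))
      })
    })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(m) identical(dim(m), shp), logical(1))))
    stop("ragged shapes across sections")
  SectionStack(pages, pixelSizeNm = pixelSizeNm, thicknessNm = thicknessNm)
}

# collapse an RGB(A) plane to gray, pass matrices through
.asGray <- function(x) {
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3L, dim(x)[3]), drop = FALSE],
                                       c(1, 2), mean)
  if (length(dim(x)) != 2L) stop("sections must be 2-D grayscale images")
  x
}

# numeric file stems must be zero-padded to one width; guessed ordering of
# unpadded names ("2.png" after "10.png") is an error, not a heuristic
.checkPadding <- function(names) {
  stems <- sub("\\.[^.]+$", "", names)
  num <- grepl("[0-9]+$", stems)
  if (!any(num)) return(invisible(TRUE))
  digits <- nchar(sub("^.*?([0-9]+)$", "\\1", stems[num]))
  if (length(unique(digits)) > 1L)
    stop("image-sequence filenames have numeric suffixes of unequal width; ",
         "zero-pad them so lexicographic order equals numeric order")
  invisible(TRUE)
}

#' Write a serial-section stack
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param path output file (multipage TIFF) or directory (image sequence).
#' @param format "tiff_multipage" or "image_sequence".
#' @param bitsPerSample 8 or 16 for integer storage (quantised), 32 for
#'   lossless float storage (TIFF only).
#' @return Invisibly, the written path.
#' @export
writeStack <- function(stack, path, format = c("tiff_multipage",
                                               "image_sequence"),
                       bitsPerSample = 32L) {
  format <- match.arg(format)
  n <- nSections(stack)
  if (n < 1L) stop("empty stack")
  secs <- lapply(seq_len(n), function(i) section(stack, i))
  if (format == "tiff_multipage") {
    tiff::writeTIFF(secs, path, bits.per.sample = as.integer(bitsPerSample),
                    reduce = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    width <- max(4L, nchar(as.character(n)))
    for (i in seq_len(n)) {
      f <- file.path(path, sprintf(paste0("section_%0", width, "d.tif"), i))
      tiff::writeTIFF(secs[[i]], f,
                      bits.per.sample = as.integer(bitsPerSample),
                      reduce = FALSE)
    }
  }
  invisible(path)
}

#' Read / write integer label stacks as multipage 16-bit TIFF
#'
#' @param path multipage TIFF path.
#' @return \code{readLabels}: a \linkS4class{LabelStack}.
#' @export
readLabels <- function(path) {
  p <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(p)) p <- list(p)
  LabelStack(lapply(p, function(m) {
    storage.mode(m) <- "integer"
    m
  }))
}

#' @rdname readLabels
#' @param labels a \linkS4class{LabelStack} with ids below 65536.
#' @export
writeLabels <- function(labels, path) {
  mx <- max(labels@data)
  if (mx > 65535L) stop("label ids exceed 16-bit storage")
  secs <- lapply(seq_len(nSections(labels)),
                 function(i) section(labels, i) / 65535)
  tiff::writeTIFF(secs, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Centre-crop every section of a stack
#'
#' Cropping is symmetric about the image centre; an odd remainder leaves the
#' extra pixel on the leading (low-index) side, i.e. the leading offset is
#' floor((in - out) / 2).
#'
#' @param stack a \linkS4class{SectionStack} or \linkS4class{LabelStack}.
#' @param size integer(2) target (rows, cols).
#' @return The cropped stack of the same class.
#' @export
centerCrop <- function(stack, size) {
  d <- stackShape(stack)
  if (any(size > d)) stop("crop size exceeds section shape")
  oy <- (d[1] - size[1]) %/% 2L
  ox <- (d[2] - size[2]) %/% 2L
  sub <- stackData(stack)[oy + seq_len(size[1]), ox + seq_len(size[2]), ,
                          drop = FALSE]
  if (is(stack, "LabelStack")) LabelStack(sub)
  else SectionStack(sub, pixelSizeNm = stack@pixelSizeNm,
                    thicknessNm = stack@thicknessNm)
}
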