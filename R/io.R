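#' Write an image to a portable greymap (PGM) file
#'
#' Values in \[0, 1\] are scaled to \code{maxval} and written either as
#' binary (P5, the default) or plain-text (P2) PGM.
#'
#' @param img Square numeric matrix with values in \[0, 1\].
#' @param path Output file path.
#' @param ascii Write the plain-text P2 variant instead of binary P5.
#' @param maxval Maximum grey value (at most 255; 8-bit samples).
#' @return \code{path}, invisibly.
#' @export
write_pgm <- function(img, path, ascii = FALSE, maxval = 255L) {
  if (any(img < 0 | img > 1)) stop("image values must lie in [0, 1]")
  if (maxval < 1L || maxval > 255L) stop("maxval must be in 1..255")
  vals <- round(t(unclass(img)) * maxval)  # row-major raster order
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
                 as.character(maxval)), con)
    write(as.integer(vals), con, ncolumns = 16L)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval),
              con, eos = NULL)
    writeBin(as.raw(as.integer(vals)), con)
  }
  invisible(path)
}

#' Read a PGM (P2 or P5) file as an image grid
#'
#' @param path File path.
#' @return Numeric matrix of class \code{image_grid} with values in \[0, 1\].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file: ", path)
  toks <- character(0)
  while (length(toks) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (grepl("[[:space:]]", ch)) next
    if (ch == "#") { # comment line
      repeat { ch <- readChar(con, 1L); if (!length(ch) || ch == "\n") break }
      next
    }
    tok <- ch
    repeat {
      ch <- readChar(con, 1L)
      if (!length(ch) || grepl("[[:space:]]", ch)) break
      tok <- paste0(tok, ch)
    }
    toks <- c(toks, tok)
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2]); mx <- as.integer(toks[3])
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  m <- t(matrix(vals, nrow = w, ncol = h)) / mx
  structure(m, class = c("image_grid", class(m)))
}

#' Write a sinogram as delimited text
#'
#' The format is a comma-delimited \code{t_b x M} matrix (one column per
#' view) preceded by a header line \code{# angles_deg: a1,a2,...} recording
#' the ordered view angles in degrees.
#'
#' @param sino A [sinogram] object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# angles_deg: %s",
                     paste(format(sino$geometry$angles * 180 / pi,
                                  digits = 12, trim = TRUE), collapse = ",")),
             con)
  write.table(sino$values, con, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path File path.
#' @param side Side length of the image grid the sinogram belongs to
#'   (needed to rebuild the projection geometry).
#' @return A [sinogram] object.
#' @export
read_sinogram <- function(path, side) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# angles_deg:", header))
    stop("missing '# angles_deg:' header in ", path)
  angles <- as.numeric(strsplit(sub("^# angles_deg:\\s*", "", header),
                                ",")[[1]]) * pi / 180
  vals <- as.matrix(read.csv(path, header = FALSE, skip = 1L,
                             colClasses = "numeric"))
  dimnames(vals) <- NULL
  geom <- projection_geometry(side, n_views = length(angles),
                              n_bins = nrow(vals))
  geom$angles <- angles
  new_sinogram(vals, geom)
}

#' Read/write a square image as comma-delimited text
#'
#' @param img Square numeric matrix.
#' @param path File path.
#' @return \code{write_image_csv}: \code{path}, invisibly;
#'   \code{read_image_csv}: an \code{image_grid} matrix.
#' @export
write_image_csv <- function(img, path) {
  write.table(unclass(img), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE, colClasses = "numeric"))
  dimnames(m) <- NULL
  structure(m, class = c("image_grid", class(m)))
}
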