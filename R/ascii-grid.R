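#' Read an ESRI ASCII grid
#'
#' Parses the plain-text `.asc` raster interchange format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by `nrows` whitespace-separated rows ordered north to south.
#' Cells equal to the declared nodata value become `NA`.
#'
#' @param path file to read.
#' @return A list with `data` (numeric matrix, row 1 = northernmost),
#'   `cellsize` (metres), `xllcorner`, `yllcorner`, `nodata_value`.
#' @seealso [write_ascii_grid()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("not an ESRI ASCII grid: fewer than 6 lines", call. = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stop(sprintf("ASCII grid header missing '%s'", key), call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop_dimension(sprintf("expected %d cells, found %d", nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(
    data = m,
    cellsize = hdr$cellsize,
    xllcorner = hdr[["xllcorner"]] %||% 0,
    yllcorner = hdr[["yllcorner"]] %||% 0,
    nodata_value = nodata
  )
}

#' Write an ESRI ASCII grid
#'
#' @param data numeric matrix (row 1 = northernmost row); `NA` cells are
#'   written as the nodata value.
#' @param path output file.
#' @param cellsize cell edge length in metres.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata_value sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(data, path, cellsize = 30, xllcorner = 0,
                             yllcorner = 0, nodata_value = -9999) {
  stopifnot(is.matrix(data))
  m <- data
  m[is.na(m)] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xllcorner),
    sprintf("yllcorner %.10g", yllcorner),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
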