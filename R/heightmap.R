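#' AFM height map container
#'
#' A rectangular grid of surface heights in nm with a pixel size. Heights are
#' stored row-major with the origin at the top-left pixel; pixel (r, c) has
#' its centre at x = (c - 0.5) * pixel_size, y = (r - 0.5) * pixel_size.
#'
#' @param heights numeric matrix of heights in nm (finite).
#' @param pixel_size_nm pixel edge length in nm, positive.
#' @param metadata free-form named list (scan info, generator config, seed).
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_nm, metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("heights must be a numeric matrix")
  if (!all(is.finite(heights))) stop("all heights must be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number")
  structure(list(heights = heights, pixel_size_nm = pixel_size_nm,
                 metadata = metadata),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("AFM height map: %d x %d pixels, %.4g nm/pixel (%.4g x %.4g nm)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_nm,
              ncol(x$heights) * x$pixel_size_nm,
              nrow(x$heights) * x$pixel_size_nm))
  cat(sprintf("  height range [%.4g, %.4g] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
dim.height_map <- function(x) dim(x$heights)

#' Write an AFM height map
#'
#' Two plain formats are supported. `ascii_grid`: '#'-prefixed header lines
#' (`rows`, `cols`, `pixel_size_nm`, `units: nm`) followed by
#' whitespace-separated rows at >= 9 significant digits. `float_tiff`:
#' a 32-bit float TIFF holding min-max-normalised heights, with the affine
#' transform back to nm (`height_offset_nm`, `height_scale_nm`), the pixel
#' size and any metadata in a JSON sidecar at `<path>.json`.
#'
#' @param map a [height_map()].
#' @param path output path.
#' @param format `"ascii_grid"` or `"float_tiff"`.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(map, path, format = c("ascii_grid", "float_tiff")) {
  stopifnot(inherits(map, "height_map"))
  format <- match.arg(format)
  h <- map$heights
  if (format == "ascii_grid") {
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error")) stop("cannot open ", path, " for writing")
    on.exit(close(con))
    writeLines(c(sprintf("# rows: %d", nrow(h)),
                 sprintf("# cols: %d", ncol(h)),
                 sprintf("# pixel_size_nm: %.10g", map$pixel_size_nm),
                 "# units: nm"), con)
    writeLines(apply(h, 1L, function(r)
      paste(sprintf("%.9g", r), collapse = " ")), con)
  } else {
    off <- min(h)
    scl <- max(h) - off
    if (scl == 0) scl <- 1
    suppressWarnings(
      tiff::writeTIFF((h - off) / scl, path, bits.per.sample = 32L,
                      compression = "none", reduce = FALSE))
    sidecar <- list(rows = nrow(h), cols = ncol(h),
                    pixel_size_nm = map$pixel_size_nm, units = "nm",
                    height_offset_nm = off, height_scale_nm = scl,
                    metadata = map$metadata)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read an AFM height map
#'
#' @param path file path (for `float_tiff`, the sidecar `<path>.json` must
#'   exist).
#' @param format `"ascii_grid"` or `"float_tiff"`; default guesses from the
#'   file extension (`.tif`/`.tiff` versus anything else).
#' @return A [height_map()].
#' @export
read_height_map <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "float_tiff" else "ascii_grid"
  }
  format <- match.arg(format, c("ascii_grid", "float_tiff"))
  if (format == "ascii_grid") read_ascii_grid(path) else read_float_tiff(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty height-map file: ", path)
  is_hdr <- grepl("^\\s*#", lines)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  kv <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", l))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  if (is.null(kv$pixel_size_nm))
    stop("ASCII grid header missing pixel_size_nm")
  if (is.null(kv$units) || kv$units != "nm")
    stop("ASCII grid header must declare 'units: nm'")
  px <- as.numeric(kv$pixel_size_nm)
  rows <- strsplit(trimws(body), "\\s+")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("non-rectangular grid: row ", which(lens != lens[1])[1],
         " has ", lens[which(lens != lens[1])[1]], " values, expected ",
         lens[1])
  if (!is.null(kv$rows) && as.integer(kv$rows) != length(rows))
    stop("header declares ", kv$rows, " rows but body has ", length(rows))
  if (!is.null(kv$cols) && as.integer(kv$cols) != lens[1])
    stop("header declares ", kv$cols, " cols but rows have ", lens[1])
  h <- do.call(rbind, lapply(rows, as.numeric))
  if (any(!is.finite(h))) stop("non-numeric or non-finite height values")
  height_map(h, px, metadata = list(source = path))
}

read_float_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing JSON sidecar (pixel size): ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$pixel_size_nm)) stop("sidecar missing pixel_size_nm")
  h <- tiff::readTIFF(path)
  if (is.array(h) && length(dim(h)) == 3L) h <- h[, , 1L]
  off <- sc$height_offset_nm %||% 0
  scl <- sc$height_scale_nm %||% 1
  height_map(h * scl + off, sc$pixel_size_nm,
             metadata = c(list(source = path),
                          as.list(sc$metadata %||% list())))
}
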