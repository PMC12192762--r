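#' Environmental raster grid
#'
#' An `env_grid` is a single raster layer in ESRI ASCII grid geometry:
#' an `nrows x ncols` numeric matrix stored north-to-south (row 1 is the
#' northernmost row, exactly as an `.asc` file lists it), plus the
#' lower-left corner, the square cell size and the nodata sentinel.
#' Masked (nodata) cells are held as `NA` internally and written back as
#' the sentinel.
#'
#' The centre of cell `(r, c)` (1-based, row 1 = north) is
#' `x = xllcorner + (c - 0.5) * cellsize`,
#' `y = yllcorner + (nrows - r + 0.5) * cellsize`.
#'
#' @param values numeric matrix, north-first row order; `NA` marks nodata.
#' @param xllcorner,yllcorner coordinates of the outer corner of the
#'   lower-left cell, in degrees (geographic) or map units (planar).
#' @param cellsize positive cell edge length.
#' @param nodata_value sentinel written for masked cells (default -9999).
#' @return object of class `env_grid`.
#' @export
env_grid <- function(values, xllcorner, yllcorner, cellsize,
                     nodata_value = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("`cellsize` must be > 0")
  if (!is.finite(xllcorner) || !is.finite(yllcorner))
    stop("corner coordinates must be finite")
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad))
    stop("grid contains non-finite values that are not the nodata sentinel")
  structure(
    list(values = values,
         nrows = nrow(values), ncols = ncol(values),
         xllcorner = as.numeric(xllcorner),
         yllcorner = as.numeric(yllcorner),
         cellsize = as.numeric(cellsize),
         nodata_value = as.numeric(nodata_value)),
    class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d rows x %d cols, cellsize %g, ll = (%g, %g), %d nodata cells\n",
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.env_grid <- function(x) c(x$nrows, x$ncols)

# x/y coordinates of every cell centre, as matrices matching `values`.
cell_center_coords <- function(grid) {
  cx <- grid$xllcorner + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  cy <- grid$yllcorner + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  list(x = matrix(cx, grid$nrows, grid$ncols, byrow = TRUE),
       y = matrix(cy, grid$nrows, grid$ncols))
}

# Map lon/lat points to 1-based (row, col); NA when outside the grid.
locate_cells <- function(grid, x, y) {
  col <- floor((x - grid$xllcorner) / grid$cellsize) + 1
  row_s <- floor((y - grid$yllcorner) / grid$cellsize) + 1  # from south
  row <- grid$nrows - row_s + 1
  out <- col < 1 | col > grid$ncols | row < 1 | row > grid$nrows |
    !is.finite(col) | !is.finite(row)
  col[out] <- NA_integer_; row[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

header_num <- function(lines, key, alt = NULL, file = "<text>") {
  keys <- tolower(sub("^\\s*(\\S+).*$", "\\1", lines))
  i <- match(tolower(key), keys)
  j <- if (!is.null(alt)) match(tolower(alt), keys) else NA_integer_
  if (is.na(i) && is.na(j)) return(NULL)
  k <- if (!is.na(i)) i else j
  val <- suppressWarnings(as.numeric(sub("^\\s*\\S+\\s+(\\S+).*$", "\\1", lines[k])))
  if (is.na(val))
    stop(sprintf("malformed ESRI ASCII header in %s: cannot parse line %d: \"%s\"",
                 file, k, lines[k]))
  list(value = val, key = keys[k], line = k)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-key ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`; case-insensitive) followed by `nrows` rows of `ncols`
#' whitespace-separated values. Both corner and centre dialects are
#' accepted on read; centre coordinates are converted to corners
#' (`xllcorner = xllcenter - cellsize / 2`). Files ending in `.gz` are
#' read through a decompressing connection.
#'
#' @param input path to an `.asc` (or `.asc.gz`) file, or a character
#'   vector holding the file's lines (or a single string with newlines).
#' @return an [env_grid()].
#' @export
read_ascii_grid <- function(input) {
  file <- "<text>"
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    file <- input
    con <- if (grepl("\\.gz$", input, ignore.case = TRUE)) gzfile(input, "rt")
           else file(input, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7)
    stop(sprintf("malformed ESRI ASCII grid in %s: fewer than 7 non-empty lines", file))
  hdr <- lines[1:6]
  ncols <- header_num(hdr, "ncols", file = file)
  nrows <- header_num(hdr, "nrows", file = file)
  xll <- header_num(hdr, "xllcorner", "xllcenter", file = file)
  yll <- header_num(hdr, "yllcorner", "yllcenter", file = file)
  cz  <- header_num(hdr, "cellsize", file = file)
  nod <- header_num(hdr, "nodata_value", file = file)
  miss <- c(ncols = is.null(ncols), nrows = is.null(nrows), xll = is.null(xll),
            yll = is.null(yll), cellsize = is.null(cz), nodata = is.null(nod))
  if (any(miss))
    stop(sprintf("malformed ESRI ASCII header in %s: missing key(s) %s; header lines were: %s",
                 file, paste(names(miss)[miss], collapse = ", "),
                 paste(sprintf("\"%s\"", hdr), collapse = " ")))
  nc <- as.integer(ncols$value); nr <- as.integer(nrows$value)
  if (nc < 1 || nr < 1)
    stop(sprintf("malformed ESRI ASCII header in %s: non-positive grid shape", file))
  xc <- xll$value; yc <- yll$value
  if (xll$key == "xllcenter") xc <- xc - cz$value / 2
  if (yll$key == "yllcenter") yc <- yc - cz$value / 2

  body <- lines[-(1:6)]
  if (length(body) != nr)
    stop(sprintf("malformed ESRI ASCII grid in %s: expected %d data rows, found %d",
                 file, nr, length(body)))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    tok <- scan(text = body[r], what = numeric(), quiet = TRUE)
    if (length(tok) != nc)
      stop(sprintf("malformed ESRI ASCII grid in %s: data row %d has %d values, expected %d",
                   file, r, length(tok), nc))
    vals[r, ] <- tok
  }
  vals[vals == nod$value] <- NA_real_
  env_grid(vals, xc, yc, cz$value, nod$value)
}

#' Write an ESRI ASCII grid
#'
#' Always writes the corner dialect; values are formatted with
#' `signif(digits)` so output is deterministic. Masked cells are written
#' as the grid's nodata sentinel. A path ending in `.gz` is compressed.
#'
#' @param grid an [env_grid()].
#' @param path optional output file; when `NULL` the text is returned.
#' @param digits significant digits for data values (default 6).
#' @return the file content as a character vector of lines, invisibly
#'   when written to a file.
#' @export
write_ascii_grid <- function(grid, path = NULL, digits = 6) {
  stopifnot(inherits(grid, "env_grid"))
  v <- grid$values
  if (any(!is.na(v) & !is.finite(v)))
    stop("refusing to write grid with non-finite, non-nodata values")
  fmt1 <- function(x) {
    out <- formatC(signif(x, digits), format = "g", digits = digits, width = 1)
    trimws(out)
  }
  header <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %s", fmt1(grid$xllcorner)),
    sprintf("yllcorner %s", fmt1(grid$yllcorner)),
    sprintf("cellsize %s", fmt1(grid$cellsize)),
    sprintf("NODATA_value %s", fmt1(grid$nodata_value)))
  vv <- v
  vv[is.na(vv)] <- grid$nodata_value
  rows <- apply(vv, 1, function(r) paste(fmt1(r), collapse = " "))
  out <- c(header, rows)
  if (is.null(path)) return(out)
  con <- if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, "wt")
         else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(out)
}

geom_fields_equal <- function(a, b, rel_tol = 1e-9) {
  if (a$nrows != b$nrows) return("nrows")
  if (a$ncols != b$ncols) return("ncols")
  releq <- function(x, y) {
    s <- max(abs(x), abs(y), 1)
    abs(x - y) <= rel_tol * s
  }
  if (!releq(a$xllcorner, b$xllcorner)) return("xllcorner")
  if (!releq(a$yllcorner, b$yllcorner)) return("yllcorner")
  if (!releq(a$cellsize, b$cellsize)) return("cellsize")
  NULL
}

#' Assemble a geometry-checked multi-layer stack
#'
#' All layers must share the same grid geometry (integer fields compared
#' exactly, floating fields to a relative tolerance of 1e-9). The
#' validity mask of the stack is the intersection of the per-layer
#' masks: a cell masked in any layer becomes `NA` in every layer.
#'
#' @param grids named list of [env_grid()] objects (names are the layer
#'   names, e.g. `"bio12"`).
#' @param crs_mode `"geographic"` (degrees; the default) or `"planar"`
#'   (map units, e.g. km).
#' @return object of class `env_stack`: a list with `layers`, `crs_mode`.
#' @export
stack_layers <- function(grids, crs_mode = c("geographic", "planar")) {
  crs_mode <- match.arg(crs_mode)
  if (length(grids) < 1) stop("need at least one layer")
  nms <- names(grids)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("every layer must be named")
  if (anyDuplicated(nms))
    stop(sprintf("duplicate layer name: %s", nms[duplicated(nms)][1]))
  for (g in grids) stopifnot(inherits(g, "env_grid"))
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    f <- geom_fields_equal(ref, grids[[i]])
    if (!is.null(f))
      stop(sprintf("geometry mismatch between layers \"%s\" and \"%s\": field %s differs",
                   nms[1], nms[i], f))
  }
  mask <- Reduce(`&`, lapply(grids, function(g) !is.na(g$values)))
  grids <- lapply(grids, function(g) { g$values[!mask] <- NA_real_; g })
  structure(list(layers = grids, crs_mode = crs_mode), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("env_stack: %d layers (%s), %d x %d, %s, %d valid cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              g$nrows, g$ncols, x$crs_mode, sum(valid_mask(x))))
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

#' @export
`[[.env_stack` <- function(x, i) x$layers[[i]]

#' Validity mask of a stack
#' @param stack an `env_stack`.
#' @return logical matrix, `TRUE` where every layer has data.
#' @export
valid_mask <- function(stack) {
  Reduce(`&`, lapply(stack$layers, function(g) !is.na(g$values)))
}

# All valid cells as a matrix (rows = cells, cols = layers) plus their
# row/col indices and centre coordinates. The cell order (column-major
# over the values matrix) is the package-wide convention.
stack_cell_table <- function(stack) {
  mask <- valid_mask(stack)
  idx <- which(mask)  # column-major
  X <- vapply(stack$layers, function(g) g$values[idx], numeric(length(idx)))
  if (length(idx) == 1) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  g <- stack$layers[[1]]
  cc <- cell_center_coords(g)
  list(X = X, idx = idx, row = ((idx - 1) %% g$nrows) + 1,
       col = ((idx - 1) %/% g$nrows) + 1,
       x = cc$x[idx], y = cc$y[idx], mask = mask, geom = g)
}

# New grid with same geometry as template, values from a full matrix.
grid_like <- function(template, values) {
  env_grid(values, template$xllcorner, template$yllcorner,
           template$cellsize, template$nodata_value)
}

#' Write every layer of a stack as .asc files
#'
#' @param stack an `env_stack`.
#' @param dir output directory (created if needed).
#' @param digits significant digits passed to [write_ascii_grid()].
#' @return invisibly, the written file paths.
#' @export
write_stack_asc <- function(stack, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(stack$layers), ".asc"))
  for (i in seq_along(paths))
    write_ascii_grid(stack$layers[[i]], paths[i], digits = digits)
  invisible(paths)
}

#' Read a directory of .asc files into a stack
#'
#' @param dir directory containing `<layer>.asc` (or `.asc.gz`) files.
#' @param layer_names optional subset/order of layers to read; default is
#'   every `.asc` file, alphabetically.
#' @param crs_mode passed to [stack_layers()].
#' @return an `env_stack`.
#' @export
read_stack_asc <- function(dir, layer_names = NULL,
                           crs_mode = c("geographic", "planar")) {
  crs_mode <- match.arg(crs_mode)
  files <- list.files(dir, pattern = "\\.asc(\\.gz)?$", full.names = TRUE)
  nms <- sub("\\.asc(\\.gz)?$", "", basename(files))
  if (!is.null(layer_names)) {
    miss <- setdiff(layer_names, nms)
    if (length(miss))
      stop(sprintf("missing raster layer(s) in %s: %s", dir,
                   paste(miss, collapse = ", ")))
    files <- files[match(layer_names, nms)]
    nms <- layer_names
  } else {
    o <- order(nms); files <- files[o]; nms <- nms[o]
  }
  grids <- lapply(files, read_ascii_grid)
  names(grids) <- nms
  stack_layers(grids, crs_mode)
}
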