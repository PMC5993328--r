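# Folding x binding fitness landscapes: nearest-neighbor interpolation of
# surviving mutants' fitness over a regular (ddG, distance) grid.

#' Build a nearest-neighbor fitness landscape grid
#'
#' Both axes are min-max normalized to [0, 1] before the nearest-neighbor
#' search (unnormalized kcal/mol vs Angstrom would let one axis dominate).
#' Each grid cell takes the fitness of the nearest data point in normalized
#' Euclidean distance; exact ties go to the lowest mutant index. Every cell
#' value is therefore the F of some input mutant.
#'
#' @param ddg,distance,f numeric vectors: ddG (kcal/mol), distance from the
#'   active site (Angstrom) and fitness of surviving mutants.
#' @param resolution grid cells per axis (default 100).
#' @return object of class `landscape_grid`: `x` (ddG axis), `y` (distance
#'   axis), `z` (resolution x resolution fitness matrix, rows = x),
#'   `nearest` (index matrix).
#' @export
build_grid <- function(ddg, distance, f, resolution = 100L) {
  ok <- is.finite(ddg) & is.finite(distance) & !is.na(f)
  ddg <- ddg[ok]; distance <- distance[ok]; f <- f[ok]
  if (length(f) < 1) stop("no usable data points", call. = FALSE)
  if (length(f) < 3) warning("fewer than 3 data points: degenerate landscape")
  rngx <- range(ddg); rngy <- range(distance)
  normx <- function(v) if (diff(rngx) == 0) rep(0.5, length(v)) else (v - rngx[1]) / diff(rngx)
  normy <- function(v) if (diff(rngy) == 0) rep(0.5, length(v)) else (v - rngy[1]) / diff(rngy)
  px <- normx(ddg); py <- normy(distance)
  x <- seq(rngx[1], rngx[2], length.out = resolution)
  y <- seq(rngy[1], rngy[2], length.out = resolution)
  gx <- normx(x); gy <- normy(y)
  z <- matrix(NA_real_, resolution, resolution)
  nearest <- matrix(NA_integer_, resolution, resolution)
  for (i in seq_len(resolution)) {
    # squared distance of all points to the whole column of cells at once
    dx2 <- (px - gx[i])^2
    for (j in seq_len(resolution)) {
      d2 <- dx2 + (py - gy[j])^2
      k <- which.min(d2) # which.min returns the first (lowest index) minimum
      nearest[i, j] <- k
      z[i, j] <- f[k]
    }
  }
  structure(list(x = x, y = y, z = z, nearest = nearest,
                 x_range = rngx, y_range = rngy, resolution = resolution,
                 normalization = "min-max per axis"),
            class = "landscape_grid")
}

#' Mean fitness in a corner region of the grid
#'
#' Helper for asserting landscape structure (e.g. the FB plateau at low ddG
#' and high distance) on grid values rather than pixels.
#'
#' @param grid a [build_grid()] result.
#' @param x_frac,y_frac fraction intervals of each axis, e.g.
#'   `c(0, 0.25)` for the low quarter.
#' @return mean of the selected cells.
#' @export
grid_region_mean <- function(grid, x_frac = c(0, 0.25), y_frac = c(0.75, 1)) {
  n <- grid$resolution
  xi <- seq(max(1, ceiling(x_frac[1] * n)), floor(max(1, x_frac[2] * n)))
  yi <- seq(max(1, ceiling(y_frac[1] * n)), floor(max(1, y_frac[2] * n)))
  mean(grid$z[xi, yi])
}

#' Render a landscape grid to an image file
#'
#' Filled contour with a colorbar. Pass a shared `zlim` to keep color scales
#' identical across a batch of environments.
#'
#' @param grid a [build_grid()] result.
#' @param path output file (`.png` or `.svg` by extension).
#' @param zlim color limits (default: grid range).
#' @param main plot title.
#' @return list with the `zlim` used (color-scale metadata), invisibly.
#' @export
render_landscape <- function(grid, path, zlim = range(grid$z), main = "") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 7, height = 6)
  else grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  graphics::filled.contour(
    grid$x, grid$y, grid$z, zlim = zlim,
    color.palette = grDevices::colorRampPalette(c("#2c7bb6", "#ffffbf", "#d7191c")),
    xlab = "ddG (kcal/mol)", ylab = "distance from active site (A)",
    main = main)
  invisible(list(zlim = zlim, path = path))
}

#' Render several grids with one shared color scale
#'
#' @param grids named list of [build_grid()] results.
#' @param dir output directory.
#' @param ext image format (`"png"` or `"svg"`).
#' @return data.frame manifest with `environment`, `path`, `zlim_lo`,
#'   `zlim_hi` (identical across the batch).
#' @export
render_landscape_batch <- function(grids, dir, ext = "png") {
  zlim <- range(unlist(lapply(grids, function(g) range(g$z))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(grids), function(nm) {
    path <- file.path(dir, paste0("landscape_", nm, ".", ext))
    render_landscape(grids[[nm]], path, zlim = zlim, main = nm)
    data.frame(environment = nm, path = path,
               zlim_lo = zlim[1], zlim_hi = zlim[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
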