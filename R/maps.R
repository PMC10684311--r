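#' Spatial scalar maps of ACh level (gKs) and DC drive
#'
#' A `spatial_map` assigns one value to each of the 500 cells of a module:
#' 400 E cells on the 20 x 20 lattice and 100 I cells on the 10 x 10
#' lattice. I-cell positions are evaluated at doubled coordinates so both
#' lattices share a single 20 x 20 spatial frame.
#'
#' @name spatial_map
NULL

new_spatial_map <- function(E, I, meta) {
  structure(list(E = E, I = I, meta = meta), class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  m <- x$meta
  if (is.null(m$centers)) {
    cat(sprintf("Homogeneous spatial map: value %g (400 E + 100 I cells)\n",
                x$E[1]))
  } else {
    cat(sprintf(
      "Hotspot spatial map: %d center(s), r = %g, range [%g, %g], steepness %g\n",
      nrow(m$centers), m$r, m$value_min, m$value_max, m$steepness))
  }
  invisible(x)
}

#' Homogeneous map
#'
#' Every cell of the module receives the same value.
#'
#' @param value the constant value (mS/cm^2 for gKs maps, uA/cm^2 for DC).
#' @return A [spatial_map] object.
#' @export
homogeneous_map <- function(value) {
  stopifnot(is.finite(value))
  new_spatial_map(rep(value, N_E), rep(value, N_I),
                  list(centers = NULL, r = NA_real_, value_min = value,
                       value_max = value, steepness = NA_real_))
}

#' Sigmoidal hotspot map
#'
#' Models a spatially localized region of high ACh release (or altered DC
#' drive): cells take `value_min` deep inside a hotspot and `value_max` far
#' from every hotspot center, with a sigmoidal transition of the given
#' `steepness` at radius `r`. For a gKs map, `value_min` is the hotspot
#' (high-ACh) conductance and `value_max` the unmodulated background. The
#' cell value is
#' \deqn{v(d) = v_{min} + (v_{max} - v_{min}) S((d - r)/w)}
#' with `S` the standard logistic function and `d` the wrapped Euclidean
#' distance to the nearest center. The amplitude-scaled form makes the
#' hotspot and background attain the two stated values; `literal = TRUE`
#' instead uses the unscaled form `value_min + S(d - r)` (span fixed at 1).
#'
#' @param centers matrix or data frame with two columns (x, y) of hotspot
#'   centers in 20 x 20 lattice coordinates.
#' @param value_min,value_max value inside / far outside the hotspot
#'   (`value_min <= value_max`).
#' @param r hotspot radius (lattice units).
#' @param steepness sigmoid slope scale (lattice units).
#' @param literal use the unscaled unit-span profile.
#' @return A [spatial_map] object.
#' @examples
#' m <- hotspot_map(cbind(10, 10), value_min = 0.6, value_max = 1.5)
#' range(m$E)
#' @export
hotspot_map <- function(centers, value_min, value_max, r = 5,
                        steepness = 1, literal = FALSE) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 1) stop("at least one hotspot center is required")
  stopifnot(ncol(centers) == 2, r > 0, steepness > 0,
            value_min <= value_max)
  val_at <- function(x, y) {
    d2 <- vapply(seq_len(nrow(centers)), function(i)
      torus_dist2(x, y, centers[i, 1], centers[i, 2], E_SIDE),
      numeric(length(x)))
    d <- sqrt(if (is.matrix(d2)) apply(d2, 1, min) else min(d2))
    s <- 1 / (1 + exp(-(d - r) / steepness))
    if (literal) value_min + s else value_min + (value_max - value_min) * s
  }
  ec <- lattice_coords(E_SIDE)
  ic <- lattice_coords(I_SIDE)
  new_spatial_map(val_at(ec$x, ec$y), val_at(2 * ic$x, 2 * ic$y),
                  list(centers = centers, r = r, value_min = value_min,
                       value_max = value_max, steepness = steepness))
}

as_spatial_map <- function(x) {
  if (inherits(x, "spatial_map")) x else homogeneous_map(x)
}

#' Hotspot map presets used by the figure protocols
#'
#' Named gKs/DC map pairs for the heterogeneous-modulation protocols. The
#' hotspot is centered at (10, 10) with radius 5 lattice units unless noted;
#' two-hotspot presets use centers (5, 5) and (15, 15). (Radius, steepness
#' and center placement are free parameters of the protocols; see the
#' package vignette.)
#'
#' @param name one of `"fig6_module2"` (gKs 0.6 hotspot in 1.5 background,
#'   DC 2.0 hotspot in 3.0 background), `"fig7_module2"` (gKs 0.2 hotspot in
#'   1.5 background, DC 3.0 everywhere), `"fig8_module2"` (same maps as
#'   `fig7_module2`; used with topographic in-degree-5 wiring), or
#'   `"fig10_two_hotspots"` (gKs 0.2 at two hotspots in 1.5 background,
#'   DC 3.0 everywhere).
#' @param r,steepness hotspot geometry (lattice units).
#' @return A list with components `gks` and `dc`, both [spatial_map]s.
#' @export
ach_preset <- function(name, r = 5, steepness = 1) {
  center <- cbind(10, 10)
  two <- rbind(c(5, 5), c(15, 15))
  switch(name,
    fig6_module2 = list(
      gks = hotspot_map(center, 0.6, 1.5, r, steepness),
      dc = hotspot_map(center, 2.0, 3.0, r, steepness)),
    fig7_module2 = list(
      gks = hotspot_map(center, 0.2, 1.5, r, steepness),
      dc = homogeneous_map(3.0)),
    fig8_module2 = list(
      gks = hotspot_map(center, 0.2, 1.5, r, steepness),
      dc = homogeneous_map(3.0)),
    fig10_two_hotspots = list(
      gks = hotspot_map(two, 0.2, 1.5, r, steepness),
      dc = homogeneous_map(3.0)),
    stop("unknown preset: ", name)
  )
}

#' Write / read a spatial map as CSV grids with a JSON sidecar
#'
#' The E-lattice values are written as a 20 x 20 CSV grid (rows = x,
#' columns = y) and the I-lattice values as a 10 x 10 grid in a second
#' file (suffix `_I`); hotspot metadata goes to a `.json` sidecar.
#'
#' @param map a [spatial_map].
#' @param path base path of the E-grid CSV; the I grid and JSON sidecar
#'   derive their names from it.
#' @return `read_spatial_map` returns the reconstructed [spatial_map].
#' @export
write_spatial_map <- function(map, path) {
  e_grid <- matrix(map$E, nrow = E_SIDE, byrow = TRUE)
  i_grid <- matrix(map$I, nrow = I_SIDE, byrow = TRUE)
  write.table(e_grid, path, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(i_grid, sub("\\.csv$", "_I.csv", path), sep = ",",
              row.names = FALSE, col.names = FALSE)
  meta <- map$meta
  if (!is.null(meta$centers)) meta$centers <- unname(as.matrix(meta$centers))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spatial_map
#' @export
read_spatial_map <- function(path) {
  e_grid <- as.matrix(read.table(path, sep = ","))
  i_grid <- as.matrix(read.table(sub("\\.csv$", "_I.csv", path), sep = ","))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  if (!is.null(meta$centers)) meta$centers <- matrix(meta$centers, ncol = 2)
  new_spatial_map(as.numeric(t(e_grid)), as.numeric(t(i_grid)), meta)
}
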