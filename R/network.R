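#' @useDynLib achnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois runif
#' @importFrom utils read.table write.table
NULL

# Lattice conventions ---------------------------------------------------
#
# Each module holds 400 excitatory (E) cells on a 20 x 20 lattice and 100
# inhibitory (I) cells on a 10 x 10 lattice (20% inhibitory). Lattice
# coordinates are 0-based (x, y in [0, L-1]); the local 1-based cell id
# within a module is x*L + y + 1 for E cells and 400 + x*10 + y + 1 for I
# cells. Periodic boundary conditions make both lattices tori.

E_SIDE <- 20L
I_SIDE <- 10L
N_E <- 400L
N_I <- 100L
N_MOD <- 500L

lattice_coords <- function(L) {
  # local id = x*L + y + 1 (column y varies fastest)
  data.frame(x = rep(0:(L - 1), each = L), y = rep(0:(L - 1), times = L))
}

#' Squared wrapped (toroidal) Euclidean distance between lattice points
#'
#' @param px,py query position (may be fractional, e.g. overlay positions).
#' @param qx,qy candidate positions (vectorized).
#' @param L lattice side length; coordinates wrap modulo `L`.
#' @return Numeric vector of squared distances.
#' @export
torus_dist2 <- function(px, py, qx, qy, L) {
  dx <- abs(px - qx)
  dx <- pmin(dx, L - dx)
  dy <- abs(py - qy)
  dy <- pmin(dy, L - dy)
  dx^2 + dy^2
}

# k candidates minimizing wrapped distance to (px, py); ties at the cut
# radius are broken uniformly at random using R's RNG stream.
nearest_on_torus <- function(px, py, cand_x, cand_y, L, k) {
  if (k > length(cand_x))
    stop("k = ", k, " exceeds the number of candidate cells")
  d2 <- round(torus_dist2(px, py, cand_x, cand_y, L), 9)
  dcut <- sort(d2, partial = k)[k]
  sure <- which(d2 < dcut)
  tied <- which(d2 == dcut)
  need <- k - length(sure)
  if (need < length(tied))
    tied <- tied[sample.int(length(tied), need)]
  c(sure, tied)
}

#' Nearest lattice cells under periodic boundary conditions
#'
#' Returns the `k` cells of an `L` x `L` lattice closest (wrapped Euclidean
#' distance) to the cell at `(x, y)`, excluding that cell itself. When the
#' cut falls inside a shell of equidistant cells, the required number is
#' selected from the shell uniformly at random.
#'
#' @param x,y 0-based lattice coordinates of the center cell.
#' @param L lattice side length.
#' @param k number of neighbours (1 <= k <= L^2 - 1).
#' @return A data frame with columns `x`, `y` of the selected cells.
#' @examples
#' set.seed(1)
#' periodic_nearest(0, 0, L = 20, k = 4)  # the four axis neighbours, wrapped
#' @export
periodic_nearest <- function(x, y, L, k) {
  if (k < 1 || k > L^2 - 1)
    stop("k must be in [1, L^2 - 1]")
  cc <- lattice_coords(L)
  keep <- !(cc$x == x & cc$y == y)
  cc <- cc[keep, , drop = FALSE]
  idx <- nearest_on_torus(x, y, cc$x, cc$y, L, k)
  out <- cc[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the fixed intra-module wiring of one E-I module
#'
#' Local excitation, global inhibition: each E cell projects to its 40
#' nearest neighbours on the E lattice (weight 0.01 mS/cm^2) and, via
#' overlay of the 20 x 20 E lattice onto the 10 x 10 I lattice (coordinates
#' halved), to its 10 nearest I cells (0.05). Every I cell projects to all
#' 400 E cells (0.04) and to the 99 other I cells (0.04; self-inhibition
#' excluded). Distance ties are resolved at random, so the wiring depends
#' on the RNG state.
#'
#' @param k_ee,k_ei E-cell out-degrees onto the E and I lattices.
#' @param w_ee,w_ei,w_ie,w_ii synaptic weights (mS/cm^2).
#' @param ii_self include I->I self-edges (default `FALSE`).
#' @return An object of class `module_topology`: a list of edge data frames
#'   `ee`, `ei`, `ie`, `ii`, each with columns `src`, `dst` (local 1-based
#'   cell ids; E cells 1-400, I cells 401-500) and `w`.
#' @export
build_module <- function(k_ee = 40, k_ei = 10,
                         w_ee = 0.01, w_ei = 0.05, w_ie = 0.04, w_ii = 0.04,
                         ii_self = FALSE) {
  ec <- lattice_coords(E_SIDE)
  ic <- lattice_coords(I_SIDE)

  ee <- do.call(rbind, lapply(seq_len(N_E), function(e) {
    keep <- seq_len(N_E) != e
    idx <- which(keep)[nearest_on_torus(ec$x[e], ec$y[e],
                                        ec$x[keep], ec$y[keep], E_SIDE, k_ee)]
    data.frame(src = e, dst = idx, w = w_ee)
  }))
  ei <- do.call(rbind, lapply(seq_len(N_E), function(e) {
    idx <- nearest_on_torus(ec$x[e] / 2, ec$y[e] / 2, ic$x, ic$y, I_SIDE, k_ei)
    data.frame(src = e, dst = N_E + idx, w = w_ei)
  }))
  ie <- data.frame(src = rep(N_E + seq_len(N_I), each = N_E),
                   dst = rep(seq_len(N_E), times = N_I), w = w_ie)
  ii_t <- lapply(seq_len(N_I), function(i) {
    dst <- seq_len(N_I)
    if (!ii_self) dst <- dst[dst != i]
    data.frame(src = N_E + i, dst = N_E + dst, w = w_ii)
  })
  ii <- do.call(rbind, ii_t)
  structure(list(ee = ee, ei = ei, ie = ie, ii = ii),
            class = "module_topology")
}

#' @export
print.module_topology <- function(x, ...) {
  cat("E-I module topology: 400 E + 100 I cells\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d edges, weight %g mS/cm^2\n",
                toupper(nm), nrow(x[[nm]]), x[[nm]]$w[1]))
  invisible(x)
}

#' Build the plastic inter-module E-to-E wiring
#'
#' Two directed synapse sets (module 1 -> module 2 and the reverse). Under
#' `"random"` wiring each target E cell receives exactly `in_degree`
#' synapses from uniformly sampled E cells of the other module. Under
#' `"topographic"` wiring the two 20 x 20 lattices are overlaid and each
#' source cell connects to its `in_degree` nearest cells of the other
#' module (the directly aligned cell, at distance 0, is included); by the
#' symmetry of the construction in-degrees equal out-degrees. All initial
#' weights are 0.005 mS/cm^2, the midpoint of the plasticity bounds
#' \[0, 0.01\].
#'
#' @param mode `"random"` or `"topographic"`.
#' @param in_degree synapses per cell and direction (40 default; 5 in the
#'   topographic protocols that emphasise spatial specificity).
#' @param w0 initial synaptic weight (mS/cm^2).
#' @return An object of class `intermodule_wiring`: list with edge data
#'   frames `w12`, `w21` (columns `src`, `dst` = E-cell local ids 1-400 in
#'   the source/target module, `w`), and fields `mode`, `in_degree`.
#' @export
build_intermodule <- function(mode = c("random", "topographic"),
                              in_degree = 40, w0 = 0.005) {
  mode <- match.arg(mode)
  if (in_degree < 1 || in_degree > N_E)
    stop("in_degree must be in [1, 400]")
  one_direction <- function() {
    if (mode == "random") {
      do.call(rbind, lapply(seq_len(N_E), function(tgt) {
        data.frame(src = sample.int(N_E, in_degree), dst = tgt, w = w0)
      }))
    } else {
      ec <- lattice_coords(E_SIDE)
      do.call(rbind, lapply(seq_len(N_E), function(src) {
        idx <- nearest_on_torus(ec$x[src], ec$y[src], ec$x, ec$y,
                                E_SIDE, in_degree)
        data.frame(src = src, dst = idx, w = w0)
      }))
    }
  }
  structure(list(w12 = one_direction(), w21 = one_direction(),
                 mode = mode, in_degree = in_degree),
            class = "intermodule_wiring")
}

#' @export
print.intermodule_wiring <- function(x, ...) {
  cat(sprintf("Inter-module E->E wiring: %s, in-degree %d, %d + %d synapses\n",
              x$mode, x$in_degree, nrow(x$w12), nrow(x$w21)))
  invisible(x)
}

#' Convert one direction of inter-module wiring to a sparse matrix
#'
#' @param edges an edge data frame (`src`, `dst`, `w`) such as the `w12`
#'   component of [build_intermodule()].
#' @return A 400 x 400 `Matrix::sparseMatrix` with sources as rows.
#' @export
intermodule_matrix <- function(edges) {
  Matrix::sparseMatrix(i = edges$src, j = edges$dst, x = edges$w,
                       dims = c(N_E, N_E))
}

#' Raster display index of a cell
#'
#' Cells are indexed for raster plots by lattice column: within a lattice,
#' id = y + x*L (L = 20 for E cells, 10 for I cells), 1-based. Module 2
#' occupies indices 1-400 (E) and 401-500 (I); module 1 occupies 501-900
#' (E) and 901-1000 (I).
#'
#' @param module 1 or 2 (vectorized).
#' @param kind `"E"` or `"I"` (vectorized).
#' @param x,y 0-based lattice coordinates.
#' @return Integer display indices in 1-1000.
#' @examples
#' display_index(2, "E", 1, 2)  # 23
#' @export
display_index <- function(module, kind, x, y) {
  stopifnot(all(module %in% c(1, 2)), all(kind %in% c("E", "I")))
  L <- ifelse(kind == "E", 20L, 10L)
  base <- ifelse(module == 2,
                 ifelse(kind == "E", 0L, 400L),
                 ifelse(kind == "E", 500L, 900L))
  as.integer(base + 1L + y + x * L)
}

# display ids for the 500 cells of one module, by local id 1..500
module_display_ids <- function(module) {
  ec <- lattice_coords(E_SIDE)
  ic <- lattice_coords(I_SIDE)
  c(display_index(module, "E", ec$x, ec$y),
    display_index(module, "I", ic$x, ic$y))
}

#' Write / read an edge list as delimited text
#'
#' Plain-text interchange for connectivity: three tab-separated columns
#' `src`, `dst`, `w`.
#'
#' @param edges edge data frame with columns `src`, `dst`, `w`.
#' @param path file path.
#' @return `read_edges` returns the edge data frame.
#' @export
write_edges <- function(edges, path) {
  write.table(edges[, c("src", "dst", "w")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Write one direction of inter-module weights in MatrixMarket format
#'
#' @param edges edge data frame (`src`, `dst`, `w`).
#' @param path output `.mtx` path.
#' @export
write_weights_mtx <- function(edges, path) {
  Matrix::writeMM(intermodule_matrix(edges), path)
  invisible(path)
}
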