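#' Circular buffer kernel
#'
#' Enumerates the integer cell offsets whose centre lies within `radius`
#' metres of the focal cell centre: `(d_col, d_row)` is a member iff
#' `(d_col^2 + d_row^2) * cell_size^2 <= radius^2`, with ties at exactly the
#' radius included (closed comparison). At 5 m cells a 25 m kernel is the
#' classic 81-cell discrete disk. Offsets are listed in the canonical
#' accumulation order used by [focal_sum()]: `d_col` ascending, then `d_row`
#' ascending.
#'
#' @param radius Buffer radius (m), >= 0.
#' @param cell_size Cell size (m), > 0.
#' @param inner_radius Optional annulus inner radius (m); membership then
#'   requires distance strictly greater than `inner_radius`.
#' @return A `buffer_kernel`: list with `radius`, `cell_size` and an
#'   `offsets` matrix with columns `d_row`, `d_col`.
#' @examples
#' nrow(make_kernel(25, 5)$offsets)  # 81
#' @export
make_kernel <- function(radius, cell_size, inner_radius = NULL) {
  if (radius < 0) stop("`radius` must be >= 0")
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  q_out <- (radius / cell_size)^2
  q_in <- if (is.null(inner_radius)) -1 else (inner_radius / cell_size)^2
  k <- floor(sqrt(q_out) + 1e-9)
  dr <- integer(); dc <- integer()
  for (j in seq.int(-k, k)) {
    for (i in seq.int(-k, k)) {
      s <- i * i + j * j
      if (s <= q_out && s > q_in) {
        dc <- c(dc, j); dr <- c(dr, i)
      }
    }
  }
  structure(list(radius = radius, cell_size = cell_size,
                 inner_radius = inner_radius,
                 offsets = cbind(d_row = dr, d_col = dc)),
            class = "buffer_kernel")
}

# run the C++ focal kernel over a grid, optionally in tiles with overlap
# equal to the kernel half-width so tiled output is bit-identical
focal_run <- function(values, q_in, q_out, tile_size = NULL) {
  nr <- nrow(values); nc <- ncol(values)
  # a disk radius at least the grid's cell-centre diameter covers the whole
  # grid from every cell: every cell then holds the grand total
  if (q_in < 0 && q_out >= (nr - 1)^2 + (nc - 1)^2) {
    ok <- !is.na(values)
    tot <- if (any(ok)) sum(values[ok]) else NA_real_
    return(matrix(tot, nr, nc))
  }
  if (is.null(tile_size))
    return(focal_disk_sum_cpp(values, q_in, q_out))
  tile_size <- as.integer(tile_size)
  if (tile_size < 1L) stop("`tile_size` must be a positive integer")
  k <- as.integer(floor(sqrt(q_out) + 1e-9))
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (r0 in seq.int(1L, nr, by = tile_size)) {
    r1 <- min(nr, r0 + tile_size - 1L)
    wr0 <- max(1L, r0 - k); wr1 <- min(nr, r1 + k)
    for (c0 in seq.int(1L, nc, by = tile_size)) {
      c1 <- min(nc, c0 + tile_size - 1L)
      wc0 <- max(1L, c0 - k); wc1 <- min(nc, c1 + k)
      w <- focal_disk_sum_cpp(values[wr0:wr1, wc0:wc1, drop = FALSE], q_in, q_out)
      out[r0:r1, c0:c1] <- w[(r0 - wr0 + 1L):(r1 - wr0 + 1L),
                             (c0 - wc0 + 1L):(c1 - wc0 + 1L), drop = FALSE]
    }
  }
  out
}

#' Circular-buffer focal sum
#'
#' Every output cell holds the sum of input values over the circular kernel
#' of [make_kernel()] centred at that cell. Cells outside the grid contribute
#' 0 (zero padding), so buffer sums near the border are underestimates of
#' what a larger domain would give (a kernel lying entirely off-grid sums
#' to 0). `NA` input cells contribute 0 but are tracked: a neighbourhood
#' whose in-grid cells are all `NA` yields `NA`.
#'
#' Results are computed strictly per cell, so they do not depend on
#' `tile_size`: tiled and untiled runs are bit-identical.
#'
#' @param raster A `lur_raster`.
#' @param radius Buffer radius (m).
#' @param tile_size Optional tile edge (cells) for memory-bounded execution.
#' @return A `lur_raster` of buffer sums (predictor metadata, if any, is
#'   carried over with the radius recorded in attribute `"buffer"`).
#' @export
focal_sum <- function(raster, radius, tile_size = NULL) {
  stopifnot(inherits(raster, "lur_raster"))
  if (radius < 0) stop("`radius` must be >= 0")
  q_out <- (radius / raster$spec$cell_size)^2
  out <- new_raster(raster$spec,
                    focal_run(raster$values, -1, q_out, tile_size),
                    raster$nodata)
  attr(out, "predictor_id") <- attr(raster, "predictor_id")
  attr(out, "units") <- attr(raster, "units")
  attr(out, "buffer") <- radius
  out
}

#' Annulus (ring buffer) focal sum
#'
#' Sum over cells with centre distance in `(r_inner, r_outer]` of the focal
#' cell -- the outer disk minus the inner disk, computed directly over the
#' ring offsets (not by subtracting two disk sums), so it equals the
#' brute-force ring sum exactly.
#'
#' @inheritParams focal_sum
#' @param r_inner,r_outer Annulus radii (m), `0 <= r_inner < r_outer`.
#' @export
annulus_sum <- function(raster, r_inner, r_outer, tile_size = NULL) {
  stopifnot(inherits(raster, "lur_raster"))
  if (r_inner < 0 || r_inner >= r_outer)
    stop("need 0 <= r_inner < r_outer")
  cs <- raster$spec$cell_size
  out <- new_raster(raster$spec,
                    focal_run(raster$values, (r_inner / cs)^2, (r_outer / cs)^2,
                              tile_size),
                    raster$nodata)
  attr(out, "predictor_id") <- attr(raster, "predictor_id")
  attr(out, "units") <- attr(raster, "units")
  attr(out, "buffer") <- c(r_inner, r_outer)
  out
}

#' Compute the buffered predictors required by a set of LUR models
#'
#' Works out the distinct (predictor, buffer) pairs appearing in the models'
#' terms, computes each exactly once from the per-cell base rasters, and
#' passes unbuffered predictors (`IDC`, `IDM`, backgrounds) through from the
#' supplied stack. Requesting all six built-in models yields the 16 distinct
#' buffered predictors.
#'
#' @param base Named list of per-cell base rasters (`RL`, `MRL`, `TL`,
#'   `TML`, `HTL`, `IND`, `HAR`, `RES`, `POP`) plus any unbuffered predictor
#'   rasters (`IDC`, `IDM`, `BEO`, `BEX`, `BEP`, `BEA`) the models need.
#' @param models A list of [lur_model()] objects (or a single model).
#' @param tile_size Optional focal tile edge in cells (see [focal_sum()]).
#' @return Named list of rasters keyed by term key (`"POP_5000"`,
#'   `"HTL_25-500"`, `"IDC"`, ...), suitable for [evaluate_model()].
#' @export
compute_predictor_stack <- function(base, models, tile_size = NULL) {
  if (inherits(models, "lur_model")) models <- list(models)
  stack <- list()
  if (length(models) == 0L) return(stack)
  terms <- unique(do.call(rbind, lapply(models, model_terms_table)))
  for (k in seq_len(nrow(terms))) {
    key <- terms$key[k]
    if (!is.null(stack[[key]])) next
    pid <- terms$predictor[k]
    if (terms$type[k] == "none") {
      if (is.null(base[[pid]]))
        stop("missing unbuffered predictor raster '", pid, "'")
      stack[[key]] <- base[[pid]]
    } else {
      if (is.null(base[[pid]]))
        stop("missing base raster '", pid, "' needed for ", key)
      stack[[key]] <-
        if (terms$type[k] == "buffer")
          focal_sum(base[[pid]], terms$r2[k], tile_size = tile_size)
        else
          annulus_sum(base[[pid]], terms$r1[k], terms$r2[k], tile_size = tile_size)
    }
  }
  stack
}
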