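# Independent brute-force oracles. These deliberately re-derive results from
# first principles (per-cell loops, dense sampling) and never call the code
# paths they check.

# per-cell loop over independently enumerated disk/annulus offsets
oracle_focal <- function(values, radius, cell_size, r_inner = NULL) {
  q_out <- (radius / cell_size)^2
  q_in <- if (is.null(r_inner)) -1 else (r_inner / cell_size)^2
  k <- floor(radius / cell_size)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  s <- off$dr^2 + off$dc^2
  off <- off[s <= q_out & s > q_in, ]
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ii <- i + off$dr
    ok_i <- ii >= 1 & ii <= nr
    for (j in seq_len(nc)) {
      jj <- j + off$dc
      ok <- ok_i & jj >= 1 & jj <= nc
      v <- values[cbind(ii[ok], jj[ok])]
      if (length(v) == 0L) out[i, j] <- 0       # kernel entirely off-grid
      else if (all(is.na(v))) out[i, j] <- NA   # in-grid cells all NA
      else out[i, j] <- sum(v, na.rm = TRUE)
    }
  }
  out
}

# exact point-segment distance, minimised over all segments of a network
oracle_min_dist <- function(px, py, segs) {
  best <- rep(Inf, length(px))
  for (s in seq_len(nrow(segs))) {
    ax <- segs[s, 1]; ay <- segs[s, 2]
    dx <- segs[s, 3] - ax; dy <- segs[s, 4] - ay
    l2 <- dx^2 + dy^2
    t <- if (l2 > 0) pmin(pmax(((px - ax) * dx + (py - ay) * dy) / l2, 0), 1) else 0
    d <- sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
    best <- pmin(best, d)
  }
  best
}

# weighted-mean IDW recomputed directly at given cell centres
oracle_idw <- function(cx, cy, st, radius, power) {
  vapply(seq_along(cx), function(i) {
    d <- sqrt((cx[i] - st$x)^2 + (cy[i] - st$y)^2)
    use <- d <= radius & d > 0
    if (!any(use)) return(NA_real_)
    w <- d[use]^(-power)
    sum(w * st$value[use]) / sum(w)
  }, numeric(1))
}

# dense-sampling oracle for line-length rasterization: walk each segment at
# `step` metre resolution and bin sample counts into cells
oracle_line_length <- function(roads, spec, step = 0.001) {
  ext <- c(spec$x_min, spec$x_min + spec$n_cols * spec$cell_size,
           spec$y_max - spec$n_rows * spec$cell_size, spec$y_max)
  m <- matrix(0, spec$n_rows, spec$n_cols)
  for (g in roads$geometry) {
    for (s in seq_len(nrow(g) - 1L)) {
      L <- sqrt(sum((g[s + 1L, ] - g[s, ])^2))
      if (L == 0) next
      n <- max(2L, ceiling(L / step))
      t <- (seq_len(n) - 0.5) / n
      x <- g[s, 1] + t * (g[s + 1L, 1] - g[s, 1])
      y <- g[s, 2] + t * (g[s + 1L, 2] - g[s, 2])
      ok <- x >= ext[1] & x < ext[2] & y > ext[3] & y <= ext[4]
      if (!any(ok)) next
      col <- floor((x[ok] - spec$x_min) / spec$cell_size) + 1L
      row <- floor((spec$y_max - y[ok]) / spec$cell_size) + 1L
      cnt <- table(row + (col - 1L) * spec$n_rows)
      m[as.integer(names(cnt))] <- m[as.integer(names(cnt))] + cnt * L / n
    }
  }
  m
}

random_network <- function(n_lines, extent = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_lines), function(k) {
    nv <- sample(2:4, 1)
    tibble::tibble(feature_id = paste0("r", k),
                   road_class = sample(c("major", "minor"), 1),
                   traffic_intensity = runif(1, 100, 20000),
                   heavy_traffic_intensity = runif(1, 10, 2000),
                   geometry = list(cbind(x = runif(nv, 0, extent),
                                         y = runif(nv, 0, extent))))
  })
  net <- do.call(rbind, rows)
  class(net) <- c("road_network", class(net))
  net
}

total_network_length <- function(roads, clip_spec = NULL) {
  sum(vapply(roads$geometry, function(g)
    sum(sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)), numeric(1)))
}

# a constant-value stack providing every term of a model on a small grid
constant_stack <- function(model, spec, value = 0) {
  tt <- lurmap:::model_terms_table(model)
  stack <- list()
  for (k in seq_len(nrow(tt))) {
    r <- new_raster(spec, value)
    attr(r, "units") <- unname(predictor_units[tt$predictor[k]])
    stack[[tt$key[k]]] <- r
  }
  stack
}
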