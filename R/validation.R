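#' Paired observed/modelled sample
#'
#' @param observed,modelled Equal-length numeric vectors (same units). Pairs
#'   where either value is `NA` are removed.
#' @param labels Optional site ids, kept alongside.
#' @return A `paired_sample` with elements `observed`, `modelled`, `n`,
#'   `labels`.
#' @export
paired_sample <- function(observed, modelled, labels = NULL) {
  if (length(observed) != length(modelled))
    stop("observed and modelled must have equal length")
  keep <- !is.na(observed) & !is.na(modelled)
  structure(list(observed = as.numeric(observed[keep]),
                 modelled = as.numeric(modelled[keep]),
                 n = sum(keep),
                 labels = if (is.null(labels)) NULL else labels[keep]),
            class = "paired_sample")
}

#' Root mean square error of a paired sample
#'
#' `sqrt(mean((o - m)^2))` over the N paired locations.
#' @param sample A [paired_sample()].
#' @export
rmse <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n < 1L) stop("empty sample")
  sqrt(mean((sample$observed - sample$modelled)^2))
}

#' Mean bias of a paired sample
#'
#' `mean(o - m)`: observed minus modelled, so positive bias means the model
#' underpredicts.
#' @inheritParams rmse
#' @export
bias <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n < 1L) stop("empty sample")
  mean(sample$observed - sample$modelled)
}

#' Coefficient of determination of a paired sample
#'
#' The squared Pearson correlation of observed and modelled values -- the
#' usual LUR-validation convention, symmetric in the two vectors (not the
#' R-squared of a particular regression fit).
#' @inheritParams rmse
#' @export
r_squared <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n < 2L) stop("r_squared needs at least 2 pairs")
  if (sd(sample$observed) == 0 || sd(sample$modelled) == 0)
    stop("r_squared is undefined: zero variance in observed or modelled values")
  cor(sample$observed, sample$modelled)^2
}

#' Two-sided t-test of the mean bias against zero
#'
#' One-sample t-test on the differences `o - m`. Degenerate cases follow a
#' fixed convention: identically-zero differences give `t = 0, p = 1`;
#' constant nonzero differences (zero variance, nonzero mean) give
#' `p = 0` with `t = Inf` (sign of the mean) and are flagged.
#'
#' @inheritParams rmse
#' @return List with `t`, `p`, `df`, and `degenerate` flag.
#' @export
bias_t_test <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n < 2L) stop("bias_t_test needs at least 2 pairs")
  d <- sample$observed - sample$modelled
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = sample$n - 1L, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = sample$n - 1L,
                degenerate = TRUE))
  }
  tt <- t.test(d, mu = 0, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' All validation statistics of a paired sample
#'
#' @inheritParams rmse
#' @param dataset,pollutant Optional labels carried into the report row.
#' @return One-row tibble: `dataset`, `pollutant`, `n`, `r2`, `rmse`,
#'   `bias`, `t`, `p`.
#' @export
validation_report <- function(sample, dataset = NA_character_,
                              pollutant = NA_character_) {
  tt <- bias_t_test(sample)
  r2 <- tryCatch(r_squared(sample), error = function(e) NA_real_)
  tibble(dataset = dataset, pollutant = pollutant, n = sample$n,
         r2 = r2, rmse = rmse(sample), bias = bias(sample),
         t = tt$t, p = tt$p)
}

#' Screen raw station records for completeness and average them
#'
#' Applies the exclusion rule used when validating against routine
#' monitoring data: stations with *more than* `max_missing_fraction`
#' missing values over the period are removed (a station at exactly the
#' threshold is retained), and each survivor's value is the mean of its
#' non-missing records.
#'
#' @param records Data frame with columns `id`, `x`, `y`, `value` (one row
#'   per station and time step; missing measurements as `NA`).
#' @param max_missing_fraction Exclusion threshold, default 0.20.
#' @return A `station_set` of the surviving stations with period-mean
#'   values; empty (with a warning) when none survive.
#' @export
screen_stations <- function(records, max_missing_fraction = 0.20) {
  need <- c("id", "x", "y", "value")
  if (!all(need %in% names(records)))
    stop("`records` needs columns ", paste(need, collapse = ", "))
  ids <- unique(records$id)
  keep <- character(); xs <- numeric(); ys <- numeric(); vs <- numeric()
  for (i in ids) {
    rec <- records[records$id == i, ]
    frac <- mean(is.na(rec$value))
    if (frac > max_missing_fraction) next
    keep <- c(keep, as.character(i))
    xs <- c(xs, rec$x[1]); ys <- c(ys, rec$y[1])
    vs <- c(vs, mean(rec$value, na.rm = TRUE))
  }
  if (!length(keep)) {
    warning("no station passed the completeness screen")
    return(station_set(character(), numeric(), numeric(), numeric()))
  }
  station_set(keep, xs, ys, vs)
}

#' Scatter plot of modelled vs measured concentrations
#'
#' Modelled against observed values with the 1:1 line and a linear fit,
#' as conventionally shown in LUR validation. Requires ggplot2.
#'
#' @inheritParams rmse
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_validation <- function(sample, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_validation requires the ggplot2 package")
  df <- data.frame(observed = sample$observed, modelled = sample$modelled)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$modelled)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(title = title, x = "measured", y = "modelled") +
    ggplot2::theme_minimal()
}
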