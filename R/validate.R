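#' Parameterise dependent motions by flexion angle
#'
#' Resamples each cycle of a trajectory onto a uniform flexion grid by
#' linear interpolation, treating the rising and falling limbs of an
#' up--down cycle separately and pooling them.  Samples flagged by a
#' median-absolute-deviation outlier screen (the automated stand-in for
#' visual inspection of spurious points) are excluded and reported.
#'
#' @param trajectory a \code{trajectory_set} (or data frame read from a
#'   trajectory CSV) with columns \code{cycle}, \code{flexion_deg} and
#'   the dependent-motion columns.
#' @param grid uniform flexion grid (degrees), strictly increasing.
#' @param motions character vector of columns to parameterise; default:
#'   the five dependent motions.
#' @param mad_threshold outlier screen: samples whose residual from a
#'   running median exceeds this many scaled MADs are dropped.
#' @param limbs \code{"both"} pools rising and falling flexion limbs;
#'   \code{"up"}/\code{"down"} restrict to one.
#' @return object of class \code{flexion_curves}: list with \code{grid}
#'   and, per motion, a matrix (grid points x limb-resampled traces) plus
#'   the count of excluded outliers in the \code{n_outliers} attribute.
#' @export
parametrize_by_flexion <- function(trajectory,
                                   grid = seq(8, 111, by = 0.5),
                                   motions = c("adduction_deg",
                                               "internal_rotation_deg",
                                               "S1_mm", "S2_mm", "S3_mm"),
                                   mad_threshold = 5, limbs = "both") {
  stopifnot(all(diff(grid) > 0))
  tr <- as.data.frame(trajectory)
  missing <- setdiff(c("cycle", "flexion_deg", motions), names(tr))
  if (length(missing))
    stop("parametrize_by_flexion: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (min(tr$flexion_deg) > min(grid) || max(tr$flexion_deg) < max(grid))
    stop("parametrize_by_flexion: grid extends beyond the flexion range ",
         "of the data", call. = FALSE)

  n_out <- 0L
  out <- list(grid = grid)
  for (mo in motions) {
    cols <- list()
    for (cy in unique(tr$cycle)) {
      tc <- tr[tr$cycle == cy, ]
      # split the cycle at peak flexion into rising / falling limbs
      ipk <- which.max(tc$flexion_deg)
      segs <- list(up = tc[seq_len(ipk), ],
                   down = tc[seq(ipk, nrow(tc)), ])
      segs <- switch(limbs, both = segs, up = segs["up"],
                     down = segs["down"])
      for (sg in segs) {
        if (nrow(sg) < 3L) next
        x <- sg$flexion_deg
        y <- sg[[mo]]
        # spurious-point screen: residual from a running median, flagged
        # beyond mad_threshold scaled MADs.  Noise-free traces have a
        # zero MAD, so a 0.5 (mm or deg) gross-error floor keeps the
        # screen active there without touching smooth curvature.
        med <- stats::runmed(y, k = min(11L, nrow(sg) - !(nrow(sg) %% 2)))
        r <- y - med
        sc <- stats::mad(r)
        keep <- abs(r) <= pmax(mad_threshold * sc, 0.5)
        n_out <- n_out + sum(!keep)
        x <- x[keep]; y <- y[keep]
        o <- order(x)
        x <- x[o]; y <- y[o]
        dup <- duplicated(x)
        gr_in <- grid >= min(x) & grid <= max(x)
        v <- rep(NA_real_, length(grid))
        v[gr_in] <- stats::approx(x[!dup], y[!dup], xout = grid[gr_in],
                                  ties = "ordered")$y
        cols[[length(cols) + 1L]] <- v
      }
    }
    out[[mo]] <- do.call(cbind, cols)
  }
  attr(out, "n_outliers") <- n_out
  class(out) <- "flexion_curves"
  out
}

#' @export
print.flexion_curves <- function(x, ...) {
  mo <- setdiff(names(x), "grid")
  cat(sprintf(
    "<flexion_curves> %d motions x %d grid points, %d trace(s) each\n",
    length(mo), length(x$grid), ncol(x[[mo[1L]]])))
  invisible(x)
}

#' Average flexion-parameterised cycles
#'
#' Pointwise mean and unbiased variance across the resampled traces of
#' one motion, defined wherever at least one trace covers the grid point.
#'
#' @param curves a \code{flexion_curves} object (or a plain matrix of
#'   traces in columns).
#' @param motion the motion name when \code{curves} is a
#'   \code{flexion_curves}.
#' @return list with \code{grid} (if available), \code{mean} and
#'   \code{variance} vectors.
#' @export
average_cycles <- function(curves, motion = NULL) {
  grid <- NULL
  m <- curves
  if (inherits(curves, "flexion_curves")) {
    stopifnot(!is.null(motion))
    grid <- curves$grid
    m <- curves[[motion]]
  }
  m <- as.matrix(m)
  list(grid = grid,
       mean = rowMeans(m, na.rm = TRUE),
       variance = apply(m, 1L, function(v) {
         v <- v[!is.na(v)]
         if (length(v) > 1L) stats::var(v) else NA_real_
       }))
}

#' Linear regression of experimental on simulated kinematics
#'
#' Ordinary least squares of the experimental trace on the simulated
#' trace over a stated flexion range: \code{y = b0 + b1 x}.  Reports
#' slope, intercept, RMSE of the residuals, adjusted R-squared, the
#' two-sided p-value of the slope and Pearson's correlation.
#'
#' @param y experimental trace (same grid as \code{x}).
#' @param x simulated trace.
#' @param grid flexion grid (degrees) shared by both traces; optional --
#'   when given, the fit is restricted to \code{range}.
#' @param range flexion range (degrees, length 2) to fit over.
#' @param verbose also fit and report the reversed orientation
#'   (simulated on experimental).
#' @return an object of class \code{regression_report}.
#' @export
linear_regress <- function(y, x, grid = NULL, range = NULL,
                           verbose = FALSE) {
  if (!is.null(grid) && !is.null(range)) {
    keep <- grid >= range[1L] & grid <= range[2L]
    y <- y[keep]; x <- x[keep]
  }
  ok <- is.finite(x) & is.finite(y)
  y <- y[ok]; x <- x[ok]
  if (length(x) < 3L)
    stop("linear_regress: fewer than 3 common points", call. = FALSE)
  if (stats::var(x) == 0)
    stop("linear_regress: simulated trace has zero variance",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  # a perfect fit (the self-comparison limit) makes summary.lm warn that
  # its inference is unreliable; the report still carries the exact fit
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  out <- list(
    b0 = unname(stats::coef(fit)[1L]),
    b1 = unname(stats::coef(fit)[2L]),
    b1_se = unname(co[2L, 2L]),
    RMSE = sqrt(mean(stats::residuals(fit)^2)),
    adj_r_squared = sm$adj.r.squared,
    r_squared = sm$r.squared,
    p_value = unname(co[2L, 4L]),
    pearson_r = stats::cor(x, y),
    n = length(x),
    range = if (!is.null(range)) range
            else if (!is.null(grid)) base::range(grid)
            else c(NA_real_, NA_real_)
  )
  if (verbose) {
    fit2 <- stats::lm(x ~ y)
    out$reversed <- list(b0 = unname(stats::coef(fit2)[1L]),
                         b1 = unname(stats::coef(fit2)[2L]))
  }
  class(out) <- "regression_report"
  out
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> slope %.4f, intercept %.4f, RMSE %.4f,\n  adj R^2 %.4f, p %.3g, r %.4f, n %d, flexion %g-%g deg\n",
    x$b1, x$b0, x$RMSE, x$adj_r_squared, x$p_value, x$pearson_r, x$n,
    x$range[1L], x$range[2L]))
  invisible(x)
}

#' Pairwise kinematic comparison of experimental and simulated sweeps
#'
#' The full validation pipeline: both trajectories are parameterised by
#' flexion, cycles averaged, and each of the five dependent motions of
#' the experimental data regressed on its simulated counterpart over each
#' stated flexion range.
#'
#' @param experimental,simulated \code{trajectory_set}s, data frames, or
#'   paths to trajectory CSV files.
#' @param ranges list of flexion ranges (degrees); default the truncated
#'   and full passive-flexion ranges \code{c(7, 90)} and \code{c(7, 112)}.
#' @param motions dependent-motion columns to compare.
#' @param grid_step flexion grid step (degrees).
#' @return object of class \code{comparison_table}: data frame with one
#'   row per motion x range and columns \code{motion, lo, hi, slope,
#'   intercept, RMSE, adj_r_squared, p_value, pearson_r, n}.
#' @export
compare_nk_cm <- function(experimental, simulated,
                          ranges = list(c(7, 90), c(7, 112)),
                          motions = c("adduction_deg",
                                      "internal_rotation_deg",
                                      "S1_mm", "S2_mm", "S3_mm"),
                          grid_step = 0.5) {
  load_tr <- function(x) {
    if (is.character(x)) read_trajectory_csv(x) else as.data.frame(x)
  }
  exp_tr <- load_tr(experimental)
  sim_tr <- load_tr(simulated)
  for (nm in motions) {
    miss <- setdiff(nm, intersect(names(exp_tr), names(sim_tr)))
    if (length(miss))
      stop("compare_nk_cm: missing motion column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  lo <- max(min(exp_tr$flexion_deg), min(sim_tr$flexion_deg))
  hi <- min(max(exp_tr$flexion_deg), max(sim_tr$flexion_deg))
  grid <- seq(ceiling(lo * 2) / 2, floor(hi * 2) / 2, by = grid_step)
  ce <- parametrize_by_flexion(exp_tr, grid, motions)
  cs <- parametrize_by_flexion(sim_tr, grid, motions)

  rows <- list()
  for (mo in motions) {
    ye <- average_cycles(ce, mo)$mean
    ys <- average_cycles(cs, mo)$mean
    for (rg in ranges) {
      rg2 <- c(max(rg[1L], lo), min(rg[2L], hi))
      rep <- linear_regress(ye, ys, grid = grid, range = rg2)
      rows[[length(rows) + 1L]] <- data.frame(
        motion = mo, lo = rg[1L], hi = rg[2L],
        slope = rep$b1, intercept = rep$b0, RMSE = rep$RMSE,
        adj_r_squared = rep$adj_r_squared, p_value = rep$p_value,
        pearson_r = rep$pearson_r, n = rep$n)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", class(out))
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Kinematic comparison (experimental regressed on simulated)\n")
  df <- as.data.frame(x)
  df$slope <- round(df$slope, 3)
  df$intercept <- round(df$intercept, 3)
  df$RMSE <- round(df$RMSE, 3)
  df$adj_r_squared <- round(df$adj_r_squared, 3)
  df$pearson_r <- round(df$pearson_r, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialise a comparison table to JSON
#'
#' @param table a \code{comparison_table}.
#' @param path output path.
#' @param meta optional named list written under \code{meta}.
#' @return \code{path}, invisibly.
#' @export
write_comparison_json <- function(table, path, meta = NULL) {
  payload <- list(comparison = as.data.frame(table))
  if (!is.null(meta)) payload$meta <- meta
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}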