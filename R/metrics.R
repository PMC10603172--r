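#' Rescale a series by its maximum absolute value
#'
#' Overflow-safe, scale-invariant preprocessing applied before every
#' correlation in the package: some ternary contexts grow by a factor of up
#' to 2.1 per step, so raw sums of squares over 500 turns can exceed double
#' precision; dividing by \code{max(|b|)} bounds magnitudes by 1 and leaves
#' Pearson correlations unchanged (exactly, by scale invariance).
#'
#' @param b Numeric series (length >= 2, all finite).
#' @return The rescaled series; an all-zero series is returned unchanged.
#' @export
normalize_series <- function(b) {
  if (!is.numeric(b) || length(b) < 2L)
    stop("need a numeric series of length >= 2", call. = FALSE)
  if (any(!is.finite(b))) stop("invalid series: non-finite values", call. = FALSE)
  m <- max(abs(b))
  if (m > 0) b / m else b
}

.pearson <- function(x, y) {
  x <- normalize_series(x)
  y <- normalize_series(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Pearson correlation of a dyad's behavior series
#'
#' The per-run synchrony/complementarity statistic: the sample Pearson
#' correlation between the two agents' series, computed on max-abs rescaled
#' series (see [normalize_series()]). Strongly positive values indicate
#' synchrony (same behavior at the same time), strongly negative values
#' complementarity (opposing behavior).
#'
#' @param traj A \code{dyad_trajectory} (or any list with numeric \code{b1},
#'   \code{b2} of equal length >= 2).
#' @return The correlation in \[-1, 1\], or \code{NA} when either rescaled
#'   series has zero variance.
#' @export
pearson_r <- function(traj) {
  if (!is.list(traj) || is.null(traj$b1) || is.null(traj$b2))
    stop("need a trajectory with components b1 and b2", call. = FALSE)
  if (length(traj$b1) != length(traj$b2))
    stop("invalid trajectory: b1 and b2 differ in length", call. = FALSE)
  .pearson(traj$b1, traj$b2)
}

#' Lagged cross-correlation function across repeated runs
#'
#' For each run and each lag \eqn{k \in [-L, L]}, the Pearson correlation
#' between \code{b1(t)} and \code{b2(t + k)} over the overlapping window (no
#' padding), on max-abs rescaled series; then the mean and SD across runs per
#' lag. Positive lags mean Person 1 leads (their behavior at \eqn{t} is
#' paired with Person 2's at \eqn{t + k}). The lag-0 column equals the
#' per-run [pearson_r()] values averaged, by construction.
#'
#' @param runs List of \code{dyad_trajectory} objects of equal length.
#' @param max_lag Maximum lag \eqn{L} (positive, < series length / 2).
#' @return A data frame of class \code{"ccf_result"} with columns
#'   \code{lag, mean_corr, sd_corr, n_runs}.
#' @export
cross_correlation <- function(runs, max_lag = 50L) {
  if (!is.list(runs) || length(runs) == 0L)
    stop("need a non-empty list of trajectories", call. = FALSE)
  if (inherits(runs, "dyad_trajectory")) runs <- list(runs)
  len <- unique(vapply(runs, function(tr) length(tr$b1), integer(1)))
  if (length(len) != 1L) stop("all runs must have the same length", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= len / 2)
    stop("max_lag must be in [1, length/2)", call. = FALSE)

  lags <- seq.int(-max_lag, max_lag)
  corr <- matrix(NA_real_, nrow = length(runs), ncol = length(lags))
  for (i in seq_along(runs)) {
    x <- normalize_series(runs[[i]]$b1)
    y <- normalize_series(runs[[i]]$b2)
    for (j in seq_along(lags)) {
      k <- lags[j]
      if (k >= 0) { xs <- x[1:(len - k)]; ys <- y[(1 + k):len] }
      else        { xs <- x[(1 - k):len]; ys <- y[1:(len + k)] }
      if (stats::sd(xs) > 0 && stats::sd(ys) > 0)
        corr[i, j] <- stats::cor(xs, ys)
    }
  }
  out <- data.frame(lag = lags,
                    mean_corr = colMeans(corr, na.rm = TRUE),
                    sd_corr = apply(corr, 2, stats::sd, na.rm = TRUE),
                    n_runs = length(runs))
  out$mean_corr[is.nan(out$mean_corr)] <- NA_real_
  class(out) <- c("ccf_result", "data.frame")
  out
}

#' Threshold a dyad's series into on/off activation states
#'
#' Each series is thresholded at its own arithmetic mean with a strict
#' inequality: \code{on_i(t) = b_i(t) > mean(b_i)}. A constant series is
#' therefore all-off.
#'
#' @param traj A \code{dyad_trajectory}.
#' @return A list of class \code{"on_states"} with logical vectors
#'   \code{on1}, \code{on2} and thresholds \code{mu1}, \code{mu2}.
#' @export
binarize_on_states <- function(traj) {
  if (length(traj$b1) != length(traj$b2))
    stop("invalid trajectory: b1 and b2 differ in length", call. = FALSE)
  if (length(traj$b1) < 2L) stop("need length >= 2", call. = FALSE)
  mu1 <- mean(traj$b1); mu2 <- mean(traj$b2)
  structure(list(on1 = traj$b1 > mu1, on2 = traj$b2 > mu2,
                 mu1 = mu1, mu2 = mu2),
            class = "on_states")
}

# Signed lags from each on-event in `from` to the nearest on-state in `to`,
# window +/- max_lag, equidistant ties resolved toward the negative lag.
# Events without a partner in the window are dropped (counted by caller).
.nearest_lags <- function(from_idx, to_idx, max_lag) {
  if (length(from_idx) == 0L || length(to_idx) == 0L)
    return(list(lags = integer(0), unmatched = length(from_idx)))
  lags <- integer(0)
  unmatched <- 0L
  for (t in from_idx) {
    pos <- findInterval(t, to_idx)
    cand <- to_idx[c(if (pos >= 1L) pos, if (pos < length(to_idx)) pos + 1L)]
    d <- cand - t
    d <- d[abs(d) <= max_lag]
    if (length(d) == 0L) { unmatched <- unmatched + 1L; next }
    best <- min(abs(d))
    lags <- c(lags, if (-best %in% d) -best else best)
  }
  list(lags = lags, unmatched = unmatched)
}

#' Turn-taking lag histogram
#'
#' For every time point at which agent 1 is in an above-mean "on" state, find
#' the nearest time at which agent 2 is "on" within \code{+/- max_lag} steps
#' and record the signed offset (positive = the partner's on-state comes
#' later). Equidistant ties resolve to the negative lag. Events with no
#' partner on-state inside the window are excluded from the histogram but
#' counted. With \code{events = "both"} the analysis is pooled symmetrically
#' over both agents' on-events (each against the other's on-states).
#'
#' @param traj A \code{dyad_trajectory}.
#' @param max_lag Window half-width in turns (default 20).
#' @param events \code{"agent1"} (default) or \code{"both"}.
#' @return A data frame of class \code{"lag_histogram"} with columns
#'   \code{lag, mass, count} over \code{-max_lag..max_lag} (mass sums to 1
#'   when any event was matched) and attributes \code{n_events} (on-events
#'   considered) and \code{n_unmatched}.
#' @export
turn_lags <- function(traj, max_lag = 20L, events = c("agent1", "both")) {
  events <- match.arg(events)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("max_lag must be >= 1", call. = FALSE)
  on <- binarize_on_states(traj)
  i1 <- which(on$on1); i2 <- which(on$on2)
  res <- .nearest_lags(i1, i2, max_lag)
  all_lags <- res$lags
  n_events <- length(i1)
  unmatched <- res$unmatched
  if (events == "both") {
    res2 <- .nearest_lags(i2, i1, max_lag)
    all_lags <- c(all_lags, res2$lags)
    n_events <- n_events + length(i2)
    unmatched <- unmatched + res2$unmatched
  }
  lag_histogram(all_lags, max_lag, n_events, unmatched)
}

lag_histogram <- function(lags, max_lag, n_events, n_unmatched) {
  support <- seq.int(-max_lag, max_lag)
  count <- as.integer(table(factor(lags, levels = support)))
  mass <- if (sum(count) > 0) count / sum(count) else rep(0, length(count))
  structure(data.frame(lag = support, mass = mass, count = count),
            n_events = n_events, n_unmatched = n_unmatched,
            class = c("lag_histogram", "data.frame"))
}

#' Pool turn-taking lags across repeated runs
#'
#' Sums the per-run lag counts of [turn_lags()] over a collection of runs and
#' renormalizes, giving the aggregate histogram used for figure-style output.
#'
#' @param runs List of \code{dyad_trajectory} objects.
#' @inheritParams turn_lags
#' @return A \code{lag_histogram} (see [turn_lags()]).
#' @export
pool_turn_lags <- function(runs, max_lag = 20L, events = c("agent1", "both")) {
  events <- match.arg(events)
  if (!is.list(runs) || length(runs) == 0L)
    stop("need a non-empty list of trajectories", call. = FALSE)
  if (inherits(runs, "dyad_trajectory")) runs <- list(runs)
  hists <- lapply(runs, turn_lags, max_lag = max_lag, events = events)
  count <- Reduce(`+`, lapply(hists, `[[`, "count"))
  support <- hists[[1]]$lag
  mass <- if (sum(count) > 0) count / sum(count) else rep(0, length(count))
  structure(data.frame(lag = support, mass = mass, count = as.integer(count)),
            n_events = sum(vapply(hists, attr, numeric(1), "n_events")),
            n_unmatched = sum(vapply(hists, attr, numeric(1), "n_unmatched")),
            class = c("lag_histogram", "data.frame"))
}

#' @rdname write_trajectory
#' @param ccf A \code{ccf_result} from [cross_correlation()].
#' @export
write_ccf <- function(ccf, path) {
  utils::write.csv(ccf[, c("lag", "mean_corr", "sd_corr", "n_runs")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectory
#' @param hist A \code{lag_histogram} from [turn_lags()] or
#'   [pool_turn_lags()].
#' @export
write_lag_histogram <- function(hist, path) {
  utils::write.csv(hist[, c("lag", "mass", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
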