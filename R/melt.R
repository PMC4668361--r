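#' Simulate a differential scanning fluorimetry melt curve
#'
#' The fluorescence trace is a linear baseline plus a sum of logistic
#' (two-state) transitions with Gaussian acquisition noise:
#' `F(T) = b0 + b1*T + sum_j A_j / (1 + exp((Tm_j - T) / w_j)) + noise`.
#' The default grid matches a 20-100 degC acquisition at 0.2 degC increments.
#'
#' @param transitions Data frame with columns `tm` (degC), `amplitude`
#'   (signal units) and `width` (degC, > 0); one row per unfolding transition
#'   (e.g. Fab, CH2, CH3).
#' @param baseline Numeric `c(b0, b1)` intercept and slope.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param temperatures Strictly increasing temperature grid (degC).
#' @param seed Optional seed for the noise draw.
#' @return A `melt_curve`: list with `temperatures`, `fluorescence` and the
#'   generating metadata.
#' @export
simulate_melt_curve <- function(transitions, baseline = c(0, 0), noise_sd = 0,
                                temperatures = seq(20, 100, by = 0.2),
                                seed = NULL) {
  stopifnot(
    is.data.frame(transitions), nrow(transitions) >= 1,
    all(c("tm", "amplitude", "width") %in% names(transitions)),
    all(transitions$width > 0),
    all(diff(temperatures) > 0)
  )
  if (any(transitions$tm < min(temperatures) | transitions$tm > max(temperatures))) {
    stop("transition midpoint outside the temperature grid")
  }
  if (!is.null(seed)) set.seed(seed)
  f <- baseline[1] + baseline[2] * temperatures
  for (j in seq_len(nrow(transitions))) {
    f <- f + transitions$amplitude[j] /
      (1 + exp((transitions$tm[j] - temperatures) / transitions$width[j]))
  }
  if (noise_sd > 0) f <- f + stats::rnorm(length(temperatures), 0, noise_sd)
  structure(
    list(
      temperatures = temperatures, fluorescence = f,
      transitions = transitions, baseline = baseline, noise_sd = noise_sd
    ),
    class = "melt_curve"
  )
}

#' Read / write melt curves as long CSV
#'
#' Columns `temperature_C`, `fluorescence`.
#'
#' @param curve A `melt_curve` (for writing).
#' @param path CSV file.
#' @return `read_melt_curve()` returns a `melt_curve`.
#' @export
write_melt_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(
      temperature_C = curve$temperatures,
      fluorescence = curve$fluorescence
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_melt_curve
#' @export
read_melt_curve <- function(path) {
  tab <- utils::read.csv(path)
  structure(
    list(
      temperatures = tab$temperature_C, fluorescence = tab$fluorescence,
      transitions = NULL, baseline = NULL, noise_sd = NA_real_
    ),
    class = "melt_curve"
  )
}

# centered moving average, edge-padded
.smooth_ma <- function(x, k) {
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1
  pad <- (k - 1) / 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.vector(stats::filter(xp, rep(1 / k, k), sides = 2))[(pad + 1):(pad + length(x))]
}

# classic peak prominence of local maxima in a series
.find_peaks <- function(y) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(data.frame(index = integer(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- y[1:i]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(y[max(higher_l):i]) else min(left)
    right <- y[i:n]
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(y[i:(i + min(higher_r) - 1)]) else min(right)
    y[i] - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Extract melt transitions and assign the Fab melt
#'
#' Transitions are located as peaks of the smoothed first derivative dF/dT
#' (signal smoothed by a centered moving average, differentiated by a wide
#' central difference, derivative smoothed again), then each candidate is
#' refined by a local fit of baseline-plus-one-logistic around the peak. A
#' candidate is accepted as a transition only if its fitted amplitude reaches
#' `min_prominence` of the total fluorescence range, its fitted width is
#' physically plausible (0.2-6 degC), its midpoint stays near the derivative
#' peak, and the logistic reduces the local residual sum of squares at least
#' two-fold over a straight line (which rejects noise bumps on flat
#' baselines). The Fab melt is assigned to the largest-amplitude transition,
#' the dominant unfolding event of a Fab-containing construct (the smaller
#' CH2/CH3 transitions are reported alongside).
#'
#' @param curve A `melt_curve`.
#' @param smoothing_window Width of the moving-average smoother and of the
#'   central-difference step, in degC (default 1, i.e. 5 points on the
#'   0.2 degC grid).
#' @param min_prominence Minimum fitted amplitude as a fraction of the total
#'   fluorescence range (default 0.05).
#' @return A `melt_fit`: list with `transitions` (data frame `tm`,
#'   `amplitude`, `width`, sorted by `tm`) and `assigned_fab_tm`.
#' @export
extract_transitions <- function(curve, smoothing_window = 1, min_prominence = 0.05) {
  temps <- curve$temperatures
  f <- curve$fluorescence
  if (length(temps) < 50) stop("melt curve too short: need at least 50 grid points")
  step <- stats::median(diff(temps))
  k <- max(1L, round(smoothing_window / step))
  fs <- .smooth_ma(f, k)
  # wide central difference: dF/dT over +/- smoothing_window
  h <- max(1L, round(smoothing_window / step))
  n <- length(fs)
  ds <- numeric(n)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  ds <- (fs[hi] - fs[lo]) / (temps[hi] - temps[lo])
  ds <- .smooth_ma(ds, k)
  peaks <- .find_peaks(ds)
  if (nrow(peaks)) {
    # keep peaks at least 10% as prominent as the strongest one
    peaks <- peaks[peaks$prominence >= 0.1 * max(peaks$prominence), , drop = FALSE]
    peaks <- peaks[order(-peaks$prominence), , drop = FALSE]
    peaks <- utils::head(peaks, 6L)
  }
  frange <- max(f) - min(f)
  fits <- list()
  for (i in seq_len(nrow(peaks))) {
    tp <- temps[peaks$index[i]]
    sel <- temps >= tp - 6 & temps <= tp + 6
    # trim the window at the midpoint to any neighbouring candidate peak
    other <- temps[peaks$index[-i]]
    if (length(other)) {
      lo2 <- other[other < tp]
      hi2 <- other[other > tp]
      if (length(lo2)) sel <- sel & temps > (tp + max(lo2)) / 2
      if (length(hi2)) sel <- sel & temps < (tp + min(hi2)) / 2
    }
    tw <- temps[sel]
    fw <- f[sel]
    if (length(tw) < 10) next
    amp0 <- max(fw) - min(fw)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fw ~ c0 + c1 * tw + A / (1 + exp((tm - tw) / w)),
        start = list(c0 = min(fw), c1 = 0, A = amp0, tm = tp, w = 1.5),
        lower = c(-Inf, -Inf, 0, min(tw), 0.2),
        upper = c(Inf, Inf, 2 * max(amp0, frange), max(tw), 6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (frange > 0 && cf[["A"]] < min_prominence * frange) next
    if (abs(cf[["tm"]] - tp) > 3) next
    rss_log <- sum(stats::resid(fit)^2)
    rss_lin <- sum(stats::resid(stats::lm(fw ~ tw))^2)
    if (rss_log > 0 && rss_lin / rss_log < 2) next
    fits[[length(fits) + 1L]] <- data.frame(
      tm = cf[["tm"]], amplitude = cf[["A"]], width = cf[["w"]]
    )
  }
  if (!length(fits)) {
    stop("no transition: no derivative peak above the prominence threshold")
  }
  tr <- do.call(rbind, fits)
  tr <- tr[order(tr$tm), , drop = FALSE]
  # merge duplicate detections of the same transition
  keep <- rep(TRUE, nrow(tr))
  for (i in seq_len(nrow(tr))[-1]) {
    if (tr$tm[i] - tr$tm[max(which(keep[1:(i - 1)]))] < 1) {
      prev <- max(which(keep[1:(i - 1)]))
      if (tr$amplitude[i] > tr$amplitude[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
    }
  }
  tr <- tr[keep, , drop = FALSE]
  rownames(tr) <- NULL
  structure(
    list(
      transitions = tr,
      assigned_fab_tm = tr$tm[which.max(tr$amplitude)]
    ),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: %d transition(s), Fab Tm %.1f degC\n",
              nrow(x$transitions), x$assigned_fab_tm))
  print(x$transitions, digits = 4)
  invisible(x)
}
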