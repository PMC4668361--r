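#' Marker ratio from dual-marker plating
#'
#' In a spiking experiment the tracked clone carries an extra selective marker
#' (e.g. tetracycline on top of carbenicillin); plating a sample on both
#' plates gives a total colony count and a marker-only count. The abundance
#' ratio of marker-carrying to non-marker cells is
#' `colonies_marker / (colonies_total - colonies_marker)`, with a log-scale
#' standard error from Poisson counting statistics,
#' `sqrt(1/marker + 1/(total - marker))`.
#'
#' @param colonies_marker Colonies on the restrictive plate.
#' @param colonies_total Colonies on the permissive plate (scaled to the same
#'   effective plating volume).
#' @param dilution_factor Relative dilution of the marker plate versus the
#'   total plate; marker counts are multiplied by it before the ratio.
#' @param sample_id Optional label.
#' @return A `ratio_estimate`: list with `ratio`, `se_log`, `sample_id`.
#' @examples
#' ratio_from_plates(100, 300)$ratio # 0.5
#' @export
ratio_from_plates <- function(colonies_marker, colonies_total,
                              dilution_factor = 1, sample_id = NA_character_) {
  stopifnot(colonies_marker >= 0, colonies_total >= colonies_marker,
            dilution_factor > 0)
  if (colonies_total == 0) stop("empty plate: no colonies on the total plate")
  marker_eq <- colonies_marker * dilution_factor
  if (marker_eq >= colonies_total) {
    stop("degenerate ratio: marker colonies not below total colonies")
  }
  ratio <- marker_eq / (colonies_total - marker_eq)
  se_log <- if (colonies_marker == 0) {
    Inf
  } else {
    sqrt(1 / colonies_marker + 1 / (colonies_total - marker_eq))
  }
  structure(
    list(ratio = ratio, se_log = se_log, sample_id = sample_id),
    class = "ratio_estimate"
  )
}

#' Ratio estimate from a known abundance ratio
#'
#' Wraps an externally known marker:non-marker ratio (e.g. a designed spike)
#' as a `ratio_estimate` with no counting error.
#'
#' @param ratio Non-negative ratio.
#' @param se_log Log-scale standard error (default 0).
#' @return A `ratio_estimate`.
#' @export
ratio_estimate <- function(ratio, se_log = 0) {
  stopifnot(ratio >= 0, se_log >= 0)
  structure(
    list(ratio = ratio, se_log = se_log, sample_id = NA_character_),
    class = "ratio_estimate"
  )
}

#' Fold enrichment between two ratio estimates
#'
#' The enrichment of a tracked clone across a sort is the output:input ratio
#' of its abundance ratios (a ratio of odds, matching how dual-marker plate
#' counts are read out). The 95% interval is computed on the log scale by
#' propagating the two `se_log` values.
#'
#' @param r_in,r_out `ratio_estimate`s for the sort input and output.
#' @param conf Confidence level for the interval.
#' @return List with `fold`, `lower`, `upper`, `se_log`.
#' @examples
#' fold_enrichment(ratio_estimate(1e-6), ratio_estimate(2.35e-1))$fold # 235000
#' @export
fold_enrichment <- function(r_in, r_out, conf = 0.95) {
  stopifnot(inherits(r_in, "ratio_estimate"), inherits(r_out, "ratio_estimate"))
  if (r_in$ratio <= 0) stop("undefined enrichment: input ratio is zero")
  fold <- r_out$ratio / r_in$ratio
  se <- sqrt(r_in$se_log^2 + r_out$se_log^2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(
    fold = fold,
    lower = fold * exp(-z * se),
    upper = fold * exp(z * se),
    se_log = se
  )
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return Matrix with columns `lower`, `upper` (one row per element of `x`).
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(all(x >= 0), all(x <= n), all(n >= 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  cbind(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Clone frequencies with Wilson intervals
#'
#' Converts sequenced-clone counts from one selection round into frequencies
#' with 95% Wilson score intervals.
#'
#' @param counts Named integer vector (clone -> sequenced-colony count), or a
#'   data frame with columns `clone_id` and `count`.
#' @param n_total Total clones sequenced; defaults to `sum(counts)`.
#' @param conf Confidence level.
#' @return Data frame with `clone_id`, `count`, `frequency`, `lower`, `upper`.
#' @examples
#' clone_frequencies(c(M4L = 185, other = 41))
#' @export
clone_frequencies <- function(counts, n_total = NULL, conf = 0.95) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$clone_id)
  }
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  if (is.null(n_total)) n_total <- sum(counts)
  stopifnot(n_total >= 1, sum(counts) == n_total)
  ci <- wilson_interval(counts, n_total, conf)
  data.frame(
    clone_id = names(counts),
    count = as.vector(counts),
    frequency = as.vector(counts) / n_total,
    lower = ci[, "lower"],
    upper = ci[, "upper"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Call enrichment/depletion of clones across selection rounds
#'
#' Compares each clone's frequency in the first and last round of a
#' sequenced-clone count table. A clone absent from the final round is
#' `not_detected`; a clone whose frequency changed by at least `min_fold`
#' with non-overlapping Wilson intervals is `enriched` or `depleted`;
#' anything else is `neutral`.
#'
#' @param clone_counts Long data frame with columns `clone_id`, `round`,
#'   `count` covering at least two rounds.
#' @param min_fold Minimum frequency fold change for a call (default 2).
#' @param conf Confidence level of the Wilson intervals.
#' @return Data frame with per-clone first/last frequencies, intervals, fold
#'   change, and `call`.
#' @export
call_enrichment <- function(clone_counts, min_fold = 2, conf = 0.95) {
  stopifnot(all(c("clone_id", "round", "count") %in% names(clone_counts)))
  rounds <- sort(unique(clone_counts$round))
  if (length(rounds) < 2) {
    stop("insufficient rounds: enrichment calls need at least two rounds")
  }
  r0 <- rounds[1]
  r1 <- rounds[length(rounds)]
  clones <- unique(clone_counts$clone_id)
  take <- function(r) {
    sub <- clone_counts[clone_counts$round == r, ]
    cnt <- stats::setNames(rep(0L, length(clones)), clones)
    cnt[sub$clone_id] <- sub$count
    cnt
  }
  c0 <- take(r0)
  c1 <- take(r1)
  n0 <- sum(c0)
  n1 <- sum(c1)
  ci0 <- wilson_interval(c0, n0, conf)
  ci1 <- wilson_interval(c1, n1, conf)
  f0 <- c0 / n0
  f1 <- c1 / n1
  fold <- ifelse(f0 > 0, f1 / f0, Inf)
  separated_up <- ci1[, "lower"] > ci0[, "upper"]
  separated_dn <- ci1[, "upper"] < ci0[, "lower"]
  call <- rep("neutral", length(clones))
  call[f1 > f0 & fold >= min_fold & separated_up] <- "enriched"
  call[f1 < f0 & fold <= 1 / min_fold & separated_dn] <- "depleted"
  call[c1 == 0L] <- "not_detected"
  data.frame(
    clone_id = clones,
    count_first = as.vector(c0), count_last = as.vector(c1),
    freq_first = as.vector(f0), freq_last = as.vector(f1),
    lower_first = ci0[, "lower"], upper_first = ci0[, "upper"],
    lower_last = ci1[, "lower"], upper_last = ci1[, "upper"],
    fold_change = as.vector(fold),
    call = call,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Read per-round clone counts / plate counts from TSV
#'
#' `read_clone_counts()` expects columns `clone_id`, `round`, `count`;
#' `read_plate_counts()` expects `sample_id`, `dilution_factor`,
#' `colonies_total`, `colonies_marker`.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_clone_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "round", "count")
  if (!all(need %in% names(tab))) {
    stop("clone-count file must have columns ", paste(need, collapse = ", "))
  }
  tab
}

#' @rdname read_clone_counts
#' @export
read_plate_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "dilution_factor", "colonies_total", "colonies_marker")
  if (!all(need %in% names(tab))) {
    stop("plate-count file must have columns ", paste(need, collapse = ", "))
  }
  if (any(tab$colonies_marker > tab$colonies_total)) {
    stop("marker colonies exceed total colonies")
  }
  tab
}
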