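#' 1:1 Langmuir kinetic parameters
#'
#' Single-site binding kinetics: association rate `ka` (1/(M s)), dissociation
#' rate `kd` (1/s), saturating response `rmax` (RU). The equilibrium
#' dissociation constant is `KD = kd / ka` (M), exposed in nM via
#' [kd_equilibrium()].
#'
#' @param ka,kd,rmax Positive parameters in SI units.
#' @return A `langmuir_params` list (with `kD` in molar).
#' @export
langmuir_params <- function(ka, kd, rmax = 100) {
  stopifnot(ka > 0, kd > 0, rmax > 0)
  structure(
    list(ka = ka, kd = kd, rmax = rmax, kD = kd / ka),
    class = "langmuir_params"
  )
}

#' @export
print.langmuir_params <- function(x, ...) {
  cat(sprintf(
    "langmuir_params: ka %.3g 1/(M s), kd %.3g 1/s, Rmax %.3g RU, KD %.4g nM\n",
    x$ka, x$kd, x$rmax, kd_equilibrium(x)
  ))
  invisible(x)
}

#' Equilibrium dissociation constant in nM
#'
#' `KD(nM) = (kd / ka) * 1e9` exactly.
#'
#' @param params A [langmuir_params()] (or anything with `ka` and `kd`).
#' @return KD in nanomolar.
#' @examples
#' kd_equilibrium(langmuir_params(ka = 1.30e6, kd = 4.43e-5)) # ~0.034 nM
#' @export
kd_equilibrium <- function(params) {
  (params$kd / params$ka) * 1e9
}

#' SPR injection series
#'
#' The two acquisition designs: `multi_cycle` runs each analyte concentration
#' as its own cycle with surface regeneration (response starts from zero every
#' cycle); `single_cycle` injects an ascending series back-to-back without
#' regeneration, carrying bound response across injections, with a single
#' dissociation after the last.
#'
#' @param mode `"multi_cycle"` or `"single_cycle"`.
#' @param concentrations Analyte concentrations in molar, strictly increasing.
#' @param t_assoc Association (injection) time per concentration, seconds.
#' @param t_dissoc Dissociation time, seconds (per cycle for multi-cycle,
#'   after the final injection for single-cycle).
#' @return An `injection_series` list.
#' @export
injection_series <- function(mode = c("multi_cycle", "single_cycle"),
                             concentrations, t_assoc, t_dissoc) {
  mode <- match.arg(mode)
  stopifnot(
    all(concentrations > 0), all(diff(concentrations) > 0),
    t_assoc > 0, t_dissoc > 0
  )
  structure(
    list(
      mode = mode, concentrations = concentrations,
      t_assoc = t_assoc, t_dissoc = t_dissoc
    ),
    class = "injection_series"
  )
}

#' Stock injection designs
#'
#' `series_twofold_50nM()`: two-fold series 1.56-50 nM, 120 s association,
#' 1000 s dissociation, multi-cycle (the cytokine-binding design).
#' `series_threefold_500nM()`: three-fold series 6.17-500 nM, 120 s
#' association, 300 s dissociation, single-cycle (the Fab-analyte design).
#'
#' @return An [injection_series()].
#' @export
series_twofold_50nM <- function() {
  injection_series(
    "multi_cycle",
    concentrations = 50e-9 / 2^(5:0),
    t_assoc = 120, t_dissoc = 1000
  )
}

#' @rdname series_twofold_50nM
#' @export
series_threefold_500nM <- function() {
  injection_series(
    "single_cycle",
    concentrations = 500e-9 / 3^(4:0),
    t_assoc = 120, t_dissoc = 300
  )
}

# closed-form response over one association segment starting from R0
.assoc_segment <- function(t, ka, kd, rmax, conc, r0) {
  req <- rmax * conc / (conc + kd / ka)
  kobs <- ka * conc + kd
  req + (r0 - req) * exp(-kobs * t)
}

# closed-form noiseless response for a whole series; returns response vector
# aligned with the segment table rows
.langmuir_response <- function(ka, kd, rmax, segments) {
  out <- numeric(nrow(segments))
  r0 <- 0
  cycle_prev <- NULL
  # iterate segments in order of appearance (grouped by cycle/phase blocks)
  blocks <- rle(paste(segments$cycle, segments$phase, sep = "\r"))
  pos <- 1L
  for (b in seq_along(blocks$lengths)) {
    idx <- pos:(pos + blocks$lengths[b] - 1L)
    pos <- pos + blocks$lengths[b]
    seg <- segments[idx[1], ]
    if (seg$phase == "association") {
      if (!identical(cycle_prev, seg$cycle) && seg$reset) r0 <- 0
      resp <- .assoc_segment(segments$t_seg[idx], ka, kd, rmax, seg$conc, r0)
    } else {
      resp <- r0 * exp(-kd * segments$t_seg[idx])
    }
    out[idx] <- resp
    r0 <- resp[length(resp)]
    cycle_prev <- seg$cycle
  }
  out
}

# build the segment table (time grid + annotations) for a series
.build_segments <- function(series, dt) {
  ta <- seq(dt, series$t_assoc, by = dt)
  td <- seq(dt, series$t_dissoc, by = dt)
  segs <- list()
  t0 <- 0
  for (i in seq_along(series$concentrations)) {
    conc <- series$concentrations[i]
    segs[[length(segs) + 1L]] <- data.frame(
      cycle = i, phase = "association", conc = conc, t_seg = ta,
      time = t0 + ta, reset = series$mode == "multi_cycle" || i == 1L
    )
    t0 <- t0 + series$t_assoc
    if (series$mode == "multi_cycle" || i == length(series$concentrations)) {
      segs[[length(segs) + 1L]] <- data.frame(
        cycle = i, phase = "dissociation", conc = 0, t_seg = td,
        time = t0 + td, reset = FALSE
      )
      t0 <- t0 + series$t_dissoc
    }
  }
  do.call(rbind, segs)
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association from a bound level R0 follows
#' `R(t) = Req + (R0 - Req) exp(-(ka C + kd) t)` with
#' `Req = Rmax C / (C + KD)`; dissociation follows `R(t) = R0 exp(-kd t)`.
#' Multi-cycle injections reset R0 to zero per concentration (surface
#' regeneration); single-cycle injections carry R0 across the ascending
#' series.
#'
#' @param params A [langmuir_params()].
#' @param series An [injection_series()].
#' @param noise_sd Gaussian noise standard deviation (RU).
#' @param seed Optional seed for the noise draw.
#' @param dt Time-grid step in seconds (default 1).
#' @return A `sensorgram`: list with a `data` frame (`time`, `t_seg`, `cycle`,
#'   `phase`, `conc`, `response`), the `series`, and `noise_sd`.
#' @export
simulate_sensorgram <- function(params, series, noise_sd = 0, seed = NULL,
                                dt = 1) {
  stopifnot(inherits(params, "langmuir_params"), inherits(series, "injection_series"))
  if (!is.null(seed)) set.seed(seed)
  seg <- .build_segments(series, dt)
  seg$response <- .langmuir_response(params$ka, params$kd, params$rmax, seg)
  if (noise_sd > 0) {
    seg$response <- seg$response + stats::rnorm(nrow(seg), 0, noise_sd)
  }
  structure(
    list(data = seg, series = series, noise_sd = noise_sd),
    class = "sensorgram"
  )
}

#' Read / write sensorgrams as long CSV
#'
#' Columns `time`, `t_seg`, `cycle`, `phase`, `conc`, `response`; series
#' metadata in `#`-comment header lines.
#'
#' @param sg A `sensorgram` (for writing).
#' @param path CSV file.
#' @return `read_sensorgram()` returns a `sensorgram`.
#' @export
write_sensorgram <- function(sg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(
    c(
      paste0("# mode: ", sg$series$mode),
      paste0("# t_assoc: ", sg$series$t_assoc),
      paste0("# t_dissoc: ", sg$series$t_dissoc),
      paste0("# concentrations: ",
             paste(format(sg$series$concentrations, digits = 12), collapse = ","))
    ),
    con
  )
  utils::write.csv(sg$data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(path) {
  hdr <- readLines(path, n = 8L)
  meta <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(ln)) stop("missing '# ", key, ":' header in ", path)
    sub(sprintf("^#\\s*%s:\\s*", key), "", ln[1])
  }
  series <- injection_series(
    mode = meta("mode"),
    concentrations = as.numeric(strsplit(meta("concentrations"), ",")[[1]]),
    t_assoc = as.numeric(meta("t_assoc")),
    t_dissoc = as.numeric(meta("t_dissoc"))
  )
  tab <- utils::read.csv(path, comment.char = "#")
  structure(
    list(data = tab, series = series, noise_sd = NA_real_),
    class = "sensorgram"
  )
}

#' Globally fit the 1:1 Langmuir model to a sensorgram
#'
#' Nonlinear least squares over all segments jointly, sharing `(ka, kd, rmax)`
#' across concentrations/cycles, on log10 scale for the rate constants.
#' Robustness to the wide plausible rate range comes from a multistart over a
#' log-spaced grid of initial `ka` in `[1e3, 1e7]` and `kd` in `[1e-5, 1e-1]`;
#' the best-objective converged solution is returned.
#'
#' @param sg A `sensorgram`.
#' @param n_starts Grid points per rate axis (default 3, i.e. 9 starts).
#' @return A `langmuir_fit`: list with `params` ([langmuir_params()]),
#'   `kD_nM`, residual diagnostics (`rss`, `sigma`, `residuals`), and the
#'   number of converged starts.
#' @export
fit_langmuir <- function(sg, n_starts = 3) {
  stopifnot(inherits(sg, "sensorgram"))
  seg <- sg$data
  if (sg$series$mode == "multi_cycle" && length(sg$series$concentrations) < 2) {
    stop("multi-cycle fits need at least 2 concentrations")
  }
  if (sg$series$mode == "single_cycle" && length(sg$series$concentrations) < 3) {
    stop("single-cycle fits need at least 3 injections")
  }
  obj <- function(p) {
    pred <- .langmuir_response(10^p[1], 10^p[2], p[3], seg)
    seg$response - pred
  }
  rmax0 <- max(seg$response)
  if (rmax0 <= 0) rmax0 <- 1
  la_grid <- seq(3, 7, length.out = n_starts)
  ld_grid <- seq(-5, -1, length.out = n_starts)
  best <- NULL
  n_conv <- 0L
  for (la in la_grid) {
    for (ld in ld_grid) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(la, ld, rmax0 * 1.2),
          fn = obj,
          lower = c(0, -9, 1e-6),
          upper = c(10, 2, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || fit$info %in% c(0, 9)) next
      n_conv <- n_conv + 1L
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }
  if (is.null(best)) {
    stop("fit failure: no multistart converged; check the sensorgram")
  }
  p <- best$par
  params <- langmuir_params(ka = 10^p[1], kd = 10^p[2], rmax = p[3])
  res <- obj(p)
  structure(
    list(
      params = params,
      kD_nM = kd_equilibrium(params),
      rss = sum(res^2),
      sigma = sqrt(sum(res^2) / (length(res) - 3)),
      residuals = res,
      n_converged = n_conv
    ),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  rss %.4g, sigma %.4g RU, %d start(s) converged\n",
              x$rss, x$sigma, x$n_converged))
  invisible(x)
}

#' Write a kinetic fit to JSON
#'
#' @param fit A `langmuir_fit`.
#' @param path Output JSON path.
#' @export
write_langmuir_fit <- function(fit, path) {
  jsonlite::write_json(
    list(
      ka = fit$params$ka, kd = fit$params$kd, rmax = fit$params$rmax,
      KD_nM = fit$kD_nM, rss = fit$rss, sigma = fit$sigma
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Scale kinetic rates between printed-table units and SI
#'
#' Kinetics tables conventionally print `ka` in units of 1e5 1/(M s) and `kd`
#' in 1e-5 1/s. These helpers apply the scale factors explicitly.
#'
#' @param ka_e5 Association rate in 1e5 1/(M s).
#' @param kd_em5 Dissociation rate in 1e-5 1/s.
#' @param rmax Saturating response (RU) attached to the returned parameters.
#' @param params A [langmuir_params()] in SI units.
#' @return `rates_from_table()` returns a [langmuir_params()];
#'   `rates_to_table()` returns a list with `ka_e5`, `kd_em5`, `KD_nM`.
#' @export
rates_from_table <- function(ka_e5, kd_em5, rmax = 100) {
  langmuir_params(ka = ka_e5 * 1e5, kd = kd_em5 * 1e-5, rmax = rmax)
}

#' @rdname rates_from_table
#' @export
rates_to_table <- function(params) {
  list(
    ka_e5 = params$ka / 1e5,
    kd_em5 = params$kd / 1e-5,
    KD_nM = kd_equilibrium(params)
  )
}
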