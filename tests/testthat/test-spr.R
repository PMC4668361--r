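# the two kinetics panels used throughout: printed-table scale
# (ka in 1e5 1/(M s), kd in 1e-5 1/s) with the KD (nM) each implies
il13_rates <- data.frame(
  variant = c("WT", "M4L", "E6Q", "F27L"),
  ka_e5 = c(13.0, 11.1, 11.3, 13.0),
  kd_em5 = c(5.09, 3.16, 4.26, 4.43)
)
vegf_rates <- data.frame(
  variant = c("WT", "E6Q", "V37I", "V48L", "V48I", "E6Q.V37I", "E6Q.V48L",
              "E6Q.V48I", "V37I.V48L", "V37I.V48I", "E6Q.V37I.V48L",
              "E6Q.V37I.V48I"),
  ka_e5 = c(0.313, 0.448, 0.330, 0.346, 0.319, 0.428, 0.457, 0.421, 0.352,
            0.335, 0.471, 0.414),
  kd_em5 = c(47.1, 59.2, 50.8, 47.1, 47.1, 57.7, 50.6, 56.6, 45.0, 50.5,
             53.0, 58.4)
)

test_that("KD derivation and table scaling are exact unit conversions", {
  p <- langmuir_params(ka = 1.30e6, kd = 4.43e-5)
  expect_lt(abs(kd_equilibrium(p) - 0.034), 0.001)
  p2 <- langmuir_params(ka = 4.57e4, kd = 50.6e-5)
  expect_lt(abs(kd_equilibrium(p2) - 11.1), 0.05)
  # ka = kd numerically in SI gives 1 M = 1e9 nM
  expect_equal(kd_equilibrium(langmuir_params(ka = 0.37, kd = 0.37)), 1e9)
  # printed-scale round trip
  tab <- rates_to_table(rates_from_table(11.3, 4.26))
  expect_equal(tab$ka_e5, 11.3)
  expect_equal(tab$kd_em5, 4.26)
  expect_equal(tab$KD_nM, (4.26e-5 / 11.3e5) * 1e9)
})

test_that("association plateaus follow the equilibrium binding isotherm", {
  ka <- 1e6
  kd <- 1e-3
  kD <- kd / ka # 1 nM
  # C = KD: plateau at rmax/2 once equilibrated
  sg <- simulate_sensorgram(
    langmuir_params(ka, kd, rmax = 100),
    injection_series("multi_cycle", c(kD / 4, kD), t_assoc = 20000, t_dissoc = 10)
  )
  seg <- sg$data
  end2 <- seg$response[seg$cycle == 2 & seg$phase == "association"]
  expect_equal(end2[length(end2)], 50, tolerance = 0.1)
  # C >> KD: plateau approaches rmax
  sg2 <- simulate_sensorgram(
    langmuir_params(ka, kd, rmax = 100),
    injection_series("multi_cycle", c(kD, 1000 * kD), t_assoc = 20000, t_dissoc = 10)
  )
  top <- sg2$data$response[sg2$data$cycle == 2 & sg2$data$phase == "association"]
  expect_equal(top[length(top)], 100, tolerance = 0.2)
  # Req is strictly increasing in concentration, dissociation decreasing
  sg3 <- simulate_sensorgram(rates_from_table(11.3, 4.26), series_twofold_50nM())
  ends <- vapply(split(sg3$data, sg3$data$cycle), function(d) {
    max(d$response[d$phase == "association"])
  }, 0)
  expect_true(all(diff(ends) > 0))
  dis <- sg3$data$response[sg3$data$cycle == 6 & sg3$data$phase == "dissociation"]
  expect_true(all(diff(dis) < 0))
})

test_that("sensorgrams match an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- rates_from_table(0.448, 59.2, rmax = 120) # slow-ka Fab analyte
  for (series in list(series_twofold_50nM(), series_threefold_500nM())) {
    sg <- simulate_sensorgram(p, series)
    # integrate dR/dt = ka C (Rmax - R) - kd R per segment, carrying R0
    r0 <- 0
    for (cyc in unique(sg$data$cycle)) {
      for (phase in c("association", "dissociation")) {
        seg <- sg$data[sg$data$cycle == cyc & sg$data$phase == phase, ]
        if (!nrow(seg)) next
        if (phase == "association" && series$mode == "multi_cycle") r0 <- 0
        conc <- seg$conc[1]
        sol <- deSolve::ode(
          y = c(R = r0), times = c(0, seg$t_seg),
          func = function(t, y, parms) {
            list(p$ka * conc * (p$rmax - y[1]) - p$kd * y[1])
          },
          parms = NULL, rtol = 1e-10, atol = 1e-10
        )
        expect_equal(seg$response, sol[-1, "R"], tolerance = 1e-6,
                     ignore_attr = TRUE)
        r0 <- seg$response[nrow(seg)]
      }
    }
  }
})

test_that("single-cycle traces carry bound response across injections", {
  p <- rates_from_table(0.346, 47.1)
  sg <- simulate_sensorgram(p, series_threefold_500nM())
  seg <- sg$data
  starts <- vapply(1:5, function(cyc) {
    seg$response[seg$cycle == cyc & seg$phase == "association"][1]
  }, 0)
  ends <- vapply(1:5, function(cyc) {
    d <- seg$response[seg$cycle == cyc & seg$phase == "association"]
    d[length(d)]
  }, 0)
  # continuity at injection boundaries: each start is within one time step
  # of the previous end, and bound response never resets
  expect_true(all(starts[-1] >= ends[-5] - 1e-9))
  expect_true(all(abs(starts[-1] - ends[-5]) < p$rmax * 0.05))
  expect_true(all(diff(ends) > 0))
})

test_that("noise-free global fits recover every tabulated rate pair within 1%", {
  panels <- list(
    list(rates = il13_rates, series = series_twofold_50nM()),
    list(rates = vegf_rates, series = series_threefold_500nM())
  )
  for (panel in panels) {
    for (i in seq_len(nrow(panel$rates))) {
      truth <- rates_from_table(panel$rates$ka_e5[i], panel$rates$kd_em5[i])
      fit <- fit_langmuir(simulate_sensorgram(truth, panel$series))
      expect_lt(abs(fit$params$ka / truth$ka - 1), 0.01)
      expect_lt(abs(fit$params$kd / truth$kd - 1), 0.01)
      expect_lt(abs(fit$kD_nM / kd_equilibrium(truth) - 1), 0.01)
    }
  }
})

test_that("fits tolerate measurement noise with small KD error", {
  truth <- rates_from_table(13.0, 5.09, rmax = 100) # anti-IL-13 WT rates
  errs <- vapply(1:8, function(s) {
    sg <- simulate_sensorgram(truth, series_twofold_50nM(),
                              noise_sd = 2, seed = 100 + s)
    abs(log(fit_langmuir(sg)$kD_nM / kd_equilibrium(truth)))
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("sensorgrams and fits serialize to CSV/JSON", {
  p <- rates_from_table(11.3, 4.26)
  sg <- simulate_sensorgram(p, series_twofold_50nM())
  tmp <- tempfile(fileext = ".csv")
  write_sensorgram(sg, tmp)
  back <- read_sensorgram(tmp)
  expect_equal(back$series$mode, "multi_cycle")
  expect_equal(back$series$concentrations, sg$series$concentrations)
  expect_equal(back$data$response, sg$data$response, tolerance = 1e-9)
  fit <- fit_langmuir(back)
  expect_lt(abs(fit$kD_nM / kd_equilibrium(p) - 1), 0.01)
  fj <- tempfile(fileext = ".json")
  write_langmuir_fit(fit, fj)
  j <- jsonlite::read_json(fj)
  expect_equal(j$KD_nM, fit$kD_nM, tolerance = 1e-9)
})

test_that("degenerate series and fit inputs are rejected", {
  expect_error(injection_series("multi_cycle", c(5e-9, 1e-9), 120, 300),
               "concentrations")
  p <- rates_from_table(11.3, 4.26)
  one <- injection_series("multi_cycle", 5e-8, 120, 100)
  expect_error(fit_langmuir(simulate_sensorgram(p, one)), "at least 2")
})
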