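test_that("gamma calibration recovers known exponents and the measured folds", {
  expect_equal(calibrate_gamma(c(2, 4), c(2, 4)), 1)
  x <- c(2, 3, 5, 9)
  expect_equal(calibrate_gamma(x, sqrt(x)), 0.5, tolerance = 1e-12)
  # the measured expression/MFI pairing used for the default model
  expect_lt(abs(calibrate_gamma(c(3.7, 5.6, 7.2), c(1.25, 1.37, 1.4)) - 0.17),
            0.01)
  expect_error(calibrate_gamma(c(1), c(1)), "insufficient")
  expect_error(calibrate_gamma(c(1, 2), c(1)), "equal length")
})

test_that("non-binders draw from the background distribution", {
  mod <- fluorescence_model(p_unpermeabilized = 0.3)
  x <- sample_fluorescence(5, mod, n = 1e4, binder = FALSE, seed = 1)
  set.seed(2)
  bg <- stats::rlnorm(1e4, log(mod$mu_background), mod$cv)
  expect_gt(suppressWarnings(stats::ks.test(x, bg)$p.value), 0.001)
})

test_that("the bound-component median follows the closed form", {
  mod <- fluorescence_model(mu_background = 2, scale = 100, gamma = 0.17,
                            cv = 0.6, p_unpermeabilized = 0)
  med <- bound_median(c(1, 7.2), mod)
  expect_equal(med, 2 + 100 * c(1, 7.2)^0.17)
  # the WT -> 7.2x median ratio reproduces the ~1.4-fold MFI shift
  expect_fraction_close(med[2] / med[1], 1.4, 0.02)
  # empirical medians agree
  x1 <- sample_fluorescence(1, mod, 4e4, seed = 3)
  x2 <- sample_fluorescence(7.2, mod, 4e4, seed = 4)
  expect_fraction_close(median(x2) / median(x1), med[2] / med[1], 0.03)
})

test_that("partial permeabilization yields a bimodal fluorescence mixture", {
  mod <- fluorescence_model(p_unpermeabilized = 0.3)
  x <- sample_fluorescence(5.6, mod, n = 1e5, seed = 8)
  d <- stats::density(log(x), bw = 0.25)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  modes <- d$x[peaks[d$y[peaks] > 0.05 * max(d$y)]]
  expect_equal(length(modes), 2L)
  expect_lt(abs(modes[1] - log(mod$mu_background)), 0.3)
  expect_lt(abs(modes[2] - log(bound_median(5.6, mod))), 0.3)
})

test_that("a full gate is a pure resampler and identical phenotypes stay exchangeable", {
  ph <- variant_phenotype(c("a", "b", "c"), c(2, 2, 2))
  mod <- fluorescence_model()
  # gate_fraction ~ 1: every analyzed cell is kept
  cfg <- facs_config(2e4, gate_fraction = 0.999, n_rounds = 1, regrow_to = 2e4, seed = 5)
  st <- run_screen(c(a = 5000, b = 5000, c = 10000), ph, mod, cfg)
  f1 <- population_frequencies(st[[2]])
  f0 <- population_frequencies(st[[1]])
  expect_equal(sum(f1), 1)
  # multinomial 4 sigma bound on each variant
  for (v in names(f0)) {
    se <- sqrt(f0[[v]] * (1 - f0[[v]]) / 2e4)
    expect_lt(abs(f1[[v]] - f0[[v]]), 4 * se + 1 / 2e4)
  }
  # identical phenotypes under a selective gate: frequencies preserved too
  cfg2 <- facs_config(5e4, 0.01, 1, 5e4, seed = 6)
  st2 <- run_screen(c(a = 25000, b = 25000, c = 0) + 1, ph, mod, cfg2)
  f2 <- population_frequencies(st2[[2]])
  expect_lt(abs(f2[["a"]] - 0.5), 0.1) # 500 gated cells, binomial noise
})

test_that("gate composition matches the lognormal tail-probability oracle", {
  ph <- panel_phenotypes()
  mod <- fluorescence_model()
  cfg <- facs_config(2e5, 0.01, 1, 2e5, seed = 21)
  set.seed(cfg$seed)
  pop <- population_state(setNames(rep(5e4, 4), ph$variant_id))
  post <- sort_round(pop, ph, mod, cfg)
  t <- post$gate_threshold
  med <- bound_median(ph$expression_fold, mod)
  pass <- (1 - mod$p_unpermeabilized) *
    stats::plnorm(t, log(med), mod$cv, lower.tail = FALSE) +
    mod$p_unpermeabilized *
    stats::plnorm(t, log(mod$mu_background), mod$cv, lower.tail = FALSE)
  oracle <- post$analyzed * pass / sum(post$analyzed * pass)
  kept_f <- post$kept / sum(post$kept)
  # oracle frequencies are expected gate composition at this threshold
  for (i in 1:4) {
    se <- sqrt(oracle[i] * (1 - oracle[i]) / sum(post$kept))
    expect_lt(abs(kept_f[i] - oracle[i]), 4 * se + 0.01)
  }
  # expected pass probability is monotone in median fluorescence
  expect_true(all(diff(pass) > 0))
})

test_that("regrowth conserves population size and round bookkeeping", {
  ph <- panel_phenotypes()
  cfg <- facs_config(1e4, 0.01, 3, 12345, seed = 2)
  st <- run_screen(setNames(rep(1000, 4), ph$variant_id), ph,
                   fluorescence_model(), cfg)
  expect_equal(length(st), 4L)
  for (r in 2:4) {
    expect_equal(sum(st[[r]]$counts), 12345)
    expect_equal(st[[r]]$round_index, r - 1L)
    expect_false(is.na(st[[r]]$gate_threshold))
  }
  expect_equal(st[[1]]$round_index, 0L)
  # zero rounds: trajectory equals the input
  st0 <- run_screen(c(x = 10, y = 20), variant_phenotype(c("x", "y")),
                    fluorescence_model(), facs_config(100, 0.5, 0, 100, seed = 1))
  expect_equal(length(st0), 1L)
  expect_equal(st0[[1]]$counts, c(x = 10, y = 20))
})

test_that("of two binders the brighter one gains frequency every round", {
  ph <- variant_phenotype(c("dim", "bright"), c(1, 7.2))
  mod <- fluorescence_model()
  ok <- logical(20)
  for (s in 1:20) {
    cfg <- facs_config(1e5, 0.01, 2, 1e5, seed = 1000 + s)
    st <- run_screen(c(dim = 5e4, bright = 5e4), ph, mod, cfg)
    f <- vapply(st, function(x) population_frequencies(x)[["bright"]], 0)
    ok[s] <- all(diff(f) > 0)
  }
  expect_true(all(ok))
})

test_that("a rare perfect binder is capped at 1/gate_fraction per round", {
  ph <- variant_phenotype(c("binder", "junk"), c(100, 1), binder = c(TRUE, FALSE))
  mod <- fluorescence_model(p_unpermeabilized = 0)
  cfg <- facs_config(1e5, 0.01, 1, 1e5, seed = 77)
  st <- run_screen(c(binder = 100, junk = 1e5 - 100), ph, mod, cfg)
  post <- st[[2]]
  f_analyzed <- post$analyzed[["binder"]] / sum(post$analyzed)
  f_kept <- post$kept[["binder"]] / sum(post$kept)
  expect_lte(f_kept, f_analyzed / cfg$gate_fraction + 1e-12)
  # binder signal dominates the gate so the cap is nearly attained
  expect_gt(f_kept / f_analyzed, 0.8 / cfg$gate_fraction)
})

test_that("screen trajectories serialize to TSV and JSON", {
  ph <- variant_phenotype(c("x", "y"), c(1, 3))
  st <- run_screen(c(x = 500, y = 500), ph, fluorescence_model(),
                   facs_config(1e4, 0.05, 2, 1e4, seed = 4))
  prefix <- tempfile()
  paths <- write_screen(st, prefix)
  tab <- utils::read.delim(paths[["counts"]])
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(tab$count[tab$round == 2]), 1e4)
  gates <- jsonlite::read_json(paths[["gates"]])
  expect_equal(length(gates), 3L)
})
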