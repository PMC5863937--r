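# Small two-parameter fixture: two-state channel, three voltage-step traces.
toy_traceset <- function(kf = 2, kb = 8, zz = 1.2, sigma = 0.01, seed = NULL,
                         dt = 0.02) {
  sc <- two_state()
  p <- two_state_params(kf, kb, zz)
  traces <- lapply(c(-120, -80, -40), function(V) {
    pr <- voltage_protocol(data.frame(voltage = V, duration = 2),
                           sample_dt = dt)
    traj <- simulate_protocol(sc, p, pr)
    tt <- traj$times[-1]
    po <- open_probability(traj)[-1]
    if (!is.null(seed)) po <- po + stats::rnorm(length(po), 0, sigma)
    list(id = paste0("V", V), protocol = pr, times = tt, po = po,
         sigma = sigma)
  })
  trace_set(traces, condition = "toy")
}

test_that("objective is zero on self-generated data and ~1 with declared noise", {
  sc <- two_state()
  p <- two_state_params(2, 8, 1.2)
  ts <- toy_traceset()
  obj <- objective(ts, sc, p)
  expect_lt(obj$rss, 1e-20)

  # chi-square expectation with exactly declared sigma
  set.seed(11)
  tsn <- toy_traceset(seed = 1, sigma = 0.01)
  obj <- objective(tsn, sc, p)
  expect_equal(obj$mse_star, 1, tolerance = 3 / sqrt(obj$n))

  # invariant under trace reordering
  tsr <- tsn; tsr$traces <- rev(tsr$traces)
  expect_equal(objective(tsr, sc, p)$mse_star, obj$mse_star)
})

test_that("global fit recovers a two-parameter model and respects zero-parameter fits", {
  set.seed(2)
  ts <- toy_traceset(seed = 1, sigma = 0.01)
  sc <- two_state()
  init <- two_state_params(kf = 0.5, kb = 30, zz = 1.2)
  spec <- fit_spec(sc, init, free = c("kf", "kb"), n_starts = 3, seed = 4)
  fit <- global_fit(ts, spec)
  expect_equal(unname(fit$params$values["kf"]), 2, tolerance = 0.05)
  expect_equal(unname(fit$params$values["kb"]), 8, tolerance = 0.05)
  expect_false(any(fit$nd))

  # bit-wise reproducibility for a fixed seed
  fit2 <- global_fit(ts, spec)
  expect_identical(fit$theta, fit2$theta)

  # no free parameters: objective at the fixed values, untouched
  spec0 <- fit_spec(sc, two_state_params(2, 8, 1.2), free = character(0))
  fit0 <- global_fit(ts, spec0)
  expect_equal(fit0$mse_star, objective(ts, sc, two_state_params(2, 8, 1.2))$mse_star)
  expect_equal(fit0$p, 0)
})

test_that("curvature standard errors shrink with noise and match a bootstrap", {
  sc <- two_state()
  make <- function(sigma, seed) toy_traceset(seed = seed, sigma = sigma)
  init <- two_state_params(2, 8, 1.2)
  spec <- fit_spec(sc, init, free = c("kf", "kb"), n_starts = 1)
  set.seed(3)
  fit_lo <- global_fit(make(1e-4, 1), spec)
  fit_hi <- global_fit(make(2e-2, 2), spec)
  expect_lt(max(fit_lo$se_percent), 0.2)
  expect_gt(min(fit_hi$se_percent), max(fit_lo$se_percent))

  # parametric bootstrap oracle: refit fresh noise realizations and compare
  # the spread of estimates with the curvature-based se
  set.seed(4)
  sets <- lapply(1:12, function(k) make(0.02, k))
  ests <- t(vapply(sets, function(s) {
    f <- global_fit(s, spec)
    log(f$params$values[c("kf", "kb")])
  }, numeric(2)))
  boot_se_pct <- 100 * apply(ests, 2, stats::sd)
  f0 <- global_fit(sets[[1]], spec)
  for (j in 1:2) {
    ratio <- f0$se_percent[j] / boot_se_pct[j]
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("standard errors vanish with the noise for identifiable parameters", {
  m <- model_1n_fitted()
  cat27 <- make_protocols("no_cAMP")
  cat27 <- cat27[cat27$Va == -140 & cat27$Vd == -40, ]   # 3 fast traces
  ts <- generate_traceset(m$scheme, params_1n(), cat27, noise = NULL,
                          sample_dt = 0.02, sigma_floor = 1e-4)
  spec <- fit_spec(m$scheme, params_1n(), free = c("k1", "k7"), n_starts = 1)
  fit <- global_fit(ts, spec)
  expect_lt(max(fit$se_percent), 1)
  expect_false(any(fit$nd))
})

test_that("model ranking orders by normalized error with sensible tie-breaks", {
  set.seed(6)
  m <- model_1n_fitted()
  cat27 <- make_protocols("no_cAMP")
  sub <- cat27[cat27$ta %in% c(0.3, 1, 4) | cat27$ta == 1.5, ]
  ts <- thin_traceset(generate_traceset(m$scheme, params_1n(), sub, seed = 21,
                                        sample_dt = 5e-3), 0.05)

  fit_true <- global_fit(ts, fit_spec(m$scheme, params_1n(), n_starts = 1,
                                      maxit = 120))
  # over-constrained competitor: single voltage-dependent step C<->O
  sc1 <- kinetic_scheme("one_step",
    states = data.frame(name = c("C", "O"), conducting = c(FALSE, TRUE)),
    transitions = data.frame(from = "C", to = "O", kf = "kf", kb = "kb",
                             z = "zz", stringsAsFactors = FALSE))
  fit_one <- global_fit(ts, fit_spec(sc1, two_state_params(1, 10, 4),
                                     n_starts = 4, seed = 8, maxit = 120))
  tab <- rank_models(list(`1n` = fit_true, one_step = fit_one))
  expect_equal(tab$model[1], "1n")
  expect_lt(tab$mse_star[1], tab$mse_star[2])
  # summed gating charge: exactly z1 + z2 = 8.10 with the published charges,
  # and close to it for the refitted model
  fit_fixed <- global_fit(ts, fit_spec(m$scheme, params_1n(),
                                       free = character(0)))
  expect_equal(rank_models(list(fixed = fit_fixed))$sumz, 8.10)
  expect_equal(tab$sumz[tab$model == "1n"], 8.10, tolerance = 0.05)

  # single fit ranks first trivially
  t1 <- rank_models(list(only = fit_true))
  expect_equal(t1$rank, 1)

  # mixed tracesets are rejected
  ts2 <- thin_traceset(generate_traceset(m$scheme, params_1n(), sub, seed = 22,
                                         sample_dt = 5e-3), 0.05)
  fit_other <- global_fit(ts2, fit_spec(m$scheme, params_1n(), n_starts = 1,
                                        maxit = 30))
  expect_error(rank_models(list(a = fit_true, b = fit_other)),
               "inconsistent ranking")
})
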