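test_that("flux densities vanish at equilibrium and reconstruct dp/dt", {
  m <- model_1n_fitted()
  ss <- stationary_distribution(m$scheme, m$params, -100)
  traj <- simulate_protocol(m$scheme, m$params,
    voltage_protocol(data.frame(voltage = -100, duration = 1),
                     sample_dt = 1e-2),
    initial = ss)
  fs <- flux_density(traj)
  expect_lt(max(abs(fs$flux)), 1e-9)

  # finite-difference oracle: dp/dt = incoming - outgoing flux
  pr <- double_pulse(-130, 0.5, -40, td = 0.5, sample_dt = 1e-4)
  traj <- simulate_protocol(m$scheme, m$params, pr)
  fs <- flux_density(traj)
  tr <- m$scheme$transitions
  dpdt <- matrix(0, length(traj$times), ncol(traj$occupancy),
                 dimnames = list(NULL, colnames(traj$occupancy)))
  for (j in seq_len(nrow(tr))) {
    dpdt[, tr$from[j]] <- dpdt[, tr$from[j]] - fs$flux[, j]
    dpdt[, tr$to[j]] <- dpdt[, tr$to[j]] + fs$flux[, j]
  }
  i <- seq(2, length(traj$times) - 1)
  i <- i[traj$times[i + 1] > traj$times[i - 1]]
  # skip the first ms after the switch: the fastest relaxation there
  # (tau ~ 0.1 ms) is below the resolution of the central difference
  i <- i[traj$times[i] < 0.5 - 2e-4 | traj$times[i] > 0.503]
  fd <- (traj$occupancy[i + 1, ] - traj$occupancy[i - 1, ]) /
    (traj$times[i + 1] - traj$times[i - 1])
  expect_lt(max(abs(fd - dpdt[i, ])), 1e-6 * max(1, max(abs(dpdt))))
})

test_that("activation flux routes through the closed row, not C0->O0", {
  m <- model_1n_fitted()
  traj <- simulate_protocol(m$scheme, m$params,
    voltage_protocol(data.frame(voltage = -130, duration = 2),
                     sample_dt = 1e-3))
  fs <- flux_density(traj)
  peak_main <- max(fs$flux[, "C0->C1"])
  peak_leak <- max(abs(fs$flux[, "C0->O0"]))
  expect_gt(peak_main, 100 * peak_leak)
})

test_that("gating current vanishes without charge and integrates to the summed charge", {
  # all z = 0: no gating current at all
  sc <- two_state()
  traj <- simulate_protocol(sc, two_state_params(5, 1, zz = 0),
    voltage_protocol(data.frame(voltage = -100, duration = 1),
                     sample_dt = 1e-3),
    initial = c(1, 0))
  expect_equal(max(abs(gating_current(traj)$current)), 0)

  # saturating pulse moves z1 + z2 = 8.10 elementary charges (no cAMP)
  m <- model_1n_fitted()
  q <- total_gating_charge(m$scheme, m$params, V = -160, t_pulse = 100,
                           sample_dt = 2e-3)
  expect_equal(q, 8.10, tolerance = 0.02)

  # charge-flux consistency: integral of e*sum z*J equals sum over steps of
  # z times the net number of step transits counted from occupancy changes
  pr <- voltage_protocol(data.frame(voltage = -140, duration = 20),
                         sample_dt = 2e-3)
  traj <- simulate_protocol(m$scheme, m$params, pr)
  gc <- gating_current(traj)
  occ0 <- traj$occupancy[1, ]; occ1 <- traj$occupancy[nrow(traj$occupancy), ]
  right_z1 <- c("C1", "C2", "O1", "O2")     # states beyond either z1 step
  right_z2 <- c("C2", "O2")
  q_direct <- m$params$values["z1"] *
    (sum(occ1[right_z1]) - sum(occ0[right_z1])) +
    m$params$values["z2"] * (sum(occ1[right_z2]) - sum(occ0[right_z2]))
  expect_equal(gc$charge[length(gc$charge)], unname(q_direct),
               tolerance = 1e-3)
})

test_that("ON and OFF moved charge balance over a full cycle", {
  m <- model_1n_fitted()
  pr <- voltage_protocol(data.frame(voltage = c(-140, 0),
                                    duration = c(60, 120)),
                         sample_dt = 5e-3)
  traj <- simulate_protocol(m$scheme, m$params, pr, log_dense = TRUE,
                            n_log = 500)
  gc <- gating_current(traj)
  i_switch <- max(which(traj$times <= 60))
  q_on <- gc$charge[i_switch]
  q_off <- gc$charge[length(gc$charge)] - q_on
  expect_equal(abs(q_off) / abs(q_on), 1, tolerance = 0.005)
})

test_that("peak ON-gating current and cAMP enlargement match the computed scales", {
  m <- model_1n_fitted(); a <- model_1a_fitted()
  g_n <- gating_current(simulate_protocol(m$scheme, m$params,
    voltage_protocol(data.frame(voltage = -140, duration = 5),
                     sample_dt = 5e-4)))
  g_a <- gating_current(simulate_protocol(a$scheme, a$params,
    voltage_protocol(data.frame(voltage = -140, duration = 2),
                     sample_dt = 1e-4)))
  pk_n <- peak_gating_current(g_n)$peak
  pk_a <- peak_gating_current(g_a)$peak
  expect_equal(pk_n, 1.5e-18, tolerance = 0.35)
  expect_equal(pk_a, 1.7e-17, tolerance = 0.35)
  expect_equal(pk_a / pk_n, 11, tolerance = 0.25)
})

test_that("slow OFF-gating component is carried by open-row deactivation", {
  # upon repolarization the C2->C1 transit is fast while O2->O1->O0 is slow:
  # late OFF current must be dominated by the open-row steps in both models
  for (m in list(model_1n_fitted(), model_1a_fitted())) {
    pr <- voltage_protocol(data.frame(voltage = c(-130, -40),
                                      duration = c(10, 2)),
                           sample_dt = 1e-3)
    traj <- simulate_protocol(m$scheme, m$params, pr)
    gc <- gating_current(traj)
    late <- traj$times > 10.02 & traj$times <= 10.6
    lab <- colnames(gc$per_step)
    open_steps <- lab %in% c("O0->O1", "O1->O2")
    closed_steps <- lab %in% c("C0->C1", "C1->C2")
    q_open <- sum(abs(colSums(gc$per_step[late, open_steps, drop = FALSE])))
    q_closed <- sum(abs(colSums(gc$per_step[late, closed_steps, drop = FALSE])))
    expect_gt(q_open, 5 * q_closed)
  }
})

test_that("pulse-limited activation curves approach the true steady state from below", {
  m <- model_1n_fitted()
  V <- seq(-150, -90, by = 10)
  c1 <- steady_state_activation(m$scheme, m$params, V, t_pulse = 1)
  c15 <- steady_state_activation(m$scheme, m$params, V, t_pulse = 15)
  cinf <- steady_state_activation(m$scheme, m$params, V, t_pulse = Inf)
  expect_true(all(c1$po <= c15$po + 1e-9))
  expect_true(all(c15$po <= cinf$po + 1e-9))
  # 15 s pulses approximate but do not reach the steady state
  expect_gt(max(cinf$po - c15$po), 1e-3)
  expect_lt(max(cinf$po - c15$po), 0.2)
  # saturating limit equals k7/(k7+k8) = P_o,sat
  expect_equal(steady_state_activation(m$scheme, m$params, -400,
                                       t_pulse = Inf)$po,
               0.71, tolerance = 1e-6)
})

test_that("Boltzmann fitting is exact on Boltzmann data and scale-equivariant", {
  V <- seq(-160, -60, by = 5)
  po <- 1 / (1 + exp(5 * (V - (-118)) / 25.4))
  fit <- boltzmann_fit(data.frame(voltage = V, po = po))
  expect_equal(fit$z, 5, tolerance = 1e-6)
  expect_equal(fit$Vh, -118, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)

  fit2 <- boltzmann_fit(data.frame(voltage = V, po = 0.71 * po))
  expect_equal(fit2$z, fit$z, tolerance = 1e-6)
  expect_equal(fit2$Vh, fit$Vh, tolerance = 1e-6)
  expect_equal(fit2$amplitude, 0.71, tolerance = 1e-6)

  expect_error(boltzmann_fit(data.frame(voltage = V, po = rep(0.3, length(V)))),
               "fit failure")
})

test_that("4 s pulse activation of the cAMP-free model reproduces the measured midpoint", {
  m <- model_1n_fitted()
  curve <- steady_state_activation(m$scheme, m$params, seq(-160, -60, by = 5),
                                   t_pulse = 4)
  fit <- boltzmann_fit(curve, VT = m$params$VT)
  expect_lt(abs(fit$Vh - (-118.4)), 6)
})
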