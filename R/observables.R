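#' Net probability flux densities along each transition
#'
#' For every reversible transition the net probability flux density at time
#' t is \eqn{J(t) = k_f(V_t)\,p_{from}(t) - k_b(V_t)\,p_{to}(t)} (s^-1),
#' signed positive in the forward (activating) direction. At stationarity
#' under detailed balance every J vanishes.
#'
#' @param traj a `trajectory` from [simulate_protocol()].
#' @return object of class `flux_series`: `times`, `flux` (time-by-transition
#'   matrix, columns labelled "from->to"), `zval` (numeric step charge per
#'   transition) and `voltage`.
#' @export
flux_density <- function(traj) {
  scheme <- traj$scheme; params <- traj$params
  uv <- unique(traj$voltage)
  ntr <- nrow(scheme$transitions)
  J <- matrix(0, length(traj$times), ntr)
  zval <- numeric(ntr)
  lab <- paste0(scheme$transitions$from, "->", scheme$transitions$to)
  for (V in uv) {
    sel <- traj$voltage == V
    tr <- transition_rates(scheme, params, V)
    zval <- tr$zval
    for (j in seq_len(ntr)) {
      J[sel, j] <- tr$kf_V[j] * traj$occupancy[sel, tr$from[j]] -
        tr$kb_V[j] * traj$occupancy[sel, tr$to[j]]
    }
  }
  colnames(J) <- lab
  structure(list(times = traj$times, flux = J, zval = zval,
                 voltage = traj$voltage, scheme = scheme),
            class = "flux_series")
}

#' Per-channel gating current and cumulative moved charge
#'
#' Each voltage-dependent step contributes the product of its net
#' probability flux density, its effective gating charge and the elementary
#' charge; summing over steps gives the total per-channel gating current
#' \eqn{I_g(t) = e \sum_x z_x J_x(t)} (amperes, activation-positive sign).
#' The cumulative moved charge is the time integral of \eqn{I_g/e}
#' (elementary charges).
#'
#' @param traj a `trajectory`.
#' @param exclude_charges character vector of charge parameter names whose
#'   steps are omitted (e.g. `"zc"` to drop the buffer-state contribution).
#' @return object of class `gating_current`: `times`, `current` (A),
#'   `per_step` (time-by-transition matrix, A), `charge` (cumulative, in
#'   elementary charges), `voltage`.
#' @export
gating_current <- function(traj, exclude_charges = character()) {
  fs <- flux_density(traj)
  z <- fs$zval
  zn <- traj$scheme$transitions$z
  z[!is.na(zn) & zn %in% exclude_charges] <- 0
  e <- traj$params$e
  per_step <- sweep(fs$flux, 2, e * z, `*`)
  current <- rowSums(per_step)
  charge <- pracma::cumtrapz(fs$times, current)[, 1] / e
  structure(list(times = fs$times, current = current, per_step = per_step,
                 charge = charge, voltage = fs$voltage),
            class = "gating_current")
}

#' Peak of a gating-current time course
#'
#' Grid maximum with parabolic refinement through the two neighbouring
#' samples (no smoothing).
#'
#' @param gc a `gating_current`.
#' @return list with `peak` (A) and `t_peak` (s).
#' @export
peak_gating_current <- function(gc) {
  i <- which.max(gc$current)
  peak <- gc$current[i]; tp <- gc$times[i]
  if (i > 1 && i < length(gc$current)) {
    y1 <- gc$current[i - 1]; y2 <- peak; y3 <- gc$current[i + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) {
      d <- 0.5 * (y1 - y3) / den
      if (abs(d) <= 1) {
        peak <- y2 - 0.25 * (y1 - y3) * d
        tp <- tp + d * (gc$times[i + 1] - gc$times[i])
      }
    }
  }
  list(peak = peak, t_peak = tp)
}

#' Total moved gating charge for a voltage step
#'
#' Convenience wrapper: simulate from the stationary state at `holding` to a
#' single long pulse at `V` and return the asymptotic integral of the
#' per-channel gating current in elementary charges.
#'
#' @inheritParams generator_matrix
#' @param V pulse voltage (mV).
#' @param t_pulse pulse duration (s); long enough to saturate charge
#'   movement.
#' @param holding holding potential (mV).
#' @param sample_dt integration grid (s).
#' @param exclude_charges see [gating_current()].
#' @param log_dense resolve fast early transits with additional log-spaced
#'   samples (recommended; see [simulate_protocol()]).
#' @return total moved charge in elementary charges.
#' @export
total_gating_charge <- function(scheme, params, V, t_pulse = 100,
                                holding = 0, sample_dt = 1e-3,
                                exclude_charges = character(),
                                log_dense = TRUE) {
  pr <- voltage_protocol(data.frame(voltage = V, duration = t_pulse),
                         holding = holding, sample_dt = sample_dt)
  traj <- simulate_protocol(scheme, params, pr, log_dense = log_dense,
                            n_log = 400)
  gc <- gating_current(traj, exclude_charges = exclude_charges)
  gc$charge[length(gc$charge)]
}

#' Voltage dependence of activation (pulse-limited or true steady state)
#'
#' Open probability at the end of an activating pulse of duration
#' `t_pulse` starting from the stationary distribution at the holding
#' potential, or the true stationary open probability when
#' `t_pulse = Inf`.
#'
#' @inheritParams generator_matrix
#' @param voltages vector of pulse voltages (mV).
#' @param t_pulse pulse duration in s, or `Inf` for the stationary curve.
#' @param holding holding potential (mV).
#' @param sample_dt simulation grid for finite pulses (s).
#' @return object of class `activation_curve`: data.frame with columns
#'   `voltage` and `po`, attribute `t_pulse`.
#' @export
steady_state_activation <- function(scheme, params, voltages, t_pulse = Inf,
                                    holding = 0, sample_dt = 5e-3) {
  stopifnot(length(voltages) >= 1)
  cond <- scheme$states$name[scheme$states$conducting]
  po <- vapply(voltages, function(V) {
    if (is.infinite(t_pulse)) {
      sum(stationary_distribution(scheme, params, V)[cond])
    } else {
      pr <- voltage_protocol(data.frame(voltage = V, duration = t_pulse),
                             holding = holding,
                             sample_dt = min(sample_dt, t_pulse))
      res <- .propagate(scheme, params, pr, "stationary_at_holding",
                        list(t_pulse))
      sum(res$occupancy[1, cond])
    }
  }, numeric(1))
  structure(data.frame(voltage = voltages, po = po),
            class = c("activation_curve", "data.frame"), t_pulse = t_pulse)
}

#' Boltzmann fit of an activation curve
#'
#' Weighted least-squares fit of the sigmoid
#' \deqn{P_o(V) = \frac{A}{1 + \exp(z_B (V - V_h)/V_T)}}
#' where \eqn{z_B} is the slope charge (elementary charges) and \eqn{V_h}
#' the half-activation voltage (mV).
#'
#' @param curve an `activation_curve` (or data.frame with `voltage`, `po`).
#' @param VT thermal voltage in mV.
#' @return list with `z`, `Vh`, `amplitude`, `rss` and the underlying `fit`.
#' @export
boltzmann_fit <- function(curve, VT = 25.4) {
  if (nrow(curve) < 4) stop("need at least 4 voltage points")
  V <- curve$voltage; po <- curve$po
  amp0 <- max(po)
  if (amp0 <= 0 || stats::sd(po) < 1e-10)
    stop("fit failure: input curve is flat, not a sigmoid")
  half <- amp0 / 2
  i <- which.min(abs(po - half))
  start <- list(amp = amp0, Vh = V[i], zB = 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(po ~ amp / (1 + exp(zB * (V - Vh) / VT)),
                      data = data.frame(V = V, po = po),
                      start = start,
                      lower = c(amp = 1e-6, Vh = min(V) - 200, zB = 0.01),
                      upper = c(amp = 2, Vh = max(V) + 200, zB = 30),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit failure (non-sigmoidal input?): ", conditionMessage(e),
           "; range of P_o was [", signif(min(po), 3), ", ",
           signif(max(po), 3), "]"))
  cf <- stats::coef(fit)
  list(z = unname(cf["zB"]), Vh = unname(cf["Vh"]),
       amplitude = unname(cf["amp"]),
       rss = sum(stats::resid(fit)^2), fit = fit)
}
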