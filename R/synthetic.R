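#' The study's double-pulse protocol catalog
#'
#' Nine combinations of activation voltage and duration crossed with three
#' deactivation voltages give 27 double-pulse protocols per condition.
#' Without cAMP the activation voltages are -140 mV (0.3, 1, 4 s),
#' -125 mV (0.5, 2, 11 s) and -110 mV (1.5, 5, 15 s); with cAMP they are
#' -130 mV (0.15, 0.3, 3 s), -100 mV (0.5, 2, 11 s) and -90 mV
#' (1.5, 5, 15 s). Deactivation voltages are -40, +20 and +80 mV in both
#' conditions; the holding potential is 0 mV.
#'
#' @param condition `"no_cAMP"` or `"cAMP"`.
#' @param t_deact deactivation segment duration in s (not part of the
#'   published protocol description; tails at these voltages complete well
#'   within the 2 s default).
#' @param holding holding potential (mV).
#' @param sample_dt default sampling interval (s).
#' @return object of class `protocol_catalog`: data.frame with columns
#'   `id`, `condition`, `Va`, `ta`, `Vd`, `td`, `holding` and a list column
#'   `protocol`.
#' @export
make_protocols <- function(condition = c("no_cAMP", "cAMP"), t_deact = 2,
                           holding = 0, sample_dt = 1e-3) {
  condition <- match.arg(condition)
  act <- if (condition == "no_cAMP") {
    data.frame(Va = rep(c(-140, -125, -110), each = 3),
               ta = c(0.3, 1, 4, 0.5, 2, 11, 1.5, 5, 15))
  } else {
    data.frame(Va = rep(c(-130, -100, -90), each = 3),
               ta = c(0.15, 0.3, 3, 0.5, 2, 11, 1.5, 5, 15))
  }
  Vd <- c(-40, 20, 80)
  grid <- merge(act, data.frame(Vd = Vd))
  grid <- grid[order(grid$Va, grid$ta, grid$Vd), ]
  grid$td <- t_deact
  grid$holding <- holding
  grid$condition <- condition
  grid$id <- sprintf("%s_Va%+04d_ta%g_Vd%+03d", condition, grid$Va, grid$ta,
                     grid$Vd)
  grid$protocol <- lapply(seq_len(nrow(grid)), function(i)
    double_pulse(grid$Va[i], grid$ta[i], grid$Vd[i], td = t_deact,
                 holding = holding, sample_dt = sample_dt, id = grid$id[i]))
  rownames(grid) <- NULL
  structure(grid[, c("id", "condition", "Va", "ta", "Vd", "td", "holding",
                     "protocol")],
            class = c("protocol_catalog", "data.frame"))
}

#' Noise model for synthetic averaged recordings
#'
#' Emulates the uncertainty of per-point open probabilities averaged over
#' several patches: each patch trace is the clean model curve scaled by a
#' patch-specific factor (Normal(1, `scale_sd`), rundown/expression
#' variability) plus additive Gaussian recording noise with standard
#' deviation \eqn{a + b\sqrt{P_o(1-P_o)}}. Averaging n patches shrinks the
#' s.e.m. like \eqn{1/\sqrt n}.
#'
#' @param a baseline per-patch noise s.d. (P_o units).
#' @param b occupancy-dependent noise scale.
#' @param scale_sd s.d. of the multiplicative patch-to-patch scale jitter.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(a = 0.005, b = 0.03, scale_sd = 0.02) {
  stopifnot(a >= 0, b >= 0, scale_sd >= 0, a + b > 0)
  structure(list(a = a, b = b, scale_sd = scale_sd), class = "noise_model")
}

#' Generate a synthetic trace set from a model
#'
#' For every protocol in the catalog the clean open-probability time course
#' is simulated, `n` per-patch noisy replicates are drawn (with `n` sampled
#' uniformly from `n_patches_range`), and their mean and empirical s.e.m.
#' form the trace. Deterministic for a fixed seed.
#'
#' @inheritParams generator_matrix
#' @param catalog a `protocol_catalog` from [make_protocols()].
#' @param noise a `noise_model`; pass `noise_model(0, 1e-12, 0)`-like values
#'   for (near) noise-free sets, or `NULL` for exactly clean traces with a
#'   nominal sigma.
#' @param n_patches_range integer range c(min, max) of patches per trace.
#' @param seed integer seed.
#' @param sample_dt sampling interval of the emitted traces (s).
#' @param sigma_floor lower bound applied to emitted sigma values.
#' @return a `trace_set`.
#' @export
generate_traceset <- function(scheme, params, catalog,
                              noise = noise_model(),
                              n_patches_range = c(5, 18), seed = 1,
                              sample_dt = 1e-3, sigma_floor = 1e-3) {
  params <- apply_constraints(scheme, params)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  traces <- vector("list", nrow(catalog))
  npatch <- integer(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    pr <- catalog$protocol[[i]]
    traj <- simulate_protocol(scheme, params, pr, sample_dt = sample_dt)
    po <- open_probability(traj)
    if (is.null(noise)) {
      mean_po <- po
      sem <- rep(sigma_floor, length(po))
      n <- round(mean(n_patches_range))
    } else {
      n <- if (n_patches_range[1] == n_patches_range[2]) n_patches_range[1]
           else sample(seq(n_patches_range[1], n_patches_range[2]), 1)
      sd_point <- noise$a + noise$b * sqrt(pmax(po * (1 - po), 0))
      reps <- vapply(seq_len(n), function(k) {
        scale <- 1 + stats::rnorm(1, 0, noise$scale_sd)
        po * scale + stats::rnorm(length(po), 0, sd_point)
      }, numeric(length(po)))
      mean_po <- rowMeans(reps)
      sem <- apply(reps, 1, stats::sd) / sqrt(n)
    }
    npatch[i] <- n
    traces[[i]] <- list(id = catalog$id[i], protocol = pr,
                        times = traj$times, po = mean_po,
                        sigma = pmax(sem, sigma_floor))
  }
  trace_set(traces, condition = catalog$condition[1], n_patches = npatch)
}

#' Thin a trace set to a coarser sampling interval
#'
#' Keeps every sample whose time is (approximately) a multiple of `dt`,
#' plus the final sample of each trace. Useful to keep global fits fast
#' while retaining the full protocol coverage.
#'
#' @param traceset a `trace_set`.
#' @param dt target sampling interval (s).
#' @return the thinned `trace_set`.
#' @export
thin_traceset <- function(traceset, dt) {
  traceset$traces <- lapply(traceset$traces, function(tr) {
    keep <- abs(tr$times / dt - round(tr$times / dt)) < 1e-9
    keep[1] <- TRUE
    keep[length(keep)] <- TRUE
    tr$times <- tr$times[keep]; tr$po <- tr$po[keep]
    tr$sigma <- if (length(tr$sigma) == 1) tr$sigma else tr$sigma[keep]
    tr
  })
  traceset
}

#' Macroscopic currents from open probabilities (ohmic stand-in)
#'
#' \eqn{I(t) = N g (V(t) - V_{rev}) P_o(t)} with the single-channel
#' conductance `g` in pS and voltages in mV (current in amperes).
#' [po_from_current()] inverts the transform exactly in the noise-free
#' case; samples with driving force below `tol` mV are masked with `NA`.
#'
#' @param po open-probability vector.
#' @param voltage segment voltage at each sample (mV).
#' @param g single-channel conductance (pS).
#' @param v_rev reversal potential (mV).
#' @param n_channels number of channels.
#' @return current vector in amperes.
#' @export
current_from_po <- function(po, voltage, g = 1.67, v_rev = -30,
                            n_channels = 1) {
  n_channels * (g * 1e-12) * ((voltage - v_rev) * 1e-3) * po
}

#' @rdname current_from_po
#' @param current current vector in amperes.
#' @param tol minimum |driving force| (mV) below which P_o is undefined.
#' @export
po_from_current <- function(current, voltage, g = 1.67, v_rev = -30,
                            n_channels = 1, tol = 1e-6) {
  drive <- voltage - v_rev
  po <- current / (n_channels * (g * 1e-12) * (drive * 1e-3))
  po[abs(drive) < tol] <- NA_real_
  po
}
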