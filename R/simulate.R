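#' Voltage-clamp protocol with piecewise-constant segments
#'
#' @param segments data.frame with columns `voltage` (mV) and `duration` (s).
#' @param holding holding potential in mV preceding the first segment.
#' @param sample_dt default output sampling interval in s.
#' @param id optional protocol label.
#' @return an object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(segments, holding = 0, sample_dt = 1e-3, id = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  stopifnot(all(c("voltage", "duration") %in% names(segments)))
  if (any(segments$duration <= 0)) stop("segment durations must be positive")
  if (sample_dt <= 0) stop("sample_dt must be positive")
  if (sample_dt > min(segments$duration))
    stop("sample_dt must not exceed the shortest segment")
  structure(list(segments = segments, holding = holding,
                 sample_dt = sample_dt, id = id),
            class = "voltage_protocol")
}

#' Double-pulse protocol (activation pulse then deactivation pulse)
#'
#' Convenience wrapper: holding -> (`Va`, `ta`) -> (`Vd`, `td`).
#'
#' @param Va,ta activation voltage (mV) and duration (s).
#' @param Vd,td deactivation voltage (mV) and duration (s).
#' @param holding holding potential (mV).
#' @param sample_dt sampling interval (s).
#' @param id optional protocol label.
#' @return a `voltage_protocol`.
#' @export
double_pulse <- function(Va, ta, Vd, td = 2, holding = 0, sample_dt = 1e-3,
                         id = NULL) {
  voltage_protocol(data.frame(voltage = c(Va, Vd), duration = c(ta, td)),
                   holding = holding, sample_dt = sample_dt, id = id)
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat("Voltage protocol", if (!is.null(x$id)) paste0("'", x$id, "'"),
      ": holding ", x$holding, " mV; ",
      paste(sprintf("%g mV/%g s", x$segments$voltage, x$segments$duration),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Stationary state-occupancy distribution
#'
#' Solves \eqn{pQ = 0, \sum p = 1} for the generator at voltage `V`.
#'
#' @inheritParams generator_matrix
#' @return named occupancy vector (probabilities summing to 1).
#' @export
stationary_distribution <- function(scheme, params, V) {
  Q <- generator_matrix(scheme, params, V)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  p <- tryCatch(qr.solve(A, c(rep(0, n), 1)),
                error = function(e) stop("no unique stationary distribution: ",
                                         conditionMessage(e)))
  if (min(p) < -1e-8)
    stop("no unique stationary distribution (negative occupancy component)")
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- rownames(Q)
  p
}

# Spectral propagator for dp/dt = pQ at fixed voltage. Returns an object that
# maps (p0, tau-vector) to an occupancy matrix. Falls back to
# scaling-and-squaring matrix exponentials when the eigenbasis is
# ill-conditioned (near-defective Q).
.make_propagator <- function(Q, cond_limit = 1e8) {
  A <- t(Q)                      # column-vector convention: dp'/dt = A p'
  eg <- eigen(A)
  ok <- FALSE
  Vi <- NULL
  if (all(is.finite(eg$values))) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      kappa <- norm(eg$vectors, "1") * norm(Vi, "1")
      ok <- is.finite(kappa) && kappa < cond_limit
    }
  }
  if (ok) {
    force(eg); force(Vi)
    function(p0, tau) {
      w <- Vi %*% p0
      E <- exp(outer(eg$values, tau))          # n x m
      occ <- Re(eg$vectors %*% (E * as.vector(w)))
      t(occ)                                    # m x n
    }
  } else {
    function(p0, tau) {
      m <- length(tau)
      occ <- matrix(0, m, nrow(A))
      ord <- order(tau)
      p <- p0
      tprev <- 0
      cache <- list()
      for (i in ord) {
        dt <- tau[i] - tprev
        if (dt > 0) {
          key <- sprintf("%.17g", dt)
          if (is.null(cache[[key]]))
            cache[[key]] <- as.matrix(Matrix::expm(A * dt))
          p <- cache[[key]] %*% p
          tprev <- tau[i]
        }
        occ[i, ] <- p
      }
      occ
    }
  }
}

# Per-parameter-set cache of voltage propagators and stationary
# distributions, shared across the traces of one objective evaluation.
.prop_cache <- function(scheme, params) {
  env <- new.env(parent = emptyenv())
  env$get <- function(V) {
    key <- sprintf("p%.17g", V)
    if (is.null(env[[key]]))
      env[[key]] <- .make_propagator(generator_matrix(scheme, params, V))
    env[[key]]
  }
  env$stat <- function(V) {
    key <- sprintf("s%.17g", V)
    if (is.null(env[[key]]))
      env[[key]] <- stationary_distribution(scheme, params, V)
    env[[key]]
  }
  env
}

# Shared propagation core. `times_by_segment` is a list of absolute-time
# vectors (one per segment, possibly empty) at which occupancies are wanted.
# Returns list(times, occupancy, voltage).
.propagate <- function(scheme, params, protocol, initial, times_by_segment,
                       cache = NULL) {
  segs <- protocol$segments
  if (is.null(cache)) cache <- .prop_cache(scheme, params)
  if (identical(initial, "stationary_at_holding"))
    initial <- cache$stat(protocol$holding)
  p <- as.numeric(initial)
  if (abs(sum(p) - 1) > 1e-6) stop("initial occupancy must sum to 1")
  st <- scheme$states$name
  if (length(p) != length(st)) stop("initial occupancy has wrong length")
  getprop <- cache$get
  t0 <- 0
  times <- numeric(0); volt <- numeric(0)
  occ <- matrix(numeric(0), 0, length(st))
  for (s in seq_len(nrow(segs))) {
    pr <- getprop(segs$voltage[s])
    tt <- times_by_segment[[s]]
    tau <- tt - t0
    if (length(tau)) {
      if (any(tau < -1e-12) || any(tau > segs$duration[s] + 1e-9))
        stop("requested times fall outside their segment")
      o <- pr(p, pmax(tau, 0))
      times <- c(times, tt)
      volt <- c(volt, rep(segs$voltage[s], length(tt)))
      occ <- rbind(occ, o)
    }
    p <- as.numeric(pr(p, segs$duration[s]))   # exact boundary propagation
    t0 <- t0 + segs$duration[s]
  }
  colnames(occ) <- st
  list(times = times, occupancy = occ, voltage = volt, final = p)
}

#' Simulate state occupancies through a voltage protocol
#'
#' Propagates the master equation \eqn{dp/dt = pQ(V)} segment by segment,
#' using cached eigendecompositions of the generator per voltage (with a
#' matrix-exponential fallback for ill-conditioned eigenbases). Occupancies
#' are continuous across segment boundaries and conserve total probability.
#'
#' @inheritParams generator_matrix
#' @param protocol a `voltage_protocol`.
#' @param initial occupancy vector summing to 1, or
#'   `"stationary_at_holding"` (default) to start from the stationary
#'   distribution at the holding potential.
#' @param sample_dt output sampling interval; defaults to the protocol's.
#' @param log_dense also place `n_log` log-spaced samples after each segment
#'   start (from `1e-8` s), resolving fast relaxations after voltage steps
#'   (e.g. for accurate trapezoidal charge integrals over OFF-current
#'   spikes).
#' @param n_log number of log-spaced samples per segment when `log_dense`.
#' @return an object of class `trajectory`: list with `times` (s),
#'   `occupancy` (time-by-state matrix), `voltage` (mV at each sample), and
#'   references to scheme/params/protocol.
#' @export
simulate_protocol <- function(scheme, params, protocol,
                              initial = "stationary_at_holding",
                              sample_dt = NULL, log_dense = FALSE,
                              n_log = 300) {
  dt <- if (is.null(sample_dt)) protocol$sample_dt else sample_dt
  segs <- protocol$segments
  t0 <- 0
  tbs <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    local <- seq(0, segs$duration[s], by = dt)
    if (local[length(local)] < segs$duration[s])
      local <- c(local, segs$duration[s])
    if (log_dense) {
      lg <- 10^seq(-8, log10(segs$duration[s]), length.out = n_log)
      local <- sort(unique(c(local, lg)))
    }
    if (s > 1) local <- local[-1]      # boundary sample belongs to previous row set
    tbs[[s]] <- t0 + local
    t0 <- t0 + segs$duration[s]
  }
  res <- .propagate(scheme, params, protocol, initial, tbs)
  structure(list(times = res$times, occupancy = res$occupancy,
                 voltage = res$voltage, scheme = scheme, params = params,
                 protocol = protocol),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$times), " samples over ",
      signif(max(x$times), 4), " s, ", ncol(x$occupancy), " states ('",
      x$scheme$name, "')\n", sep = "")
  invisible(x)
}

#' Open probability time course of a trajectory
#'
#' Sum of the occupancies of all conducting states at each sample.
#'
#' @param traj a `trajectory`.
#' @return numeric vector of \eqn{P_o(t)} values in [0, 1].
#' @export
open_probability <- function(traj) {
  cond <- traj$scheme$states$name[traj$scheme$states$conducting]
  rowSums(traj$occupancy[, cond, drop = FALSE])
}

# Model P_o evaluated at arbitrary absolute times of a protocol (used by the
# fitting objective; avoids building a dense uniform grid).
.model_po_at <- function(scheme, params, protocol, times,
                         initial = "stationary_at_holding", cache = NULL) {
  segs <- protocol$segments
  ends <- cumsum(segs$duration)
  starts <- c(0, ends[-length(ends)])
  idx <- findInterval(times, starts, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > nrow(segs)] <- nrow(segs)
  tbs <- lapply(seq_len(nrow(segs)), function(s) times[idx == s])
  res <- .propagate(scheme, params, protocol, initial, tbs, cache = cache)
  cond <- scheme$states$name[scheme$states$conducting]
  po <- rowSums(res$occupancy[, cond, drop = FALSE])
  po[match(times, res$times)]
}
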