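# Shared fixtures: tiny schemes and an independent stiff-ODE oracle.

two_state <- function() {
  kinetic_scheme(
    name = "two_state",
    states = data.frame(name = c("C", "O"), conducting = c(FALSE, TRUE)),
    transitions = data.frame(from = "C", to = "O", kf = "kf", kb = "kb",
                             z = "zz", stringsAsFactors = FALSE))
}

two_state_params <- function(kf = 1, kb = 1, zz = 0, VT = 25.4) {
  parameter_set(c(kf = kf, kb = kb, zz = zz), VT = VT)
}

# n-state ring with named per-edge rates f1..fn / b1..bn, last forward rate
# derived by microscopic reversibility.
ring_scheme <- function(n) {
  st <- paste0("S", seq_len(n))
  tr <- data.frame(from = st, to = st[c(2:n, 1)],
                   kf = paste0("f", seq_len(n)), kb = paste0("b", seq_len(n)),
                   z = NA, stringsAsFactors = FALSE)
  kinetic_scheme(
    name = sprintf("ring%d", n),
    states = data.frame(name = st,
                        conducting = c(rep(FALSE, n - 1), TRUE)),
    transitions = tr,
    constraints = list(list(kind = "detailed_balance", cycle = st,
                            derived = paste0("f", n))))
}

# Independent oracle: integrate dp/dt = p Q(V(t)) with a stiff solver,
# switching generators at segment boundaries.
ode_occupancy <- function(scheme, params, protocol, initial, times,
                          rtol = 1e-10, atol = 1e-12) {
  segs <- protocol$segments
  ends <- cumsum(segs$duration)
  starts <- c(0, ends[-length(ends)])
  p <- as.numeric(initial)
  out <- matrix(NA_real_, length(times), length(p))
  for (s in seq_len(nrow(segs))) {
    Q <- generator_matrix(scheme, params, segs$voltage[s])
    deriv <- function(t, y, parms) list(as.numeric(y %*% Q))
    sel <- which(times > starts[s] - 1e-12 & times <= ends[s] + 1e-12)
    tt <- sort(unique(c(0, times[sel] - starts[s], segs$duration[s])))
    sol <- deSolve::lsoda(p, tt, deriv, NULL, rtol = rtol, atol = atol)
    for (i in sel) {
      j <- which.min(abs(tt - (times[i] - starts[s])))
      out[i, ] <- sol[j, -1]
    }
    p <- as.numeric(sol[nrow(sol), -1])
  }
  colnames(out) <- scheme$states$name
  out
}

model_1n_fitted <- function() {
  sc <- build_model_1n()
  list(scheme = sc, params = apply_constraints(sc, params_1n()))
}

model_1a_fitted <- function() {
  sc <- build_model_1a()
  list(scheme = sc, params = apply_constraints(sc, params_1a()))
}
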