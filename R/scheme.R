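#' Parameter set for a kinetic scheme
#'
#' Bundles named rate constants (s^-1, values at 0 mV for voltage-dependent
#' steps) and effective gating charges (elementary charges, dimensionless)
#' together with the physical constants used to evaluate rate laws: the
#' thermal voltage \eqn{V_T = RT/F} in mV and the elementary charge in
#' coulombs.
#'
#' @param values named numeric vector; rate constants must be positive,
#'   gating charges non-negative.
#' @param VT thermal voltage in mV. Default 25.4 mV (about 22 degrees C,
#'   typical for excised Xenopus oocyte patches).
#' @param e elementary charge in coulombs.
#' @return an object of class `parameter_set`.
#' @export
parameter_set <- function(values, VT = 25.4, e = 1.602e-19) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("all parameter values must be named")
  if (anyDuplicated(names(values)))
    stop("duplicated parameter names: ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite parameter values")
  if (!is.numeric(VT) || length(VT) != 1 || !is.finite(VT) || VT <= 0)
    stop("invalid thermal voltage: VT must be a single positive number")
  structure(list(values = values, VT = VT, e = e), class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Parameter set (", length(x$values), " parameters, VT = ", x$VT, " mV)\n",
      sep = "")
  print(x$values)
  invisible(x)
}

#' Update values in a parameter set
#'
#' @param params a `parameter_set`.
#' @param values named numeric vector of values to set or add.
#' @return the updated `parameter_set`.
#' @export
set_params <- function(params, values) {
  stopifnot(inherits(params, "parameter_set"))
  v <- params$values
  v[names(values)] <- values
  params$values <- v
  params
}

.param <- function(params, name) {
  v <- params$values[name]
  if (anyNA(v) || any(!(name %in% names(params$values))))
    stop("missing parameter(s): ",
         paste(name[!(name %in% names(params$values)) | is.na(v)], collapse = ", "))
  unname(v)
}

#' Voltage-dependent rate of a single gating step
#'
#' Single-barrier Eyring rate law. A step with total effective gating charge
#' `z` splits that charge between its two directions according to `partition`
#' (the fraction carried by the evaluated direction; the forward and backward
#' fractions of one step sum to 1). With the sign convention used for
#' hyperpolarization-activated channels, the forward (activating) rate grows
#' at negative membrane potentials:
#' \deqn{k_f(V) = k_f^0 \exp(-z\,\pi_f\,V/V_T), \quad
#'       k_b(V) = k_b^0 \exp(+z\,\pi_b\,V/V_T).}
#' At `V = 0` or `z = 0` the rate equals `k0` exactly.
#'
#' @param k0 rate at 0 mV (s^-1), positive.
#' @param z effective gating charge of the full step (>= 0, dimensionless).
#' @param V membrane voltage in mV (vectorized).
#' @param VT thermal voltage in mV.
#' @param direction `"forward"` or `"backward"`.
#' @param partition fraction of `z` carried by this direction, in [0, 1].
#' @return rate(s) in s^-1.
#' @examples
#' rate_at_voltage(0.16, 0.79, V = -140)    # activating step of model 1_n
#' @export
rate_at_voltage <- function(k0, z, V, VT = 25.4,
                            direction = c("forward", "backward"),
                            partition = 0.5) {
  direction <- match.arg(direction)
  if (!is.finite(VT) || VT <= 0) stop("invalid thermal voltage: VT must be > 0")
  if (any(k0 <= 0)) stop("rate constant k0 must be positive")
  if (any(z < 0)) stop("gating charge z must be non-negative")
  if (any(partition < 0 | partition > 1)) stop("partition must lie in [0, 1]")
  sgn <- if (direction == "forward") -1 else +1
  k0 * exp(sgn * z * partition * V / VT)
}

#' Define a kinetic scheme
#'
#' A scheme is a labelled, connected graph of channel conformations. Each
#' reversible transition carries a forward and a backward rate-constant name,
#' an optional shared gating-charge name (`NA` for voltage-independent
#' steps), a forward charge partition, and optional fixed numeric scale
#' factors (used e.g. for stoichiometric multiplicities in MWC-type models).
#'
#' @param name scheme label.
#' @param states data.frame with columns `name` (character, unique) and
#'   `conducting` (logical); at least one conducting and one non-conducting
#'   state are required.
#' @param transitions data.frame with columns `from`, `to`, `kf`, `kb`
#'   (parameter names), `z` (charge parameter name or `NA`), and optionally
#'   `pf` (forward partition, default 0.5), `kf_scale`, `kb_scale`
#'   (default 1).
#' @param constraints list of constraint descriptors; see
#'   [apply_constraints()].
#' @return an object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(name, states, transitions, constraints = list()) {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "conducting") %in% names(states)),
            all(c("from", "to", "kf", "kb") %in% names(transitions)))
  if (!"z" %in% names(transitions)) transitions$z <- NA_character_
  if (!"pf" %in% names(transitions)) transitions$pf <- 0.5
  if (!"kf_scale" %in% names(transitions)) transitions$kf_scale <- 1
  if (!"kb_scale" %in% names(transitions)) transitions$kb_scale <- 1
  if (anyDuplicated(states$name))
    stop("state names must be unique")
  if (!any(states$conducting) || all(states$conducting))
    stop("scheme needs at least one conducting and one non-conducting state")
  bad <- setdiff(c(transitions$from, transitions$to), states$name)
  if (length(bad)) stop("transitions reference unknown states: ",
                        paste(unique(bad), collapse = ", "))
  if (any(transitions$from == transitions$to)) stop("self-transitions not allowed")
  if (any(transitions$pf < 0 | transitions$pf > 1))
    stop("forward partitions must lie in [0, 1]")
  sc <- structure(list(name = name, states = states,
                       transitions = transitions, constraints = constraints),
                  class = "kinetic_scheme")
  if (!.is_connected(sc))
    stop("transition graph is not connected")
  sc
}

.is_connected <- function(scheme) {
  st <- scheme$states$name
  adj <- lapply(st, function(s) {
    tr <- scheme$transitions
    unique(c(tr$to[tr$from == s], tr$from[tr$to == s]))
  })
  names(adj) <- st
  seen <- st[1]
  frontier <- st[1]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(st)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", nrow(x$states), " states (",
      sum(x$states$conducting), " conducting), ",
      nrow(x$transitions), " reversible transitions, ",
      length(x$constraints), " constraints\n", sep = "")
  invisible(x)
}

#' Names of the free parameters of a scheme
#'
#' All rate/charge names referenced by the transitions minus those derived
#' by constraints (`detailed_balance`, `posat`).
#'
#' @param scheme a `kinetic_scheme`.
#' @return character vector of parameter names.
#' @export
free_parameters <- function(scheme) {
  tr <- scheme$transitions
  all <- unique(c(tr$kf, tr$kb, tr$z[!is.na(tr$z)]))
  derived <- vapply(scheme$constraints, function(cs)
    if (cs$kind %in% c("detailed_balance", "posat")) cs$derived else NA_character_,
    character(1))
  setdiff(all, derived[!is.na(derived)])
}

#' Names of the gating-charge parameters of a scheme
#' @param scheme a `kinetic_scheme`.
#' @return character vector (possibly empty).
#' @export
charge_parameters <- function(scheme) {
  z <- scheme$transitions$z
  unique(z[!is.na(z)])
}

# Edge lookup along an ordered state cycle. Returns, per cycle edge, the
# clockwise and counter-clockwise 0 mV rates (scale included), and the signed
# charge moved when traversing the edge in cycle direction.
.cycle_edges <- function(scheme, cycle) {
  tr <- scheme$transitions
  n <- length(cycle)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- cycle[i]; b <- cycle[if (i == n) 1 else i + 1]
    j <- which(tr$from == a & tr$to == b)
    if (length(j) == 1) {
      out[[i]] <- list(cw = tr$kf[j], ccw = tr$kb[j],
                       cw_scale = tr$kf_scale[j], ccw_scale = tr$kb_scale[j],
                       z = tr$z[j], zsign = +1)
    } else {
      j <- which(tr$from == b & tr$to == a)
      if (length(j) != 1)
        stop("cycle edge ", a, "-", b, " not found (or ambiguous) in scheme")
      out[[i]] <- list(cw = tr$kb[j], ccw = tr$kf[j],
                       cw_scale = tr$kb_scale[j], ccw_scale = tr$kf_scale[j],
                       z = tr$z[j], zsign = -1)
    }
  }
  out
}

#' Enforce the constraints of a scheme on a parameter set
#'
#' Supported constraint kinds:
#' \describe{
#'   \item{`posat`}{`list(kind = "posat", opening, closing, posat, derived = closing)`:
#'     pins the saturating open probability of a voltage-independent
#'     closed-open isomerization by deriving the closing rate as
#'     \eqn{k_{close} = k_{open}(1 - P_{o,sat})/P_{o,sat}}.}
#'   \item{`detailed_balance`}{`list(kind = "detailed_balance", cycle, derived)`:
#'     `cycle` is the ordered vector of state names around a reaction loop;
#'     the designated derived rate is solved so that the product of
#'     clockwise 0 mV rates equals the product of counter-clockwise 0 mV
#'     rates (microscopic reversibility). The signed step charges around the
#'     cycle must cancel, otherwise the constraint cannot hold at all
#'     voltages and an error is raised.}
#'   \item{`shared`}{`list(kind = "shared", target, source)`: copies the value
#'     of `source` into `target`.}
#'   \item{`fixed`}{`list(kind = "fixed", names)`: marker only; the named
#'     parameters are excluded from fitting.}
#' }
#' `posat` and `shared` constraints are applied before `detailed_balance`
#' ones so that derived closing rates can participate in cycle products.
#'
#' @param scheme a `kinetic_scheme`.
#' @param params a `parameter_set` containing every non-derived parameter.
#' @return the `parameter_set` with derived rates filled in.
#' @export
apply_constraints <- function(scheme, params) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(params, "parameter_set"))
  kinds <- vapply(scheme$constraints, `[[`, character(1), "kind")
  ord <- order(match(kinds, c("shared", "posat", "detailed_balance", "fixed")))
  for (cs in scheme$constraints[ord]) {
    if (cs$kind == "shared") {
      params <- set_params(params, stats::setNames(.param(params, cs$source), cs$target))
    } else if (cs$kind == "posat") {
      p <- cs$posat
      if (!is.finite(p) || p <= 0 || p >= 1)
        stop("P_o,sat must lie strictly between 0 and 1")
      kopen <- .param(params, cs$opening)
      params <- set_params(params,
                           stats::setNames(kopen * (1 - p) / p, cs$closing))
    } else if (cs$kind == "detailed_balance") {
      edges <- .cycle_edges(scheme, cs$cycle)
      znet <- 0
      for (e in edges) {
        if (!is.na(e$z)) znet <- znet + e$zsign * .param(params, e$z)
      }
      if (abs(znet) > 1e-9)
        stop("cycle has non-zero net step charge (", signif(znet, 4),
             "): detailed balance cannot hold at all voltages")
      log_cw <- 0; log_ccw <- 0; slot <- NULL
      for (e in edges) {
        if (is.null(slot) && e$cw == cs$derived) slot <- "cw"
        else if (is.null(slot) && e$ccw == cs$derived) slot <- "ccw"
        if (e$cw != cs$derived)
          log_cw <- log_cw + log(e$cw_scale * .param(params, e$cw))
        if (e$ccw != cs$derived)
          log_ccw <- log_ccw + log(e$ccw_scale * .param(params, e$ccw))
      }
      if (is.null(slot))
        stop("derived rate '", cs$derived, "' does not appear on the cycle")
      val <- if (slot == "cw") exp(log_ccw - log_cw) else exp(log_cw - log_ccw)
      if (!is.finite(val) || val <= 0)
        stop("infeasible detailed-balance constraint: derived rate for '",
             cs$derived, "' is not positive and finite")
      params <- set_params(params, stats::setNames(val, cs$derived))
    } else if (cs$kind != "fixed") {
      stop("unknown constraint kind: ", cs$kind)
    }
  }
  params
}

#' Product ratio of clockwise to counter-clockwise rates around a cycle
#'
#' Diagnostic for microscopic reversibility: after [apply_constraints()] the
#' ratio is 1 (to numerical precision) at every voltage.
#'
#' @param scheme a `kinetic_scheme`.
#' @param params a `parameter_set` with derived rates filled.
#' @param cycle ordered state names; default: first declared detailed-balance
#'   cycle.
#' @param V membrane voltage in mV.
#' @return the dimensionless product ratio.
#' @export
cycle_flux_ratio <- function(scheme, params, cycle = NULL, V = 0) {
  if (is.null(cycle)) {
    db <- Filter(function(cs) cs$kind == "detailed_balance", scheme$constraints)
    if (!length(db)) stop("scheme declares no detailed-balance cycle")
    cycle <- db[[1]]$cycle
  }
  edges <- .cycle_edges(scheme, cycle)
  tr <- scheme$transitions
  lr <- 0
  for (e in edges) {
    z <- if (is.na(e$z)) 0 else .param(params, e$z)
    # locate partition of the underlying transition
    j <- which((tr$kf == e$cw & tr$kb == e$ccw) | (tr$kf == e$ccw & tr$kb == e$cw))[1]
    pf <- tr$pf[j]
    if (tr$kf[j] == e$cw) {   # traversed along forward direction
      kcw <- e$cw_scale * .param(params, e$cw) * exp(-z * pf * V / params$VT)
      kcc <- e$ccw_scale * .param(params, e$ccw) * exp(+z * (1 - pf) * V / params$VT)
    } else {                   # traversed against forward direction
      kcw <- e$cw_scale * .param(params, e$cw) * exp(+z * (1 - tr$pf[j]) * V / params$VT)
      kcc <- e$ccw_scale * .param(params, e$ccw) * exp(-z * tr$pf[j] * V / params$VT)
    }
    lr <- lr + log(kcw) - log(kcc)
  }
  exp(lr)
}

#' Evaluate all transition rates of a scheme at a voltage
#'
#' @param scheme a `kinetic_scheme`.
#' @param params a `parameter_set` (constraints applied).
#' @param V membrane voltage in mV (scalar).
#' @return data.frame with one row per transition: `from`, `to`, `kf_V`,
#'   `kb_V` (s^-1) and the numeric step charge `zval`.
#' @export
transition_rates <- function(scheme, params, V) {
  tr <- scheme$transitions
  n <- nrow(tr)
  kf <- kb <- zv <- numeric(n)
  for (j in seq_len(n)) {
    z <- if (is.na(tr$z[j])) 0 else .param(params, tr$z[j])
    zv[j] <- z
    kf[j] <- tr$kf_scale[j] * .param(params, tr$kf[j]) *
      exp(-z * tr$pf[j] * V / params$VT)
    kb[j] <- tr$kb_scale[j] * .param(params, tr$kb[j]) *
      exp(+z * (1 - tr$pf[j]) * V / params$VT)
  }
  data.frame(from = tr$from, to = tr$to, kf_V = kf, kb_V = kb, zval = zv,
             stringsAsFactors = FALSE)
}

#' Generator (Q) matrix of the master equation at a voltage
#'
#' Off-diagonal entry `Q[i, j]` is the transition rate i -> j at membrane
#' voltage `V`; diagonal entries make every row sum to zero, so that state
#' occupancies evolve as \eqn{dp/dt = p\,Q}.
#'
#' @inheritParams transition_rates
#' @return square numeric matrix with state names as dimnames.
#' @export
generator_matrix <- function(scheme, params, V) {
  st <- scheme$states$name
  n <- length(st)
  Q <- matrix(0, n, n, dimnames = list(st, st))
  tr <- transition_rates(scheme, params, V)
  for (j in seq_len(nrow(tr))) {
    Q[tr$from[j], tr$to[j]] <- Q[tr$from[j], tr$to[j]] + tr$kf_V[j]
    Q[tr$to[j], tr$from[j]] <- Q[tr$to[j], tr$from[j]] + tr$kb_V[j]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}
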