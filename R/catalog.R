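#' Six-state two-gating-step model of HCN2 activation (no cAMP)
#'
#' Two rows of three states: closed C0-C1-C2 and open O0-O1-O2. The two
#' horizontal steps of each row are voltage dependent and share the charges
#' `z1` (first step) and `z2` (second step) between rows; the two vertical
#' closed-open isomerizations (C0-O0 via `k5`/`k6`, C2-O2 via `k7`/`k8`) are
#' voltage independent. `k6` is derived from microscopic reversibility
#' around the single loop and `k8` from the saturating open probability
#' (`k8 = k7 (1 - P_o,sat)/P_o,sat`).
#'
#' @param posat saturating open probability pinning the C2-O2 equilibrium
#'   (0.71 for the cAMP-free channel).
#' @return a `kinetic_scheme` with flags attribute (st/ze/f all FALSE).
#' @export
build_model_1n <- function(posat = 0.71) {
  states <- data.frame(
    name = c("C0", "C1", "C2", "O0", "O1", "O2"),
    conducting = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  transitions <- data.frame(
    from = c("C0", "C1", "O0", "O1", "C0", "C2"),
    to   = c("C1", "C2", "O1", "O2", "O0", "O2"),
    kf   = c("k1", "k3", "k9", "k11", "k5", "k7"),
    kb   = c("k2", "k4", "k10", "k12", "k6", "k8"),
    z    = c("z1", "z2", "z1", "z2", NA, NA),
    stringsAsFactors = FALSE)
  sc <- kinetic_scheme(
    name = "1n", states = states, transitions = transitions,
    constraints = list(
      list(kind = "posat", opening = "k7", closing = "k8",
           posat = posat, derived = "k8"),
      list(kind = "detailed_balance",
           cycle = c("C0", "C1", "C2", "O2", "O1", "O0"),
           derived = "k6")))
  attr(sc, "flags") <- list(st = FALSE, ze = FALSE, f = FALSE)
  sc
}

#' Seven-state model with a buffer closed state (saturating cAMP)
#'
#' The six-state two-step topology of [build_model_1n()] plus one
#' non-conducting state C1* attached to C1 outside the activation pathway
#' (`k13`/`k14`, voltage dependent with its own charge `zc`). With cAMP
#' bound, the saturating open probability is 0.99.
#'
#' @param posat saturating open probability (0.99 with cAMP).
#' @return a `kinetic_scheme`.
#' @export
build_model_1a <- function(posat = 0.99) {
  base <- build_model_1n(posat = posat)
  states <- rbind(base$states,
                  data.frame(name = "C1star", conducting = FALSE))
  transitions <- rbind(base$transitions,
                       data.frame(from = "C1", to = "C1star",
                                  kf = "k13", kb = "k14", z = "zc",
                                  pf = 0.5, kf_scale = 1, kb_scale = 1,
                                  stringsAsFactors = FALSE))
  sc <- kinetic_scheme(name = "1a", states = states,
                       transitions = transitions,
                       constraints = base$constraints)
  attr(sc, "flags") <- list(st = FALSE, ze = FALSE, f = FALSE)
  sc
}

#' Fitted rate constants and gating charges for the cAMP-free model
#'
#' Zero-voltage rate constants (s^-1) and effective gating charges for the
#' six-state two-step model in the absence of cAMP. The derived rates `k6`
#' and `k8` are intentionally absent; fill them with
#' [apply_constraints()].
#'
#' @param VT thermal voltage in mV.
#' @return a `parameter_set`.
#' @export
params_1n <- function(VT = 25.4) {
  parameter_set(c(
    k1 = 1.60e-1, k2 = 5.01e1, z1 = 0.79,
    k3 = 8.12e-8, k4 = 3.32e6, z2 = 7.31,
    k5 = 1.77e-2, k7 = 3.11,
    k9 = 1.30e-3, k10 = 2.35e1,
    k11 = 5.11e-5, k12 = 8.93e3), VT = VT)
}

#' Fitted rate constants and gating charges for the saturating-cAMP model
#'
#' As [params_1n()] but for the seven-state model at 10 uM cAMP, including
#' the buffer-state rates `k13`/`k14` and charge `zc`.
#'
#' @param VT thermal voltage in mV.
#' @return a `parameter_set`.
#' @export
params_1a <- function(VT = 25.4) {
  parameter_set(c(
    k1 = 3.24, k2 = 1.21e2, z1 = 0.78,
    k3 = 1.70e-3, k4 = 9.88e4, z2 = 4.34,
    k5 = 2.12e-1, k7 = 4.45,
    k9 = 3.10, k10 = 2.68e1,
    k11 = 4.92e-2, k12 = 6.96e2,
    k13 = 1.85e-1, k14 = 1.84, zc = 1.03), VT = VT)
}

#' Allosteric MWC-type model with independent voltage sensors
#'
#' `n_sensors` identical voltage sensors move independently (stoichiometric
#' multiplicities on each step), all carrying the same charge `z`; a
#' concerted voltage-independent closed-open isomerization couples to the
#' sensors through a constant allosteric factor `f`. The split is
#' symmetric: open-row sensor steps have forward rates scaled by
#' \eqn{\sqrt f} and backward rates by \eqn{1/\sqrt f}, and the
#' closed-open rates at sensor level j are scaled by \eqn{f^{\pm j/2}}, so
#' the level-j open equilibrium is \eqn{L_0 f^j} and every rung cycle obeys
#' detailed balance by construction.
#'
#' Parameters: `a`/`b` (per-sensor forward/backward rates at 0 mV), `z`
#' (per-sensor charge), `ko`/`kc` (opening/closing rates at sensor level 0).
#'
#' @param n_sensors number of voltage sensors (1 to 4).
#' @param f allosteric factor (> 0), baked into the scheme's scale factors.
#' @return a `kinetic_scheme` with 2(n_sensors + 1) states.
#' @export
build_model_mwc <- function(n_sensors = 4, f = 1) {
  stopifnot(n_sensors >= 1, n_sensors <= 4, f > 0)
  n <- n_sensors
  cn <- paste0("C", 0:n); on <- paste0("O", 0:n)
  states <- data.frame(name = c(cn, on),
                       conducting = rep(c(FALSE, TRUE), each = n + 1))
  tr <- list()
  for (j in seq_len(n)) {
    tr[[length(tr) + 1]] <- data.frame(
      from = cn[j], to = cn[j + 1], kf = "a", kb = "b", z = "z", pf = 0.5,
      kf_scale = (n - j + 1), kb_scale = j, stringsAsFactors = FALSE)
    tr[[length(tr) + 1]] <- data.frame(
      from = on[j], to = on[j + 1], kf = "a", kb = "b", z = "z", pf = 0.5,
      kf_scale = (n - j + 1) * sqrt(f), kb_scale = j / sqrt(f),
      stringsAsFactors = FALSE)
  }
  for (j in 0:n) {
    tr[[length(tr) + 1]] <- data.frame(
      from = cn[j + 1], to = on[j + 1], kf = "ko", kb = "kc", z = NA, pf = 0.5,
      kf_scale = f^(j / 2), kb_scale = f^(-j / 2), stringsAsFactors = FALSE)
  }
  sc <- kinetic_scheme(name = sprintf("mwc%d", 2 * (n + 1)),
                       states = states, transitions = do.call(rbind, tr))
  attr(sc, "flags") <- list(st = TRUE, ze = TRUE, f = TRUE)
  sc
}

#' Default illustrative parameters for the MWC catalog model
#' @param VT thermal voltage in mV.
#' @return a `parameter_set` with `a`, `b`, `z`, `ko`, `kc`.
#' @export
params_mwc <- function(VT = 25.4) {
  parameter_set(c(a = 0.5, b = 100, z = 1.5, ko = 1, kc = 10), VT = VT)
}

#' Coupled-dimer model
#'
#' The four subunits act as two identical dimers; each dimer is resting
#' (r), activated (a) or flipped (f). Composite unordered-pair states
#' rr, ra, rf, aa, af, ff; the channel conducts only when both dimers are
#' flipped (ff). The r-a step is voltage dependent (`kra`/`kar`, charge
#' `zd`); the a-f flip is voltage independent (`kaf`/`kfa`). Transitions in
#' which either of two equivalent dimers may move carry a combinatorial
#' factor 2.
#'
#' @return a `kinetic_scheme` with 6 states.
#' @export
build_model_cd <- function() {
  states <- data.frame(
    name = c("rr", "ra", "rf", "aa", "af", "ff"),
    conducting = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  tr <- data.frame(
    from     = c("rr", "ra", "rf", "ra", "aa", "af"),
    to       = c("ra", "aa", "af", "rf", "af", "ff"),
    kf       = c("kra", "kra", "kra", "kaf", "kaf", "kaf"),
    kb       = c("kar", "kar", "kar", "kfa", "kfa", "kfa"),
    z        = c("zd", "zd", "zd", NA, NA, NA),
    pf       = 0.5,
    kf_scale = c(2, 1, 1, 1, 2, 1),
    kb_scale = c(1, 2, 1, 1, 1, 2),
    stringsAsFactors = FALSE)
  sc <- kinetic_scheme(name = "cd", states = states, transitions = tr)
  attr(sc, "flags") <- list(st = TRUE, ze = TRUE, f = FALSE)
  sc
}

#' Default illustrative parameters for the coupled-dimer catalog model
#' @param VT thermal voltage in mV.
#' @return a `parameter_set` with `kra`, `kar`, `zd`, `kaf`, `kfa`.
#' @export
params_cd <- function(VT = 25.4) {
  parameter_set(c(kra = 0.1, kar = 50, zd = 4, kaf = 5, kfa = 1), VT = VT)
}

#' Look up a catalog model by name
#'
#' @param name one of `"1n"`, `"1a"`, `"mwc10"`, `"cd"`.
#' @param ... passed to the specific builder.
#' @return list with elements `scheme` and `params` (constraints applied
#'   where the model has derived rates).
#' @export
catalog_model <- function(name, ...) {
  name <- match.arg(name, c("1n", "1a", "mwc10", "cd"))
  out <- switch(name,
    "1n" = list(scheme = build_model_1n(...), params = params_1n()),
    "1a" = list(scheme = build_model_1a(...), params = params_1a()),
    "mwc10" = list(scheme = build_model_mwc(4, ...), params = params_mwc()),
    "cd" = list(scheme = build_model_cd(), params = params_cd()))
  out$params <- apply_constraints(out$scheme, out$params)
  out
}
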