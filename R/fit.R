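#' Bundle open-probability traces for global fitting
#'
#' @param traces list; each element a list with `id` (label), `protocol`
#'   (a `voltage_protocol`), `times` (s, strictly increasing), `po` and
#'   `sigma` (per-point uncertainty, > 0).
#' @param condition free-text condition label (e.g. "no_cAMP").
#' @param n_patches optional per-trace patch counts (metadata).
#' @return an object of class `trace_set`.
#' @export
trace_set <- function(traces, condition = "", n_patches = NULL) {
  for (tr in traces) {
    stopifnot(!is.null(tr$protocol), length(tr$times) == length(tr$po),
              length(tr$sigma) %in% c(1, length(tr$po)))
    if (any(diff(tr$times) <= 0)) stop("trace times must be strictly increasing")
    if (any(tr$sigma <= 0)) stop("sigma must be positive")
    total <- sum(tr$protocol$segments$duration)
    if (max(tr$times) > total + 1e-9)
      stop("trace times extend beyond the protocol")
  }
  structure(list(traces = traces, condition = condition,
                 n_patches = n_patches),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  np <- sum(vapply(x$traces, function(t) length(t$times), integer(1)))
  cat("Trace set (", x$condition, "): ", length(x$traces), " traces, ",
      np, " samples\n", sep = "")
  invisible(x)
}

.traceset_fingerprint <- function(traceset) {
  c(n_traces = length(traceset$traces),
    n_points = sum(vapply(traceset$traces, function(t) length(t$times),
                          integer(1))),
    sum_po = sum(vapply(traceset$traces, function(t) sum(t$po), numeric(1))))
}

# Weighted residual vector (model - data)/sigma over all traces. A single
# propagator cache is shared across traces (protocols reuse few voltages).
.weighted_residuals <- function(traceset, scheme, params) {
  cache <- .prop_cache(scheme, params)
  unlist(lapply(traceset$traces, function(tr) {
    po <- .model_po_at(scheme, params, tr$protocol, tr$times, cache = cache)
    (po - tr$po) / tr$sigma
  }), use.names = FALSE)
}

#' Global-fit objective: RSS and normalized mean square error
#'
#' `RSS` is the plain residual sum of squares over every sample of every
#' trace; `MSE*` is the sigma-normalized mean square error,
#' \eqn{MSE^* = N^{-1}\sum (r_i/\sigma_i)^2}, which is ~1 when the model is
#' correct and the declared per-point uncertainties are accurate.
#'
#' @param traceset a `trace_set`.
#' @param scheme a `kinetic_scheme`.
#' @param params candidate `parameter_set` (constraints are applied here).
#' @return list with `rss`, `mse_star` and `n` (total number of samples).
#' @export
objective <- function(traceset, scheme, params) {
  params <- apply_constraints(scheme, params)
  cache <- .prop_cache(scheme, params)
  rss <- 0; wss <- 0; n <- 0
  for (tr in traceset$traces) {
    po <- .model_po_at(scheme, params, tr$protocol, tr$times, cache = cache)
    r <- po - tr$po
    rss <- rss + sum(r^2)
    wss <- wss + sum((r / tr$sigma)^2)
    n <- n + length(r)
  }
  list(rss = rss, mse_star = wss / n, n = n)
}

#' Specification of a global fit
#'
#' Rates are fitted in log space, gating charges linearly. Parameters named
#' in a `fixed` constraint of the scheme, and derived rates, are never free.
#'
#' @param scheme a `kinetic_scheme`.
#' @param params_init full `parameter_set` providing starting values and the
#'   values of fixed parameters.
#' @param free names of free parameters; default: all non-derived scheme
#'   parameters.
#' @param lower,upper named bounds. Defaults: rates in [1e-10, 1e8] s^-1,
#'   charges in [0, 12].
#' @param n_starts number of multistart launches (start 1 is `params_init`,
#'   the rest are seeded random perturbations).
#' @param seed integer seed controlling the random starts.
#' @param spread multistart spread: log10-scale s.d. for rates, absolute
#'   s.d. for charges.
#' @param maxit maximum Levenberg-Marquardt iterations per start.
#' @return an object of class `fit_spec`.
#' @export
fit_spec <- function(scheme, params_init, free = NULL,
                     lower = NULL, upper = NULL,
                     n_starts = 8, seed = 1, spread = 1, maxit = 150) {
  if (is.null(free)) free <- free_parameters(scheme)
  bad <- setdiff(free, names(params_init$values))
  if (length(bad)) stop("free parameters missing from params_init: ",
                        paste(bad, collapse = ", "))
  charges <- intersect(free, charge_parameters(scheme))
  rates <- setdiff(free, charges)
  lo <- c(stats::setNames(rep(1e-10, length(rates)), rates),
          stats::setNames(rep(0, length(charges)), charges))
  hi <- c(stats::setNames(rep(1e8, length(rates)), rates),
          stats::setNames(rep(12, length(charges)), charges))
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  structure(list(scheme = scheme, params_init = params_init, free = free,
                 rates = rates, charges = charges,
                 lower = lo[free], upper = hi[free],
                 n_starts = n_starts, seed = seed, spread = spread,
                 maxit = maxit),
            class = "fit_spec")
}

.theta_from_params <- function(spec, params) {
  v <- params$values[spec$free]
  v[spec$rates] <- log(v[spec$rates])
  v
}

.params_from_theta <- function(spec, theta) {
  v <- theta
  v[spec$rates] <- exp(v[spec$rates])
  set_params(spec$params_init, v)
}

.theta_bounds <- function(spec) {
  lo <- spec$lower; hi <- spec$upper
  lo[spec$rates] <- log(lo[spec$rates])
  hi[spec$rates] <- log(hi[spec$rates])
  list(lower = lo, upper = hi)
}

#' Global multi-trace least-squares fit
#'
#' Fits the free parameters of a scheme to every trace of a `trace_set`
#' simultaneously by weighted least squares (residuals divided by the
#' per-point sigma), using multistart Levenberg-Marquardt over
#' log-transformed rates and linear charges. Detailed-balance and
#' saturating-P_o constraints are enforced by construction (derived rates
#' are recomputed for every candidate), never penalized. Deterministic for
#' a fixed seed.
#'
#' @param traceset a `trace_set`.
#' @param spec a `fit_spec`.
#' @param verbose print per-start progress.
#' @return an object of class `fit_result`: best `params` (constraints
#'   applied), `theta`, `rss`, `mse_star`, `se_percent`, `nd` flags,
#'   `covariance`, `n`, `p`, `nd_p`, per-start diagnostics in `starts`.
#' @export
global_fit <- function(traceset, spec, verbose = FALSE) {
  stopifnot(inherits(traceset, "trace_set"), inherits(spec, "fit_spec"))
  n_obs <- sum(vapply(traceset$traces, function(t) length(t$times), integer(1)))
  resfun <- function(theta) {
    names(theta) <- spec$free
    r <- tryCatch({
      params <- apply_constraints(spec$scheme, .params_from_theta(spec, theta))
      .weighted_residuals(traceset, spec$scheme, params)
    }, error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) rep(1e6, n_obs) else r
  }
  if (length(spec$free) == 0) {
    params <- apply_constraints(spec$scheme, spec$params_init)
    obj <- objective(traceset, spec$scheme, spec$params_init)
    return(structure(list(params = params, theta = numeric(0),
                          rss = obj$rss, mse_star = obj$mse_star,
                          se_percent = numeric(0), nd = logical(0),
                          covariance = matrix(0, 0, 0), n = obj$n, p = 0,
                          nd_p = 0, starts = list(), spec = spec,
                          fingerprint = .traceset_fingerprint(traceset)),
                     class = "fit_result"))
  }
  bounds <- .theta_bounds(spec)
  theta0 <- .theta_from_params(spec, spec$params_init)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  starts <- list(theta0)
  if (spec$n_starts > 1) {
    for (s in 2:spec$n_starts) {
      th <- theta0
      th[spec$rates] <- th[spec$rates] +
        stats::rnorm(length(spec$rates), 0, spec$spread * log(10))
      th[spec$charges] <- th[spec$charges] +
        stats::rnorm(length(spec$charges), 0, spec$spread)
      starts[[s]] <- pmin(pmax(th, bounds$lower), bounds$upper)
    }
  }
  runs <- vector("list", length(starts))
  best <- NULL
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[s]], fn = resfun,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = spec$maxit, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      runs[[s]] <- list(ok = FALSE, message = conditionMessage(fit))
      next
    }
    runs[[s]] <- list(ok = TRUE, deviance = fit$deviance,
                      niter = fit$niter, info = fit$info)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (verbose) message(sprintf("start %d: deviance %.6g (%d iter)",
                                 s, fit$deviance, fit$niter))
  }
  if (is.null(best))
    stop("fit failure: all multistart launches failed; see per-start log")
  theta <- stats::setNames(best$par, spec$free)
  params <- apply_constraints(spec$scheme, .params_from_theta(spec, theta))
  obj <- objective(traceset, spec$scheme, params)
  out <- structure(list(params = params, theta = theta,
                        rss = obj$rss, mse_star = obj$mse_star,
                        n = obj$n, p = length(spec$free),
                        starts = runs, spec = spec,
                        fingerprint = .traceset_fingerprint(traceset)),
                   class = "fit_result")
  err <- parameter_errors(out, traceset)
  out$se_percent <- err$se_percent
  out$nd <- err$nd
  out$covariance <- err$covariance
  out$nd_p <- sum(out$nd)
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Global fit ('", x$spec$scheme$name, "'): RSS = ", signif(x$rss, 5),
      ", MSE* = ", signif(x$mse_star, 5), ", p = ", x$p,
      ", n.d. = ", x$nd_p, "\n", sep = "")
  if (x$p > 0) {
    v <- x$params$values[x$spec$free]
    tab <- data.frame(value = signif(v, 4),
                      se_percent = round(x$se_percent, 1),
                      nd = x$nd)
    print(tab)
  }
  invisible(x)
}

#' Asymptotic standard errors of fitted parameters
#'
#' Curvature-based errors from the Jacobian of the weighted residual vector
#' at the optimum: \eqn{cov = s^2 (J^T J)^{-1}} with
#' \eqn{s^2 = RSS_w/(N - p)}. Errors are reported as percent of the
#' parameter value (for log-fitted rates the delta method gives
#' se% = 100 x se of the log-parameter). A parameter is flagged not
#' determined (n.d.) when its se exceeds 60% or the curvature is singular
#' along its direction.
#'
#' @param fit a `fit_result`.
#' @param traceset the `trace_set` the fit was run on.
#' @return list with `se_percent`, `nd`, `covariance` and `rank`.
#' @export
parameter_errors <- function(fit, traceset) {
  spec <- fit$spec
  p <- length(spec$free)
  if (p == 0)
    return(list(se_percent = numeric(0), nd = logical(0),
                covariance = matrix(0, 0, 0), rank = 0))
  theta <- fit$theta
  f0 <- .weighted_residuals(traceset, spec$scheme, fit$params)
  n <- length(f0)
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    rp <- .weighted_residuals(traceset, spec$scheme,
                              apply_constraints(spec$scheme,
                                                .params_from_theta(spec, tp)))
    rm <- .weighted_residuals(traceset, spec$scheme,
                              apply_constraints(spec$scheme,
                                                .params_from_theta(spec, tm)))
    J[, j] <- (rp - rm) / (2 * h)
  }
  JtJ <- crossprod(J)
  s2 <- sum(f0^2) / max(n - p, 1)
  qrj <- qr(JtJ)
  rank <- qrj$rank
  cov <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
  if (is.null(cov)) {
    se_theta <- rep(Inf, p)
    cov <- matrix(NA_real_, p, p)
  } else {
    d <- diag(cov)
    se_theta <- ifelse(d >= 0, sqrt(d), Inf)
  }
  names(se_theta) <- spec$free
  se_pct <- numeric(p); names(se_pct) <- spec$free
  se_pct[spec$rates] <- 100 * se_theta[spec$rates]
  vals <- fit$params$values[spec$charges]
  se_pct[spec$charges] <- 100 * se_theta[spec$charges] /
    pmax(abs(vals), .Machine$double.eps)
  nd <- !is.finite(se_pct) | se_pct > 60
  list(se_percent = se_pct, nd = nd, covariance = cov, rank = rank)
}

#' Rank competing model fits on one trace set
#'
#' @param fits named list of `fit_result`s obtained on the same trace set.
#' @return data.frame sorted by `MSE*` (ties broken by fewer free
#'   parameters, then fewer n.d. parameters): model, st/ze/f flags, summed
#'   gating charge, p, nd_p, RSS, MSE*.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$scheme$name, character(1))
  fps <- lapply(fits, `[[`, "fingerprint")
  if (length(fits) > 1 &&
      !all(vapply(fps[-1], function(f) isTRUE(all.equal(f, fps[[1]])),
                  logical(1))))
    stop("inconsistent ranking: fits were obtained on different trace sets")
  row <- function(nm) {
    f <- fits[[nm]]
    fl <- attr(f$spec$scheme, "flags")
    if (is.null(fl)) fl <- list(st = NA, ze = NA, f = NA)
    zn <- charge_parameters(f$spec$scheme)
    sumz <- if (length(zn)) sum(f$params$values[zn]) else 0
    data.frame(model = nm, st = fl$st, ze = fl$ze, f = fl$f,
               sumz = sumz, p = f$p, nd_p = f$nd_p,
               rss = f$rss, mse_star = f$mse_star,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(names(fits), row))
  tab <- tab[order(tab$mse_star, tab$p, tab$nd_p), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
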