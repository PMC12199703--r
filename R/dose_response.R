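#' Two-parameter log-logistic effect (LL.4 with limits fixed at 0 and 1)
#'
#' Evaluates the log-logistic dose-response curve
#' \deqn{E(c) = \frac{1}{1 + (e/c)^h}}
#' where `e` is the EC50 and `h > 0` the slope in the increasing-effect
#' convention (equal to minus the classical LL.4 slope parameter `b`).
#' The lower and upper limits are fixed at 0 and 1, so `E(e) = 0.5` exactly
#' and `E(0) = 0` by continuity.
#'
#' @param concentration numeric vector of concentrations (ug/l), each >= 0.
#' @param slope positive slope `h` (dimensionless).
#' @param ec50 positive EC50 `e` (same units as `concentration`).
#' @return numeric vector of effect fractions in `[0, 1]`.
#' @examples
#' ll4_effect(10, slope = 2, ec50 = 10)  # 0.5
#' ll4_effect(20, slope = 2, ec50 = 10)  # 0.8
#' @export
ll4_effect <- function(concentration, slope, ec50) {
  if (!is.numeric(concentration) || any(!is.finite(concentration)))
    stop("'concentration' must be finite numeric", call. = FALSE)
  if (any(concentration < 0))
    stop("'concentration' must be >= 0", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0)
    stop("'slope' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(ec50) || length(ec50) != 1L || !is.finite(ec50) || ec50 <= 0)
    stop("'ec50' must be a single positive finite number", call. = FALSE)
  out <- numeric(length(concentration))
  pos <- concentration > 0
  # plogis(h * (log c - log e)) is the numerically stable form of 1/(1+(e/c)^h)
  out[pos] <- stats::plogis(slope * (log(concentration[pos]) - log(ec50)))
  out
}

# Internal: aggregate immobility records into a per-well data.frame with
# columns conc, n, y, keeping wells (rows) as the sampling unit.
.wells_from_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("conc_ug_per_l", "n_exposed", "n_immobile")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "), call. = FALSE)
  data.frame(conc = records$conc_ug_per_l,
             n = records$n_exposed,
             y = records$n_immobile)
}

# Internal: negative binomial log-likelihood and gradient for the LL.4 model
# on (log h, log e). eta_i = h (log c_i - log e); p_i = plogis(eta_i).
.ll4_negloglik <- function(par, dat) {
  logc <- dat$logc; n <- dat$n; y <- dat$y
  h <- exp(par[1L]); loge <- par[2L]
  eta <- h * (logc - loge)
  # y*log p + (n-y)*log(1-p) via log-plogis for stability
  -sum(y * stats::plogis(eta, log.p = TRUE) +
       (n - y) * stats::plogis(-eta, log.p = TRUE))
}

.ll4_neggrad <- function(par, dat) {
  logc <- dat$logc; n <- dat$n; y <- dat$y
  h <- exp(par[1L]); loge <- par[2L]
  eta <- h * (logc - loge)
  p <- stats::plogis(eta)
  r <- y - n * p                      # dl/deta per well
  # deta/dlogh = eta, deta/dloge = -h
  -c(sum(r * eta), -h * sum(r))
}

#' Fit the log-logistic dose-response curve to immobility counts
#'
#' Maximum-likelihood fit of the log-logistic curve with limits fixed at 0 and
#' 1 (see [ll4_effect()]) to per-well binomial immobility counts. The binomial
#' log-likelihood is maximized over `(log h, log e)` with an analytic gradient
#' and multiple starting values drawn from a coarse grid, so the fit is
#' invariant to the `(h, e)` vs `(log h, log e)` parameterization and robust
#' to poor single starts.
#'
#' Wells at concentration 0 do not enter the fit (the lower limit is fixed at
#' 0); they trigger a warning when control immobility exceeds 10%, the usual
#' acceptability bound for acute immobilization tests.
#'
#' @param records data.frame of immobility records with columns
#'   `condition`, `timepoint_h`, `conc_ug_per_l`, `n_exposed`, `n_immobile`
#'   (see [read_immobility_csv()]); or any data.frame with the last three
#'   columns. Should contain one condition and one timepoint; use `condition`
#'   and `timepoint` to filter first.
#' @param condition optional condition label to filter on.
#' @param timepoint optional timepoint (hours) to filter on.
#' @return an object of class `ll4_fit`: a list with elements `slope`, `ec50`,
#'   `lower_limit` (0), `upper_limit` (1), `covariance` (2x2, on
#'   `(log h, log e)`, scaled by the dispersion floored at 1), `dispersion`
#'   (raw Pearson estimate), `residual_df`, `n_observations`, `loglik`,
#'   `fitted` (per-well fitted probabilities), `wells` (the fitting data),
#'   `converged`, `condition`, `timepoint`.
#' @seealso [estimate_dispersion()], [compare_ec50()], [fit_particle_curve()]
#' @export
fit_ll4 <- function(records, condition = NULL, timepoint = NULL) {
  if (!is.null(condition) && "condition" %in% names(records))
    records <- records[records$condition %in% condition, , drop = FALSE]
  if (!is.null(timepoint) && "timepoint_h" %in% names(records))
    records <- records[records$timepoint_h %in% timepoint, , drop = FALSE]
  wells <- .wells_from_records(records)
  if (any(wells$y > wells$n) || any(wells$y < 0) || any(wells$n <= 0))
    stop("invalid counts: need 0 <= n_immobile <= n_exposed, n_exposed > 0",
         call. = FALSE)
  ctrl <- wells[wells$conc == 0, , drop = FALSE]
  if (nrow(ctrl) && sum(ctrl$y) / sum(ctrl$n) > 0.10)
    warning(sprintf("control immobility %.0f%% exceeds the 10%% acceptability bound",
                    100 * sum(ctrl$y) / sum(ctrl$n)), call. = FALSE)
  wells <- wells[wells$conc > 0, , drop = FALSE]
  if (length(unique(wells$conc)) < 3L)
    stop("need >= 3 distinct positive concentrations to fit", call. = FALSE)
  if (sum(wells$y) == 0L)
    stop("degenerate data: no immobile animals at any concentration", call. = FALSE)
  if (sum(wells$y) == sum(wells$n))
    stop("degenerate data: complete immobility at every concentration", call. = FALSE)

  logc <- log(wells$conc)
  fit <- .optimize_multistart(
    .ll4_negloglik, .ll4_neggrad,
    h_grid = c(1, 2.5, 6),
    loge_grid = log(c(min(wells$conc), exp(mean(range(logc))), max(wells$conc))),
    dat = list(logc = logc, n = wells$n, y = wells$y))

  h <- exp(fit$par[1L]); e <- exp(fit$par[2L])
  p_hat <- ll4_effect(wells$conc, h, e)
  out <- .finish_fit(fit, wells, p_hat,
                     condition = if (!is.null(condition)) condition
                                 else unique(as.character(records$condition))[1L],
                     timepoint = if (!is.null(timepoint)) timepoint
                                 else unique(records$timepoint_h)[1L])
  out$slope <- h
  out$ec50 <- e
  out
}

# Internal: shared multistart BFGS driver over (log h, log e)-shaped problems.
# Starts combine a fixed coarse grid with the best cells of a likelihood scan
# over a widened (slope, EC50) box, so ridge-shaped surfaces (e.g. the
# additivity particle fit when its component is weakly identified) cannot trap
# every start on a boundary plateau.
.optimize_multistart <- function(negll, neggrad, h_grid, loge_grid, dat) {
  scan <- expand.grid(
    logh = seq(log(0.3), log(40), length.out = 15L),
    loge = seq(min(loge_grid) - log(5), max(loge_grid) + log(20),
               length.out = 25L))
  scan_val <- vapply(seq_len(nrow(scan)),
                     function(i) negll(as.numeric(scan[i, ]), dat), numeric(1L))
  top <- scan[order(scan_val)[1:3], ]
  starts <- rbind(expand.grid(logh = log(h_grid), loge = loge_grid), top)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), negll, neggrad, dat = dat,
                   method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  if (is.null(best))
    stop("optimizer failed to converge from every start", call. = FALSE)
  # Newton polish: drive the gradient norm towards machine precision
  par <- best$par; val <- best$value
  for (iter in 1:25) {
    g <- neggrad(par, dat)
    if (sqrt(sum(g^2)) < 1e-10) break
    H <- stats::optimHess(par, negll, neggrad, dat = dat)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    vc <- negll(cand, dat)
    if (!is.finite(vc) || vc > val + 1e-9) {   # halve once, then give up
      cand <- par - step / 2
      vc <- negll(cand, dat)
      if (!is.finite(vc) || vc > val + 1e-9) break
    }
    par <- cand; val <- vc
  }
  best$par <- par; best$value <- val
  g <- neggrad(best$par, dat)
  if (sqrt(sum(g^2)) > 1e-3 * max(1, abs(best$value)))
    warning(sprintf("gradient norm %.2e at optimum; fit may be on a flat likelihood",
                    sqrt(sum(g^2))), call. = FALSE)
  hess <- stats::optimHess(best$par, negll, neggrad, dat = dat)
  list(par = best$par, value = best$value, hessian = hess,
       converged = best$convergence == 0L)
}

# Internal: assemble an ll4_fit object from optimizer output and fitted probs.
.finish_fit <- function(fit, wells, p_hat, condition, timepoint) {
  residual_df <- nrow(wells) - 2L
  if (residual_df <= 0L)
    stop("residual degrees of freedom <= 0: too few wells", call. = FALSE)
  pearson <- sum((wells$y - wells$n * p_hat)^2 /
                 pmax(wells$n * p_hat * (1 - p_hat), .Machine$double.eps))
  dispersion <- pearson / residual_df
  vcov_raw <- tryCatch(solve(fit$hessian), error = function(e) {
    warning("singular information matrix; covariance unavailable", call. = FALSE)
    matrix(NA_real_, 2L, 2L)
  })
  covariance <- max(dispersion, 1) * vcov_raw   # never deflate variances
  dimnames(covariance) <- list(c("log_slope", "log_ec50"),
                               c("log_slope", "log_ec50"))
  structure(list(
    lower_limit = 0, upper_limit = 1,
    covariance = covariance,
    dispersion = dispersion,
    residual_df = residual_df,
    n_observations = nrow(wells),
    loglik = -fit$value,
    fitted = p_hat,
    wells = wells,
    converged = fit$converged,
    condition = condition,
    timepoint = timepoint
  ), class = "ll4_fit")
}

#' Pearson overdispersion estimate for a fitted curve
#'
#' Quasi-likelihood dispersion scale: the Pearson chi-square of the per-well
#' residuals divided by the residual degrees of freedom (number of wells minus
#' the two fitted parameters). Values near 1 indicate binomial variation;
#' values above 1 extra-binomial (e.g. clustered) variation. For inference the
#' package floors the scale at 1 so that variances are never deflated; the raw
#' value is returned here.
#'
#' @param curve an `ll4_fit` object.
#' @param records optional immobility records to recompute against; defaults
#'   to the wells stored in the fit.
#' @return the raw dispersion scale (>= 0).
#' @export
estimate_dispersion <- function(curve, records = NULL) {
  stopifnot(inherits(curve, "ll4_fit"))
  if (is.null(records)) {
    wells <- curve$wells
    p_hat <- curve$fitted
  } else {
    wells <- .wells_from_records(records)
    wells <- wells[wells$conc > 0, , drop = FALSE]
    p_hat <- if (!is.null(curve$effect_fn)) curve$effect_fn(wells$conc)
             else ll4_effect(wells$conc, curve$slope, curve$ec50)
  }
  residual_df <- nrow(wells) - 2L
  if (residual_df <= 0L) stop("residual degrees of freedom <= 0", call. = FALSE)
  sum((wells$y - wells$n * p_hat)^2 /
      pmax(wells$n * p_hat * (1 - p_hat), .Machine$double.eps)) / residual_df
}

#' Compare two EC50 estimates on the log-ratio scale
#'
#' Wald t-test of equality of EC50s from two independently fitted curves, on
#' the log scale: the statistic is the difference of log EC50s divided by the
#' square root of the summed variances (each already scaled by its fit's
#' dispersion, floored at 1). The two-sided p-value uses a t reference
#' distribution with the combined residual degrees of freedom. The ratio
#' `ec50_A / ec50_B` and the standard error of its log are reported.
#'
#' @param curve_A,curve_B `ll4_fit` objects fitted on disjoint data sets.
#' @return an object of class `ec50_comparison`: list with `ratio`,
#'   `se_log_ratio`, `statistic`, `df`, `p_value`.
#' @export
compare_ec50 <- function(curve_A, curve_B) {
  stopifnot(inherits(curve_A, "ll4_fit"), inherits(curve_B, "ll4_fit"))
  va <- curve_A$covariance["log_ec50", "log_ec50"]
  vb <- curve_B$covariance["log_ec50", "log_ec50"]
  if (!is.finite(va) || !is.finite(vb))
    stop("missing covariance on one of the curves", call. = FALSE)
  d <- log(curve_A$ec50) - log(curve_B$ec50)
  se <- sqrt(va + vb)
  df <- curve_A$residual_df + curve_B$residual_df
  stat <- d / se
  structure(list(
    ratio = exp(d),
    se_log_ratio = se,
    statistic = stat,
    df = df,
    p_value = 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  ), class = "ec50_comparison")
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat("Log-logistic dose-response fit (limits fixed at 0 and 1)\n")
  if (!is.null(x$condition) && !is.na(x$condition))
    cat(sprintf("  condition: %s   timepoint: %s h\n", x$condition,
                format(x$timepoint)))
  se_e <- sqrt(x$covariance["log_ec50", "log_ec50"])
  cat(sprintf("  slope h  : %.3f\n", x$slope))
  cat(sprintf("  EC50     : %.3f ug/l (SE of log EC50: %.3f)\n", x$ec50, se_e))
  cat(sprintf("  dispersion: %.3f on %d df (%d wells)\n",
              x$dispersion, x$residual_df, x$n_observations))
  invisible(x)
}

#' @export
print.ec50_comparison <- function(x, ...) {
  cat("EC50 comparison (log-ratio Wald t-test)\n")
  cat(sprintf("  ratio A/B : %.3f (SE log ratio %.3f)\n", x$ratio, x$se_log_ratio))
  cat(sprintf("  t = %.3f on %d df, two-sided p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Plot a fitted dose-response curve with observed well proportions
#'
#' @param x an `ll4_fit` object.
#' @param n_grid number of points on the curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ll4_fit <- function(x, n_grid = 200L, ...) {
  w <- x$wells
  cc <- exp(seq(log(min(w$conc)) - 0.5, log(max(w$conc)) + 0.5,
                length.out = n_grid))
  eff <- if (!is.null(x$effect_fn)) x$effect_fn(cc)
         else ll4_effect(cc, x$slope, x$ec50)
  graphics::plot(w$conc, w$y / w$n, log = "x", ylim = c(0, 1),
                 xlab = "concentration (ug/l)", ylab = "fraction immobile", ...)
  graphics::lines(cc, eff)
  graphics::abline(v = x$ec50, h = 0.5, lty = 3, col = "grey50")
  invisible(x)
}
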