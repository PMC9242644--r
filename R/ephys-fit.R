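#' Single-exponential fit (activation or decay)
#'
#' Least-squares fit of `y = offset + amplitude * (1 - exp(-t/tau))`
#' (activation) or `y = offset + amplitude * exp(-t/tau)` (decay).
#' Initialization comes from a log-linear regression on the detrended signal;
#' the refinement uses Levenberg-Marquardt. The time origin is taken as given:
#' for tail currents pass time relative to the repolarization onset so the
#' amplitude parameter is the extrapolated onset amplitude.
#'
#' Non-convergence (including constant traces) is reported via
#' `converged = FALSE` with a diagnostic, never as an error.
#'
#' @param t Time vector, strictly increasing, length >= 20.
#' @param y Current samples, same length.
#' @param kind `"activation"` or `"decay"`.
#' @return A list of class `kinetics_fit`: `amplitude`, `tau`, `offset`,
#'   `rmse`, `converged`, `message`.
#' @export
fit_exponential <- function(t, y, kind = c("activation", "decay")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  if (length(t) < 20) stop("need >= 20 samples")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  failed <- function(msg) {
    structure(list(amplitude = NA_real_, tau = NA_real_,
                   offset = mean(y), rmse = stats::sd(y),
                   converged = FALSE, message = msg),
              class = "kinetics_fit")
  }
  if (stats::sd(y) == 0) return(failed("constant trace: nothing to fit"))

  n <- length(y)
  n_tail <- max(5L, round(0.1 * n))
  plateau <- mean(y[(n - n_tail + 1):n])
  z <- if (kind == "decay") y - plateau else plateau - y
  # initial tau from the integral identity  int z dt = amplitude * tau
  # (mean-zero noise integrates out, unlike a log-linear slope at low SNR)
  a0 <- mean(z[seq_len(min(5L, n))])
  tau0 <- sum(z) * mean(diff(t)) / a0
  span <- max(t) - min(t)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- span / 5
  tau0 <- min(max(tau0, span / 1000), 2 * span)
  if (kind == "decay") {
    start <- list(offset = plateau, amplitude = z[1], tau = tau0)
    form <- y ~ offset + amplitude * exp(-t / tau)
  } else {
    start <- list(offset = y[1], amplitude = plateau - y[1], tau = tau0)
    form <- y ~ offset + amplitude * (1 - exp(-t / tau))
  }
  dat <- data.frame(t = t, y = y)
  tau_floor <- min(diff(t)) / 10   # below the sample interval tau is meaningless
  try_fit <- function(start, ctrl) tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = c(offset = -Inf, amplitude = -Inf,
                                tau = tau_floor),
                      control = ctrl),
    error = function(e) NULL
  )
  tight <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)
  fit <- try_fit(start, tight)
  if (is.null(fit)) fit <- try_fit(start, minpack.lm::nls.lm.control(maxiter = 500))
  for (fac in c(0.25, 4)) {
    if (!is.null(fit)) break
    start2 <- start; start2$tau <- tau0 * fac
    fit <- try_fit(start2, tight)
  }
  if (is.null(fit)) return(failed("optimizer failed"))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["tau"]] <= 0) {
    return(failed("fit did not yield a positive time constant"))
  }
  structure(
    list(amplitude = unname(cf[["amplitude"]]), tau = unname(cf[["tau"]]),
         offset = unname(cf[["offset"]]),
         rmse = sqrt(mean(stats::resid(fit)^2)),
         converged = TRUE, message = "ok"),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit> amplitude=%.4g  tau=%.4g s  offset=%.4g  rmse=%.3g  %s\n",
    x$amplitude, x$tau, x$offset, x$rmse,
    if (x$converged) "converged" else paste0("NOT converged (", x$message, ")")
  ))
  invisible(x)
}

#' Kinetic and amplitude metrics of one sweep family
#'
#' At the reference voltage: `i_max` is the mean of the last 5% of pulse
#' samples (a steady-state reading, robust to noise); `tau_act` comes from an
#' activation fit over the pulse; the tail is fitted as a decaying exponential
#' after blanking the first 5 ms (capacitance transient), with time passed
#' relative to the repolarization onset so the fitted amplitude is the
#' extrapolated onset tail amplitude `i_tail`.
#'
#' @param fam A `sweep_family`.
#' @param v_ref Reference step voltage, mV; must be one of the family's steps.
#' @param blank_s Tail samples within this window after repolarization are
#'   excluded from the fit.
#' @param steady_frac Fraction of the pulse, from the end, averaged for
#'   `i_max`.
#' @return List: `i_max`, `i_tail`, `tau_act`, `tau_deact`, plus the two
#'   `kinetics_fit` objects (`act_fit`, `tail_fit`).
#' @export
family_metrics <- function(fam, v_ref = 140, blank_s = 0.005,
                           steady_frac = 0.05) {
  stopifnot(inherits(fam, "sweep_family"))
  k <- match(as.character(v_ref), colnames(fam$sweeps))
  if (is.na(k)) {
    stop("v_ref = ", v_ref, " mV is not among the family's step voltages")
  }
  y <- fam$sweeps[, k]
  pulse <- fam$segments$pulse
  tail_idx <- fam$segments$tail
  dt <- fam$meta$protocol$dt

  n_steady <- max(1L, ceiling(steady_frac * length(pulse)))
  i_max <- mean(y[pulse[(length(pulse) - n_steady + 1):length(pulse)]])

  t_pulse <- dt * seq_along(pulse)
  act_fit <- fit_exponential(t_pulse, y[pulse], kind = "activation")

  t_tail <- dt * seq_along(tail_idx)   # relative to repolarization onset
  keep <- t_tail > blank_s
  tail_fit <- fit_exponential(t_tail[keep], y[tail_idx][keep], kind = "decay")

  list(i_max = i_max,
       i_tail = if (tail_fit$converged) tail_fit$amplitude else NA_real_,
       tau_act = if (act_fit$converged) act_fit$tau else NA_real_,
       tau_deact = if (tail_fit$converged) tail_fit$tau else NA_real_,
       act_fit = act_fit, tail_fit = tail_fit)
}

#' Late/early inhibition ratios from two recordings of one cell
#'
#' Ratio of current magnitudes between a late recording (e.g. 3 min after
#' break-in, when dialysis inhibition has reached steady state) and an early
#' one (e.g. 30 s), for both the steady-state pulse current and the
#' extrapolated tail amplitude. One ratio pair per cell.
#'
#' @param fam_late,fam_early `sweep_family` objects recorded with the same
#'   protocol; `t_breakin(late) > t_breakin(early)`.
#' @param v_ref Reference voltage, mV.
#' @return List: `max_ratio`, `tail_ratio` (magnitude ratios, late/early).
#' @export
inhibition_ratio <- function(fam_late, fam_early, v_ref = 140) {
  stopifnot(inherits(fam_late, "sweep_family"),
            inherits(fam_early, "sweep_family"))
  pl <- fam_late$meta$protocol; pe <- fam_early$meta$protocol
  same <- isTRUE(all.equal(pl$step_v, pe$step_v)) &&
    isTRUE(all.equal(c(pl$pulse_s, pl$tail_s, pl$dt, pl$holding_v),
                     c(pe$pulse_s, pe$tail_s, pe$dt, pe$holding_v)))
  if (!same) stop("sweep families use different protocols")
  if (!(fam_late$meta$t_breakin > fam_early$meta$t_breakin)) {
    stop("late family must be recorded after the early one")
  }
  ml <- family_metrics(fam_late, v_ref)
  me <- family_metrics(fam_early, v_ref)
  if (!is.finite(me$i_max) || abs(me$i_max) < .Machine$double.eps^0.5) {
    stop("early maximum current is zero; ratio undefined")
  }
  if (!is.finite(me$i_tail) || abs(me$i_tail) < .Machine$double.eps^0.5) {
    stop("early tail amplitude is zero; ratio undefined")
  }
  list(max_ratio = abs(ml$i_max / me$i_max),
       tail_ratio = abs(ml$i_tail / me$i_tail))
}

#' Hill dose-response fit
#'
#' Least-squares fit of
#' \eqn{f(c) = floor + (ceiling - floor)\, c^n / (c^n + EC_{50}^n)}.
#' Initialization: `ec50` at the concentration whose response is nearest
#' half-maximal, `n = 1`, floor/ceiling from the response extremes. The design
#' must bracket the apparent midpoint (at least one concentration below and
#' one above it).
#'
#' @param conc Concentrations, uM (>= 4 distinct values, all >= 0).
#' @param response Responses (e.g. fractional inhibition), same length.
#' @param fix_floor Optionally pin the floor (e.g. 0 when the zero-dose
#'   response is a true blank).
#' @return A list of class `dose_response_fit`: `ec50`, `hill_n`, `floor`,
#'   `ceiling`, `rmse`.
#' @export
fit_dose_response <- function(conc, response, fix_floor = NULL) {
  stopifnot(is.numeric(conc), is.numeric(response),
            length(conc) == length(response))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (length(unique(conc)) < 4) {
    stop("need >= 4 distinct concentrations, got ", length(unique(conc)))
  }
  r_mid <- (min(response) + max(response)) / 2
  by_c <- tapply(response, conc, mean)
  cs <- as.numeric(names(by_c))
  ec50_0 <- cs[which.min(abs(as.numeric(by_c) - r_mid))]
  if (ec50_0 <= 0) ec50_0 <- min(cs[cs > 0])
  if (!any(conc < ec50_0) || !any(conc > ec50_0)) {
    stop("non-bracketing design: need concentrations below and above the ",
         "apparent midpoint (", signif(ec50_0, 3), " uM)")
  }
  dat <- data.frame(conc = conc, response = response)
  if (is.null(fix_floor)) {
    form <- response ~ floor + (ceiling - floor) * conc^n / (conc^n + ec50^n)
    start <- list(floor = min(response), ceiling = max(response),
                  ec50 = ec50_0, n = 1)
    lower <- c(floor = -Inf, ceiling = -Inf, ec50 = 1e-9, n = 0.05)
    upper <- c(floor = Inf, ceiling = Inf, ec50 = Inf, n = 10)
  } else {
    dat$floor_fixed <- fix_floor
    form <- response ~ floor_fixed + (ceiling - floor_fixed) * conc^n /
      (conc^n + ec50^n)
    start <- list(ceiling = max(response), ec50 = ec50_0, n = 1)
    lower <- c(ceiling = -Inf, ec50 = 1e-9, n = 0.05)
    upper <- c(ceiling = Inf, ec50 = Inf, n = 10)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(fit)) fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("dose-response fit failed: ", conditionMessage(e))
  )
  cf <- stats::coef(fit)
  floor_v <- if (is.null(fix_floor)) unname(cf[["floor"]]) else fix_floor
  out <- list(ec50 = unname(cf[["ec50"]]), hill_n = unname(cf[["n"]]),
              floor = floor_v, ceiling = unname(cf[["ceiling"]]),
              rmse = sqrt(mean(stats::resid(fit)^2)))
  if (out$ceiling < out$floor) {
    stop("dose-response fit collapsed: ceiling below floor")
  }
  structure(out, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> EC50=%.4g uM  n=%.3g  floor=%.3g  ceiling=%.3g  rmse=%.3g\n",
    x$ec50, x$hill_n, x$floor, x$ceiling, x$rmse
  ))
  invisible(x)
}
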