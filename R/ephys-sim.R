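#' Gating parameters of the simulated outward rectifier
#'
#' A deliberately minimal phenomenology of a slowly gating, outwardly
#' rectifying transporter current: Boltzmann steady-state activation
#' \eqn{p_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/k})}, mono-exponential
#' relaxation with a voltage-dependent time constant
#' \eqn{\tau_{act}(V) = \tau_0 e^{-V/V_\tau}}, and mono-exponential
#' deactivation at the holding potential.
#'
#' @param g_max Conductance scale, nS.
#' @param v_rev Reversal potential, mV.
#' @param v_half Activation midpoint, mV.
#' @param k_slope Boltzmann slope, mV (> 0).
#' @param tau0 Activation time constant at 0 mV, s.
#' @param v_tau Voltage scale of the time-constant decay, mV.
#' @param tau_deact Deactivation time constant at holding, s.
#' @param i_inst_frac Instantaneous fraction of the pulse current (0..1).
#' @return A list of class `gating_params`.
#' @export
gating_params <- function(g_max = 5, v_rev = 0, v_half = 80, k_slope = 25,
                          tau0 = 1, v_tau = 200, tau_deact = 0.08,
                          i_inst_frac = 0.1) {
  if (g_max < 0 || k_slope <= 0 || tau0 <= 0 || v_tau <= 0 || tau_deact <= 0) {
    stop("gating_params requires g_max >= 0 and positive k_slope/tau values")
  }
  if (i_inst_frac < 0 || i_inst_frac > 1) stop("i_inst_frac must be in [0, 1]")
  structure(list(g_max = g_max, v_rev = v_rev, v_half = v_half,
                 k_slope = k_slope, tau0 = tau0, v_tau = v_tau,
                 tau_deact = tau_deact, i_inst_frac = i_inst_frac),
            class = "gating_params")
}

tau_act_of_v <- function(g, v) g$tau0 * exp(-v / g$v_tau)
p_inf_of_v <- function(g, v) 1 / (1 + exp(-(v - g$v_half) / g$k_slope))

#' Dialysis inhibition model
#'
#' After break-in, an inhibitor in the pipette washes into the cell with time
#' constant `tau_wash`; its maximal effect at concentration `c` follows a Hill
#' law, and the momentary scale applied to the current is
#' \eqn{s(c, t) = 1 - f_{max}(c)\,(1 - e^{-t/\tau_{wash}})}.
#' The pulse (maximum-current) and tail-current readouts carry separate
#' ceilings, `f_ceiling` and `f_ceiling_tail`, because the lipid affects the
#' deactivation gate over and above its effect on the activated conductance:
#' tail amplitudes are suppressed more strongly than pulse currents. Defaults
#' are calibrated so that a saturating 100 uM dialysis yields late/early
#' current ratios of about 0.61 (pulse) and 0.34 (tail) between 30 s and
#' 3 min after break-in.
#'
#' @param ec50 Half-maximal concentration, uM.
#' @param hill_n Hill coefficient (> 0).
#' @param f_ceiling Maximal fractional inhibition of the pulse conductance
#'   (0..1).
#' @param f_ceiling_tail Maximal fractional inhibition of the tail amplitude
#'   (0..1).
#' @param tau_wash Dialysis time constant, s.
#' @param deact_speedup Factor (< 1) applied to the deactivation time constant
#'   when the inhibitor is present.
#' @return A list of class `inhibition_model`.
#' @export
inhibition_model <- function(ec50 = 30, hill_n = 2, f_ceiling = 0.60,
                             f_ceiling_tail = 0.88, tau_wash = 60,
                             deact_speedup = 0.6) {
  if (ec50 <= 0 || hill_n <= 0 || tau_wash <= 0) {
    stop("ec50, hill_n and tau_wash must be > 0")
  }
  if (f_ceiling < 0 || f_ceiling > 1 || f_ceiling_tail < 0 || f_ceiling_tail > 1) {
    stop("inhibition ceilings must be in [0, 1]")
  }
  if (deact_speedup <= 0 || deact_speedup > 1) {
    stop("deact_speedup must be in (0, 1]")
  }
  structure(list(ec50 = ec50, hill_n = hill_n, f_ceiling = f_ceiling,
                 f_ceiling_tail = f_ceiling_tail, tau_wash = tau_wash,
                 deact_speedup = deact_speedup),
            class = "inhibition_model")
}

#' Momentary inhibition scale s(c, t)
#'
#' @param inh An [inhibition_model()].
#' @param conc Inhibitor concentration, uM (>= 0).
#' @param t Time since break-in, s (>= 0).
#' @param component `"max"` for the pulse conductance, `"tail"` for the tail
#'   amplitude.
#' @return The scale in (0, 1].
#' @export
inhibition_scale <- function(inh, conc, t, component = c("max", "tail")) {
  stopifnot(inherits(inh, "inhibition_model"))
  component <- match.arg(component)
  if (any(conc < 0)) stop("conc must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  ceiling_x <- if (component == "max") inh$f_ceiling else inh$f_ceiling_tail
  f <- if (all(conc == 0)) 0 else {
    ceiling_x * conc^inh$hill_n / (conc^inh$hill_n + inh$ec50^inh$hill_n)
  }
  1 - f * (1 - exp(-t / inh$tau_wash))
}

#' Voltage protocol
#'
#' @param holding_v Holding potential, mV.
#' @param step_v Step voltages, mV.
#' @param pulse_s Pulse duration, s.
#' @param tail_s Tail (repolarization) duration, s.
#' @param dt Sample interval, s.
#' @param prepulse_s Pre-pulse baseline at holding, s.
#' @export
ephys_protocol <- function(holding_v = -60, step_v = seq(-80, 140, by = 20),
                           pulse_s = 2, tail_s = 0.5, dt = 0.001,
                           prepulse_s = 0.1) {
  if (dt <= 0) stop("dt must be > 0")
  if (pulse_s <= 10 * dt || tail_s <= 10 * dt) {
    stop("pulse and tail durations must exceed 10 * dt")
  }
  if (length(step_v) == 0) stop("step_v must be non-empty")
  list(holding_v = holding_v, step_v = step_v, pulse_s = pulse_s,
       tail_s = tail_s, dt = dt, prepulse_s = prepulse_s)
}

#' Simulate a whole-cell voltage-clamp sweep family
#'
#' Pulse current at step voltage V, a time `t_breakin` after break-in with
#' inhibitor concentration `conc` in the pipette:
#' \deqn{I(V, t) = s_{max}(c, t_b)\, g_{max}\, p_\infty(V)\, (V - V_{rev})
#' \left[f_{inst} + (1 - f_{inst})(1 - e^{-t/\tau_{act}(V)})\right]}
#' The tail current decays mono-exponentially at the holding potential from
#' the pulse-end open fraction, scaled by the tail inhibition component, with
#' time constant `tau_deact * deact_speedup` when inhibitor is present.
#' Additive Gaussian noise; deterministic for a fixed seed.
#'
#' @param gating A [gating_params()].
#' @param inh An [inhibition_model()].
#' @param conc Pipette inhibitor concentration, uM (>= 0).
#' @param t_breakin Time since break-in at which the family is recorded, s.
#' @param protocol An [ephys_protocol()].
#' @param noise_sd Additive Gaussian noise SD, pA.
#' @param seed Optional integer seed.
#' @return A list of class `sweep_family`: `time` (s), `sweeps` (samples x
#'   voltages matrix, pA), `segments` (index vectors `prepulse`, `pulse`,
#'   `tail`), `meta`.
#' @export
simulate_family <- function(gating, inh = inhibition_model(), conc = 0,
                            t_breakin = 30, protocol = ephys_protocol(),
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(gating, "gating_params"), inherits(inh, "inhibition_model"))
  if (conc < 0) stop("conc must be >= 0")
  if (t_breakin < 0) stop("t_breakin must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dt <- protocol$dt
  n_pre <- round(protocol$prepulse_s / dt)
  n_pulse <- round(protocol$pulse_s / dt)
  n_tail <- round(protocol$tail_s / dt)
  n_all <- n_pre + n_pulse + n_tail
  t_axis <- dt * seq_len(n_all)
  seg <- list(prepulse = seq_len(n_pre),
              pulse = n_pre + seq_len(n_pulse),
              tail = n_pre + n_pulse + seq_len(n_tail))
  s_max <- inhibition_scale(inh, conc, t_breakin, "max")
  s_tail <- inhibition_scale(inh, conc, t_breakin, "tail")
  inhibited <- conc > 0 && (inh$f_ceiling > 0 || inh$f_ceiling_tail > 0)
  spd <- if (inhibited) inh$deact_speedup else 1

  t_pulse <- dt * seq_len(n_pulse)
  t_tail <- dt * seq_len(n_tail)
  sweeps <- matrix(0, n_all, length(protocol$step_v))
  colnames(sweeps) <- as.character(protocol$step_v)
  for (k in seq_along(protocol$step_v)) {
    v <- protocol$step_v[k]
    p <- p_inf_of_v(gating, v)
    tau <- tau_act_of_v(gating, v)
    act <- gating$i_inst_frac + (1 - gating$i_inst_frac) * (1 - exp(-t_pulse / tau))
    i_pulse <- s_max * gating$g_max * p * (v - gating$v_rev) * act
    act_end <- gating$i_inst_frac +
      (1 - gating$i_inst_frac) * (1 - exp(-protocol$pulse_s / tau))
    i_tail0 <- s_tail * gating$g_max * p * act_end *
      (protocol$holding_v - gating$v_rev)
    i_tail <- i_tail0 * exp(-t_tail / (gating$tau_deact * spd))
    sweeps[, k] <- c(rep(0, n_pre), i_pulse, i_tail)
  }
  if (noise_sd > 0) {
    sweeps <- sweeps + matrix(stats::rnorm(length(sweeps), 0, noise_sd),
                              nrow(sweeps), ncol(sweeps))
  }
  structure(
    list(time = t_axis, sweeps = sweeps, segments = seg,
         meta = list(conc = conc, t_breakin = t_breakin, protocol = protocol,
                     s_max = s_max, s_tail = s_tail, noise_sd = noise_sd,
                     seed = seed)),
    class = "sweep_family"
  )
}

#' Write a sweep family as CSV plus JSON sidecar
#'
#' CSV: column `time_s` then one current column per step voltage (`mV_140`
#' style names). Sidecar: protocol, segment markers, break-in time,
#' concentration, seed.
#'
#' @param fam A `sweep_family`.
#' @param path_csv Output CSV path; the sidecar uses the same stem with
#'   `.json`.
#' @return Invisibly, the two paths.
#' @export
write_sweep_family <- function(fam, path_csv) {
  stopifnot(inherits(fam, "sweep_family"))
  dir.create(dirname(path_csv), recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(time_s = fam$time, fam$sweeps, check.names = FALSE)
  names(tab)[-1] <- sprintf("mV_%s", colnames(fam$sweeps))
  utils::write.csv(tab, path_csv, row.names = FALSE)
  path_json <- sub("\\.csv$", ".json", path_csv)
  jsonlite::write_json(
    list(protocol = fam$meta$protocol,
         segments = lapply(fam$segments, range),
         t_breakin = fam$meta$t_breakin, conc = fam$meta$conc,
         seed = fam$meta$seed),
    path_json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(path_csv, path_json))
}

#' Read a sweep family written by [write_sweep_family()]
#'
#' @param path_csv Path to the CSV; the JSON sidecar must sit alongside.
#' @return A `sweep_family`.
#' @export
read_sweep_family <- function(path_csv) {
  if (!file.exists(path_csv)) stop("sweep CSV not found: ", path_csv)
  path_json <- sub("\\.csv$", ".json", path_csv)
  if (!file.exists(path_json)) {
    stop("missing JSON sidecar for ", path_csv,
         " (protocol/concentration metadata required)")
  }
  tab <- utils::read.csv(path_csv, check.names = FALSE)
  if (names(tab)[1] != "time_s") {
    stop("malformed sweep CSV ", path_csv, ": first column must be time_s")
  }
  vcols <- grep("^mV_", names(tab))
  if (length(vcols) == 0) {
    stop("malformed sweep CSV ", path_csv, ": no mV_* current columns")
  }
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  if (is.null(meta$conc)) {
    stop("sidecar ", path_json, " lacks concentration metadata (conc)")
  }
  sweeps <- as.matrix(tab[, vcols, drop = FALSE])
  colnames(sweeps) <- sub("^mV_", "", names(tab)[vcols])
  seg <- lapply(meta$segments, function(r) seq.int(r[1], r[2]))
  structure(
    list(time = tab$time_s, sweeps = sweeps, segments = seg,
         meta = list(conc = meta$conc, t_breakin = meta$t_breakin,
                     protocol = meta$protocol, seed = meta$seed)),
    class = "sweep_family"
  )
}
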