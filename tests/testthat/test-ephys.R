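g0 <- gating_params()
inh0 <- inhibition_model()

test_that("simulated families respect the inhibition algebra", {
  # no inhibitor: recordings at different break-in times are identical
  f1 <- simulate_family(g0, inh0, conc = 0, t_breakin = 30)
  f2 <- simulate_family(g0, inh0, conc = 0, t_breakin = 180)
  expect_identical(f1$sweeps, f2$sweeps)

  # full-inhibition limit: everything goes to zero
  inh_full <- inhibition_model(f_ceiling = 1, f_ceiling_tail = 1)
  f3 <- simulate_family(g0, inh_full, conc = 1e9, t_breakin = 1e6)
  expect_lt(max(abs(f3$sweeps)), 1e-6)

  # Hill midpoint: at c = ec50 and steady state, the pulse current is
  # (1 - f_ceiling/2) times the drug-free current
  fa <- simulate_family(g0, inh0, conc = inh0$ec50, t_breakin = 1e6)
  fb <- simulate_family(g0, inh0, conc = 0, t_breakin = 1e6)
  pulse <- fa$segments$pulse
  expect_equal(fa$sweeps[pulse, "140"],
               (1 - inh0$f_ceiling / 2) * fb$sweeps[pulse, "140"],
               tolerance = 1e-12)

  expect_error(simulate_family(g0, inh0, conc = -1), "conc")
  expect_error(simulate_family(g0, inh0, t_breakin = -5), "t_breakin")
  expect_error(ephys_protocol(pulse_s = 0.005, dt = 0.001), "10")
})

test_that("monotonicity: current falls with concentration and with time", {
  i_at <- function(conc, tb) {
    f <- simulate_family(g0, inh0, conc, tb)
    family_metrics(f, 140)$i_max
  }
  by_conc <- vapply(c(0, 10, 30, 100, 300), i_at, numeric(1), tb = 120)
  expect_true(all(diff(by_conc) < 0))
  by_time <- vapply(c(0, 30, 90, 180, 600), function(tb) i_at(50, tb),
                    numeric(1))
  expect_true(all(diff(by_time) < 0))
})

test_that("single-exponential fits are exact on clean traces", {
  t <- seq(0.002, 0.6, by = 0.002)
  f <- fit_exponential(t, 10 + 100 * exp(-t / 0.05), "decay")
  expect_true(f$converged)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  expect_equal(f$tau, 0.05, tolerance = 1e-6)
  expect_equal(f$offset, 10, tolerance = 1e-6)

  fa <- fit_exponential(t, -5 + 80 * (1 - exp(-t / 0.2)), "activation")
  expect_true(fa$converged)
  expect_equal(fa$amplitude, 80, tolerance = 1e-6)
  expect_equal(fa$tau, 0.2, tolerance = 1e-6)

  # degenerate inputs are reported, not thrown
  fc <- fit_exponential(t, rep(3, length(t)), "decay")
  expect_false(fc$converged)
  expect_error(fit_exponential(t[1:10], rnorm(10), "decay"), "20")
})

test_that("tau recovery stays within 2% at SNR 20", {
  errs <- vapply(1:40, function(s) {
    set.seed(s)
    t <- seq(0.001, 0.5, by = 0.001)
    y <- 10 + 100 * exp(-t / 0.05) + rnorm(length(t), 0, 5)
    abs(fit_exponential(t, y, "decay")$tau / 0.05 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("family metrics agree with the closed-form current", {
  fam <- simulate_family(g0, inh0, conc = 0, t_breakin = 30)
  m <- family_metrics(fam, 140)
  p <- 1 / (1 + exp(-(140 - g0$v_half) / g0$k_slope))
  tau <- g0$tau0 * exp(-140 / g0$v_tau)
  act_end <- g0$i_inst_frac + (1 - g0$i_inst_frac) * (1 - exp(-2 / tau))
  expect_lt(abs(m$i_max / (g0$g_max * p * 140 * act_end) - 1), 0.005)
  expect_equal(m$i_tail, g0$g_max * p * act_end * -60, tolerance = 1e-4)
  expect_equal(m$tau_act, tau, tolerance = 1e-4)
  expect_equal(m$tau_deact, g0$tau_deact, tolerance = 1e-6)
  expect_error(family_metrics(fam, 55), "step voltages")

  # conductance linearity: doubling g_max doubles amplitudes, not taus
  g2 <- g0; g2$g_max <- 2 * g0$g_max
  m2 <- family_metrics(simulate_family(g2, inh0, 0, 30), 140)
  expect_equal(m2$i_max / m$i_max, 2, tolerance = 1e-9)
  expect_equal(m2$i_tail / m$i_tail, 2, tolerance = 1e-6)
  expect_equal(m2$tau_act, m$tau_act, tolerance = 1e-6)

  # no slow gating: nothing to fit
  g3 <- g0; g3$i_inst_frac <- 1
  m3 <- family_metrics(simulate_family(g3, inh0, 0, 30), 140)
  expect_false(m3$act_fit$converged)
})

test_that("noiseless inhibition ratios equal the analytic wash-in scale", {
  for (conc in c(10, 30, 100)) {
    fe <- simulate_family(g0, inh0, conc, 30)
    fl <- simulate_family(g0, inh0, conc, 180)
    r <- inhibition_ratio(fl, fe, 140)
    s_max <- inhibition_scale(inh0, conc, 180, "max") /
      inhibition_scale(inh0, conc, 30, "max")
    s_tail <- inhibition_scale(inh0, conc, 180, "tail") /
      inhibition_scale(inh0, conc, 30, "tail")
    expect_equal(r$max_ratio, s_max, tolerance = 1e-9)
    expect_equal(r$tail_ratio, s_tail, tolerance = 1e-9)
  }
  # control: both ratios exactly 1
  fe <- simulate_family(g0, inh0, 0, 30)
  fl <- simulate_family(g0, inh0, 0, 180)
  r0 <- inhibition_ratio(fl, fe, 140)
  expect_equal(r0$max_ratio, 1, tolerance = 1e-9)
  expect_equal(r0$tail_ratio, 1, tolerance = 1e-9)

  expect_error(inhibition_ratio(fe, fl, 140), "after")
})

test_that("steady-state inhibition reproduces the calibrated 39%/66% drop", {
  # at a saturating 100 uM the generator's own analytic ratios are ~0.61/0.34
  s_max <- inhibition_scale(inh0, 100, 180, "max") /
    inhibition_scale(inh0, 100, 30, "max")
  s_tail <- inhibition_scale(inh0, 100, 180, "tail") /
    inhibition_scale(inh0, 100, 30, "tail")
  expect_equal(s_max, 0.61, tolerance = 0.01)
  expect_equal(s_tail, 0.34, tolerance = 0.01)
  set.seed(31)
  prot <- ephys_protocol(step_v = 140)
  rats <- t(vapply(1:25, function(s) {
    fe <- simulate_family(g0, inh0, 100, 30, prot, noise_sd = 30,
                          seed = 2 * s)
    fl <- simulate_family(g0, inh0, 100, 180, prot, noise_sd = 30,
                          seed = 2 * s + 1)
    unlist(inhibition_ratio(fl, fe, 140))
  }, numeric(2)))
  expect_lt(abs(median(rats[, 1]) - s_max), 0.05)
  expect_lt(abs(median(rats[, 2]) - s_tail), 0.05)
})

test_that("a mutant with no lipid coupling is indistinguishable from control", {
  inh_mut <- inhibition_model(f_ceiling = 0, f_ceiling_tail = 0)
  f_wt0 <- simulate_family(g0, inh0, 0, 180)
  f_mut <- simulate_family(g0, inh_mut, 100, 180)
  expect_equal(f_mut$sweeps, f_wt0$sweeps, tolerance = 1e-12)
})

test_that("Hill dose-response fits recover generating parameters", {
  conc <- c(5, 10, 25, 50, 100, 200)
  resp <- 0.7 * conc^1.5 / (conc^1.5 + 30^1.5)
  fit <- fit_dose_response(conc, resp)
  expect_equal(fit$ec50, 30, tolerance = 1e-4)
  expect_equal(fit$hill_n, 1.5, tolerance = 1e-4)
  expect_equal(fit$floor, 0, tolerance = 1e-4)
  expect_equal(fit$ceiling, 0.7, tolerance = 1e-4)

  # the fitted curve passes through its own midpoint at EC50
  mid <- fit$floor + (fit$ceiling - fit$floor) * fit$ec50^fit$hill_n /
    (fit$ec50^fit$hill_n + fit$ec50^fit$hill_n)
  expect_equal(mid, (fit$floor + fit$ceiling) / 2)

  expect_error(fit_dose_response(c(10, 20, 30), c(0.1, 0.2, 0.3)), "distinct")
  expect_error(fit_dose_response(c(100, 200, 300, 400), c(0.69, 0.7, 0.7, 0.7)),
               "non-bracketing")
})

test_that("sweep families survive the CSV + sidecar round trip", {
  fam <- simulate_family(g0, inh0, 50, 30,
                         ephys_protocol(step_v = c(100, 140)),
                         noise_sd = 5, seed = 12)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cell1.csv")
  write_sweep_family(fam, path)
  back <- read_sweep_family(path)
  expect_equal(back$sweeps, fam$sweeps, tolerance = 1e-6)
  expect_equal(back$segments, fam$segments)
  expect_equal(back$meta$conc, 50)

  # missing metadata sidecar is a hard error
  file.remove(sub("csv$", "json", path))
  expect_error(read_sweep_family(path), "sidecar")
})
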