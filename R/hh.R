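# Hodgkin-Huxley squid-axon gating kinetics, shifted to a resting potential
# of -65 mV.  Rates in s^-1, voltage arguments in volts.  x/(1-exp(-x))
# evaluated via expm1 with the series limit at 0.

exprel_inv <- function(x) {
  # x / (1 - exp(-x)), removable singularity at 0
  out <- ifelse(abs(x) < 1e-9, 1 + x / 2, x / (-expm1(-x)))
  out
}

#' Hodgkin-Huxley voltage-dependent rate functions
#'
#' The classic squid-axon alpha/beta forms (6.3 degrees C convention) with
#' resting potential -65 mV, returned in s^-1 for voltage in volts.
#' Exposed individually so channel declarations and config files can refer
#' to them by name.
#'
#' @param V membrane potential (volts), vectorized.
#' @name hh_rates
#' @export
hh_alpha_m <- function(V) {
  v <- V * 1e3
  1e3 * exprel_inv((v + 40) / 10)            # 0.1*(v+40)/(1-exp(-(v+40)/10))
}
#' @rdname hh_rates
#' @export
hh_beta_m <- function(V) 4e3 * exp(-(V * 1e3 + 65) / 18)
#' @rdname hh_rates
#' @export
hh_alpha_h <- function(V) 70 * exp(-(V * 1e3 + 65) / 20)
#' @rdname hh_rates
#' @export
hh_beta_h <- function(V) 1e3 / (1 + exp(-(V * 1e3 + 35) / 10))
#' @rdname hh_rates
#' @export
hh_alpha_n <- function(V) {
  v <- V * 1e3
  1e2 * exprel_inv((v + 55) / 10)            # 0.01*(v+55)/(1-exp(-(v+55)/10))
}
#' @rdname hh_rates
#' @export
hh_beta_n <- function(V) 125 * exp(-(V * 1e3 + 65) / 80)

# Registry of named rate functions usable from JSON model configs (no code
# injection: configs may only reference these names or tabulated pairs).
rate_builtins <- function() {
  list(hh_alpha_m = hh_alpha_m, hh_beta_m = hh_beta_m,
       hh_alpha_h = hh_alpha_h, hh_beta_h = hh_beta_h,
       hh_alpha_n = hh_alpha_n, hh_beta_n = hh_beta_n)
}

#' Stochastic Hodgkin-Huxley channel definitions
#'
#' The sodium channel as an 8-state scheme (m gate count 0..3 x h gate
#' count 0..1; conducting state `m3h1`) and the potassium channel as a
#' 5-state scheme (n gate count 0..4; conducting state `n4`), with the
#' standard squid-axon alpha/beta transition rates.  Initial state
#' occupancies are the stationary binomial distributions of the independent
#' gates at `v_init`.  Reversal potentials: E_Na = +50 mV, E_K = -77 mV.
#'
#' @param g_single single-channel conductance (S) for both channels.
#' @param v_init potential (V) at which initial state fractions are taken.
#' @return Named list of two [channel()] definitions, `Na` and `K`.
#' @export
hh_gating_model <- function(g_single = 4e-12, v_init = -0.065) {
  am <- hh_alpha_m(v_init); bm <- hh_beta_m(v_init)
  ah <- hh_alpha_h(v_init); bh <- hh_beta_h(v_init)
  an <- hh_alpha_n(v_init); bn <- hh_beta_n(v_init)
  m_inf <- am / (am + bm); h_inf <- ah / (ah + bh); n_inf <- an / (an + bn)

  na_states <- as.vector(outer(0:3, 0:1, function(m, h) paste0("m", m, "h", h)))
  na_tr <- list()
  for (h in 0:1) for (m in 0:3) {
    s <- paste0("m", m, "h", h)
    if (m < 3) na_tr[[length(na_tr) + 1L]] <- list(
      from = s, to = paste0("m", m + 1, "h", h),
      rate = scaled_rate(hh_alpha_m, 3 - m))
    if (m > 0) na_tr[[length(na_tr) + 1L]] <- list(
      from = s, to = paste0("m", m - 1, "h", h),
      rate = scaled_rate(hh_beta_m, m))
    na_tr[[length(na_tr) + 1L]] <- list(
      from = s, to = paste0("m", m, "h", 1 - h),
      rate = if (h == 0) hh_alpha_h else hh_beta_h)
  }
  na_init <- stats::setNames(as.vector(outer(0:3, 0:1, function(m, h)
    choose(3, m) * m_inf^m * (1 - m_inf)^(3 - m) *
      ifelse(h == 1, h_inf, 1 - h_inf))), na_states)

  k_states <- paste0("n", 0:4)
  k_tr <- list()
  for (nn in 0:4) {
    s <- paste0("n", nn)
    if (nn < 4) k_tr[[length(k_tr) + 1L]] <- list(
      from = s, to = paste0("n", nn + 1), rate = scaled_rate(hh_alpha_n, 4 - nn))
    if (nn > 0) k_tr[[length(k_tr) + 1L]] <- list(
      from = s, to = paste0("n", nn - 1), rate = scaled_rate(hh_beta_n, nn))
  }
  k_init <- stats::setNames(choose(4, 0:4) * n_inf^(0:4) * (1 - n_inf)^(4:0),
                            k_states)

  list(
    Na = channel("Na", na_states, na_tr, open_states = "m3h1",
                 g_single = g_single, reversal = 0.050, initial = na_init),
    K = channel("K", k_states, k_tr, open_states = "n4",
                g_single = g_single, reversal = -0.077, initial = k_init)
  )
}

scaled_rate <- function(fn, mult) {
  force(fn); force(mult)
  function(V) mult * fn(V)
}

#' Deterministic-limit Hodgkin-Huxley membrane patch
#'
#' The infinite-channel-count limit of the simulator's stepping scheme on an
#' isopotential membrane patch: gating fractions m, h, n advance by the
#' exact exponential update at frozen voltage over each step (the continuum
#' analogue of the per-window channel kinetics), and the voltage advances by
#' the same backward-Euler step the mesh solver uses, with conductances
#' `g_Na m^3 h`, `g_K n^4` frozen per step.  Useful as the deterministic
#' reference that stochastic channel runs approach as single-channel
#' conductance decreases, and for cross-checks against an ODE integration.
#'
#' @param t_end simulated span (s).
#' @param dt step (s).
#' @param g_na,g_k,g_leak maximal conductance densities (S/m^2).
#' @param e_na,e_k,e_leak reversal potentials (V).
#' @param cm specific capacitance (F/m^2).
#' @param i_density injected current density (A/m^2).
#' @param v0 initial potential (V); gates start at their stationary values
#'   for `v0`.
#' @return A tibble: `time_s`, `v` (volts), `m`, `h`, `n`.
#' @export
hh_membrane_deterministic <- function(t_end, dt = 1e-6, g_na = 1200,
                                      g_k = 360, g_leak = 0.25,
                                      e_na = 0.050, e_k = -0.077,
                                      e_leak = -0.065, cm = 0.01,
                                      i_density = 0, v0 = -0.065) {
  nstep <- ceiling(t_end / dt - 1e-9)
  v <- numeric(nstep + 1); m <- numeric(nstep + 1)
  h <- numeric(nstep + 1); n <- numeric(nstep + 1)
  v[1] <- v0
  m[1] <- hh_alpha_m(v0) / (hh_alpha_m(v0) + hh_beta_m(v0))
  h[1] <- hh_alpha_h(v0) / (hh_alpha_h(v0) + hh_beta_h(v0))
  n[1] <- hh_alpha_n(v0) / (hh_alpha_n(v0) + hh_beta_n(v0))
  for (i in seq_len(nstep)) {
    step <- min(dt, t_end - (i - 1) * dt)
    vi <- v[i]
    gate <- function(x, a, b) {
      tau <- 1 / (a + b); xi <- a * tau
      xi + (x - xi) * exp(-step / tau)
    }
    m[i + 1] <- gate(m[i], hh_alpha_m(vi), hh_beta_m(vi))
    h[i + 1] <- gate(h[i], hh_alpha_h(vi), hh_beta_h(vi))
    n[i + 1] <- gate(n[i], hh_alpha_n(vi), hh_beta_n(vi))
    gna <- g_na * m[i + 1]^3 * h[i + 1]
    gk <- g_k * n[i + 1]^4
    v[i + 1] <- (cm / step * vi + gna * e_na + gk * e_k + g_leak * e_leak +
                   i_density) / (cm / step + gna + gk + g_leak)
  }
  tibble::tibble(time_s = seq(0, by = dt, length.out = nstep + 1),
                 v = v, m = m, h = h, n = n)
}
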