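#' Analytic solution of the passive cable benchmark
#'
#' Membrane potential of a sealed-end, uniform passive cylindrical cable of
#' length `L` with a step current `I` injected at `x = 0` from `t = 0`,
#' starting at rest.  With space constant `lambda = sqrt(Rm d / (4 Ra))`,
#' time constant `tau = Rm Cm` and axial resistance per length
#' `r_a = 4 Ra / (pi d^2)`:
#' steady state `v_ss(x) = I r_a lambda cosh((L-x)/lambda) / sinh(L/lambda)`
#' and transient eigenfunction series over `cos(n pi x / L)` with rates
#' `(1 + (n pi lambda / L)^2) / tau`, truncated when the next term's
#' amplitude bound drops below `tol`.
#'
#' @param x position(s) along the cable (m), in `[0, L]`.
#' @param t time(s) (s), `>= 0`.
#' @param params cable parameters: a list with `length`, `diameter`,
#'   `resistivity` (Ohm m), `leak` (S/m^2), `leak_reversal` (V),
#'   `capacitance` (F/m^2), `current` (A).  Defaults to the standard
#'   benchmark values via [rallpack1_params()].
#' @param tol series truncation tolerance (V).
#' @return Matrix `length(t) x length(x)` of potentials (V); dropped to a
#'   vector if either argument has length 1.
#' @export
rallpack1_analytic <- function(x, t, params = rallpack1_params(),
                               tol = 1e-9) {
  L <- params$length
  stopifnot(all(x >= 0), all(x <= L + 1e-15), all(t >= 0))
  Rm <- 1 / params$leak
  lambda <- sqrt(Rm * params$diameter / (4 * params$resistivity))
  tau <- Rm * params$capacitance
  r_a <- 4 * params$resistivity / (pi * params$diameter^2)
  I <- params$current
  E <- params$leak_reversal

  vss <- I * r_a * lambda * cosh((L - x) / lambda) / sinh(L / lambda)
  amp <- I * r_a * lambda^2 / L
  out <- matrix(E, length(t), length(x))
  pos_t <- which(t > 0)
  if (length(pos_t)) {
    tmin <- min(t[pos_t])
    beta <- function(n) 1 + (n * pi * lambda / L)^2
    bound <- function(n) 2 * amp / beta(n) * exp(-tmin * beta(n) / tau)
    N <- 64L
    while (bound(N + 1L) >= tol && N < 2e5) N <- N * 2L
    if (bound(N + 1L) >= tol) {
      stop(sprintf("analytic series did not converge to %g V (bound %g)",
                   tol, bound(N + 1L)), call. = FALSE)
    }
    n <- seq_len(N)
    bn <- beta(n)
    coef <- 2 * amp / bn                            # length N
    cosx <- cos(outer(n * pi / L, x))               # N x nx
    chunk <- 10000L
    for (s in seq(1, length(pos_t), by = chunk)) {
      idx <- pos_t[s:min(s + chunk - 1L, length(pos_t))]
      decay <- exp(-outer(t[idx], c(1, bn)) / tau)  # nt x (N+1)
      trans <- decay[, 1, drop = FALSE] %*% matrix(amp, 1, length(x)) +
        decay[, -1, drop = FALSE] %*% (coef * cosx)
      out[idx, ] <- out[idx, ] + rep(vss, each = length(idx)) - trans
    }
  }
  if (length(x) == 1L || length(t) == 1L) drop(out) else out
}

#' Standard passive-cable benchmark parameters
#'
#' Leak 0.25 S/m^2, reversal -65 mV, axial resistivity 1 Ohm m, injection
#' 0.1 nA, length 1 mm, specific capacitance 0.01 F/m^2, diameter 1 um,
#' voltage step 5 us.
#'
#' @return Named list of cable parameters.
#' @export
rallpack1_params <- function() {
  list(length = 1e-3, diameter = 1e-6, resistivity = 1.0, leak = 0.25,
       leak_reversal = -0.065, capacitance = 0.01, current = 0.1e-9,
       efield_dt = 5e-6)
}

#' Detect peaks in a uniformly sampled trace
#'
#' Local maxima filtered by prominence (height above the highest of the two
#' lowest points separating the peak from higher terrain) and by minimum
#' separation (greedy, keeping higher peaks first).
#'
#' @param v numeric trace.
#' @param dt sampling step (s).
#' @param min_prominence minimum prominence (same units as `v`).
#' @param min_separation minimum time between kept peaks (s).
#' @param t0 time of the first sample (s).
#' @return A tibble: `index`, `time_s`, `height`, `prominence`, sorted by
#'   time.  Zero rows when no peak qualifies.
#' @export
detect_peaks <- function(v, dt, min_prominence = 0.010,
                         min_separation = 0.002, t0 = 0) {
  n <- length(v)
  if (n < 3) return(tibble::tibble(index = integer(0), time_s = numeric(0),
                                   height = numeric(0), prominence = numeric(0)))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(tibble::tibble(index = integer(0),
                                           time_s = numeric(0),
                                           height = numeric(0),
                                           prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- v[i]
    left_higher <- which(v[seq_len(i - 1)] > h)
    lo_l <- if (length(left_higher)) min(v[(max(left_higher) + 1):(i - 1)])
            else min(v[1:(i - 1)])
    right_higher <- which(v[(i + 1):n] > h)
    lo_r <- if (length(right_higher)) min(v[(i + 1):(i + min(right_higher) - 1)])
            else min(v[(i + 1):n])
    h - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(tibble::tibble(index = integer(0),
                                           time_s = numeric(0),
                                           height = numeric(0),
                                           prominence = numeric(0)))
  ord <- order(v[cand], decreasing = TRUE)
  kept <- integer(0)
  for (i in cand[ord]) {
    if (!length(kept) || all(abs(i - kept) * dt >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  tibble::tibble(index = kept, time_s = t0 + (kept - 1) * dt,
                 height = v[kept], prominence = prom[match(kept, cand)])
}

#' Spike frequency from peak features
#'
#' `(n_peaks - 1) / (t_last - t_first)`; `NA` with fewer than 2 peaks.
#'
#' @param peaks a [detect_peaks()] result.
#' @return Frequency (Hz).
#' @export
peak_frequency <- function(peaks) {
  if (nrow(peaks) < 2) return(NA_real_)
  (nrow(peaks) - 1) / (max(peaks$time_s) - min(peaks$time_s))
}

# ---------------------------------------------------------------------------
# Two-sample Cramér-von Mises test.  Statistic per Anderson (1962) from
# midranks; asymptotic p-value from the limiting distribution of the
# one-sample statistic (Csörgő & Faraway smooth series, evaluated with
# besselK); Monte-Carlo permutation fallback for small batches.

# CDF of the limiting Cramér-von Mises distribution at x.
cvm_cdf_inf <- function(x) {
  vapply(x, function(xx) {
    if (xx <= 0) return(0)
    tot <- 0
    for (k in 0:20) {
      y <- 4 * k + 1
      q <- y^2 / (16 * xx)
      # exp(-q) * besselK(q, 1/4), via the scaled Bessel for large q
      b <- if (q < 700) exp(-q) * besselK(q, 0.25)
           else besselK(q, 0.25, expon.scaled = TRUE) * exp(-2 * q)
      term <- exp(lgamma(k + 0.5) - lgamma(k + 1)) / (pi^1.5 * sqrt(xx)) *
        sqrt(y) * b
      tot <- tot + term
      if (term < 1e-14 && k > 2) break
    }
    min(max(tot, 0), 1)
  }, numeric(1))
}

#' Two-sample Cramér-von Mises test
#'
#' Tests whether two samples come from the same distribution.  The statistic
#' is computed from midranks (ties allowed); the p-value uses the asymptotic
#' limiting distribution, or a Monte-Carlo permutation null when either
#' sample is smaller than 20 (where the asymptotic approximation is poor).
#'
#' @param x,y numeric samples.
#' @param method `"auto"` (default), `"asymptotic"` or `"permutation"`.
#' @param n_perm permutation count for the permutation method.
#' @return A list: `statistic` (T), `p_value`, `method`.
#' @export
cvm_2samp <- function(x, y, method = c("auto", "asymptotic", "permutation"),
                      n_perm = 2000) {
  method <- match.arg(method)
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) stop("both samples need at least 2 values", call. = FALSE)
  if (method == "auto") {
    method <- if (min(n, m) < 20) "permutation" else "asymptotic"
  }
  stat <- cvm_stat(x, y)
  if (method == "asymptotic") {
    # Anderson's finite-sample moment normalization onto the limiting law
    N <- n + m
    et <- (1 + 1 / N) / 6
    vt <- (N + 1) * (4 * n * m * N - 3 * (n^2 + m^2) - 2 * n * m) /
      (45 * N^2 * 4 * n * m)
    tn <- 1 / 6 + (stat - et) / sqrt(45 * vt)
    p <- if (tn < 0.003) 1 else 1 - cvm_cdf_inf(tn)
  } else {
    z <- c(x, y)
    stats_null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n + m, n)
      cvm_stat(z[idx], z[-idx])
    }, numeric(1))
    p <- (1 + sum(stats_null >= stat)) / (n_perm + 1)
  }
  list(statistic = stat, p_value = min(max(p, 0), 1), method = method)
}

cvm_stat <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y), ties.method = "average")
  rx <- sort(r[seq_len(n)])
  ry <- sort(r[n + seq_len(m)])
  U <- n * sum((rx - seq_len(n))^2) + m * sum((ry - seq_len(m))^2)
  U / (n * m * N) - (4 * n * m - 1) / (6 * N)
}

#' Batched all-pairs Cramér-von Mises comparison
#'
#' Splits each sample set into consecutive batches of `batch_size` and
#' computes the two-sample CVM p-value for every (batch of A, batch of B)
#' pair — `(nA/batch) x (nB/batch)` p-values.  Under the null the p-values
#' are uniform on [0, 1]; the null is rejected only when significantly more
#' than 1% of them fall below 0.01 (a three-sigma binomial exceedance).
#'
#' @param samples_a,samples_b numeric sample sets, lengths divisible by
#'   `batch_size`.
#' @param batch_size runs per batch.
#' @param alpha per-test level defining the exceedance count (default 0.01).
#' @return An object of class `cvm_batch`: `p_values` (matrix), `median`,
#'   `fraction_below` (fraction with p < `alpha`), `threshold`, `reject`.
#' @export
cvm_batch_compare <- function(samples_a, samples_b, batch_size = 100,
                              alpha = 0.01) {
  na <- length(samples_a); nb <- length(samples_b)
  if (batch_size > na || batch_size > nb) {
    stop("batch size exceeds sample size", call. = FALSE)
  }
  if (na %% batch_size || nb %% batch_size) {
    stop("sample sizes must be divisible by the batch size", call. = FALSE)
  }
  A <- matrix(samples_a, nrow = batch_size)
  B <- matrix(samples_b, nrow = batch_size)
  p <- matrix(NA_real_, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      p[i, j] <- cvm_2samp(A[, i], B[, j])$p_value
    }
  }
  np <- length(p)
  frac <- mean(p < alpha)
  thr <- alpha + 3 * sqrt(alpha * (1 - alpha) / np)
  structure(list(p_values = p, median = stats::median(p),
                 fraction_below = frac, alpha = alpha, threshold = thr,
                 reject = frac > thr), class = "cvm_batch")
}

#' @export
print.cvm_batch <- function(x, ...) {
  cat(sprintf("<cvm_batch> %d p-values: median %.3f, %.2f%% below %.2g (reject threshold %.2f%%): %s\n",
              length(x$p_values), x$median, 100 * x$fraction_below, x$alpha,
              100 * x$threshold,
              if (x$reject) "REJECT" else "not rejected"))
  invisible(x)
}

#' Pointwise confidence band of a trace ensemble
#'
#' Mean trace with pointwise t-interval bands
#' `mean +/- t_{1-(1-level)/2, n-1} * sd / sqrt(n)`.
#'
#' @param traces a [trace_set()] or a runs-by-time matrix.
#' @param level confidence level (default 0.99).
#' @return A tibble: `time_s` (or sample index), `mean`, `lower`, `upper`.
#' @export
ci_band <- function(traces, level = 0.99) {
  tm <- if (inherits(traces, "trace_set")) traces$traces else as.matrix(traces)
  n <- nrow(tm)
  if (n < 2) stop("confidence bands need at least 2 runs", call. = FALSE)
  mu <- colMeans(tm)
  sd <- apply(tm, 2, stats::sd)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  times <- if (inherits(traces, "trace_set"))
    traces$t0 + (seq_along(mu) - 1) * traces$dt else seq_along(mu)
  tibble::tibble(time_s = times, mean = mu, lower = mu - half,
                 upper = mu + half)
}

#' Mutual confidence-band comparison of two trace ensembles
#'
#' Rejects the hypothesis that the two ensembles come from the same model
#' when one ensemble's mean leaves the other's pointwise band on more than
#' `allowed_fraction` of the time points.  Even under the null some exits
#' are expected: the pointwise band brackets the *true* mean, while the
#' compared quantity is another noisy ensemble mean, so with equal run
#' counts about `2 (1 - pnorm(qt((1+level)/2, n-1) / sqrt(2)))` of points
#' (~6% at the 99% level) exit by construction.  The default tolerance sits
#' above that baseline; ensembles from genuinely different models overshoot
#' it decisively.
#'
#' @param a,b [trace_set()]s or runs-by-time matrices (same time base).
#' @param level band confidence level.
#' @param allowed_fraction tolerated fraction of exiting time points.
#' @return A list: `fraction_a_outside_b`, `fraction_b_outside_a`,
#'   `reject`.
#' @export
ci_band_compare <- function(a, b, level = 0.99, allowed_fraction = 0.15) {
  ba <- ci_band(a, level); bb <- ci_band(b, level)
  fa <- mean(ba$mean < bb$lower | ba$mean > bb$upper)
  fb <- mean(bb$mean < ba$lower | bb$mean > ba$upper)
  list(fraction_a_outside_b = fa, fraction_b_outside_a = fb,
       reject = fa > allowed_fraction || fb > allowed_fraction)
}
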