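# Independent oracles used by the module tests and the acceptance suite.

# brute-force quadrature of the dose integral: piecewise-constant A(t) times
# exp(-lambda t), trapezoid rule on a fine grid (default 0.001 min)
quadrature_dose <- function(A, frame_min, T_min, lambda, B0 = 1,
                            step = 0.001) {
  cst <- dose_constants()
  scale <- cst$decays_per_mci_min * cst$mgy_per_mev_g * B0
  tt <- seq(0, T_min, by = step)
  frame_idx <- pmin(floor(tt / frame_min) + 1L, ncol(A))
  # frame boundaries are discontinuities of A(t): integrate per segment
  vapply(seq_len(nrow(A)), function(i) {
    f <- A[i, frame_idx] * exp(-lambda * tt)
    # trapezoid with correction at interior frame boundaries: use the
    # left-limit value on the closing point of each frame
    total <- 0
    brk <- unique(c(seq(0, T_min, by = frame_min), T_min))
    for (k in seq_len(length(brk) - 1)) {
      t0 <- brk[k]; t1 <- brk[k + 1]
      ts <- seq(t0, t1, by = step)
      if (ts[length(ts)] < t1) ts <- c(ts, t1)
      fa <- A[i, min(floor(t0 / frame_min) + 1L, ncol(A))] * exp(-lambda * ts)
      total <- total + sum((fa[-1] + fa[-length(fa)]) / 2 * diff(ts))
    }
    total * scale
  }, 0)
}

# numeric Klein-Nishina expectation of a function of cos(theta)
kn_expectation <- function(energy_mev, fun) {
  num <- stats::integrate(function(ct) fun(ct) *
                            klein_nishina_pdf(energy_mev, ct), -1, 1,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(ct) klein_nishina_pdf(energy_mev, ct),
                          -1, 1, rel.tol = 1e-10)$value
  num / den
}
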