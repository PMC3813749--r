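# Generic fixed-step RK4 used as an independent integration oracle in tests.
rk4_integrate <- function(f, y0, t0, t1, dt) {
  ns <- round((t1 - t0) / dt)
  y <- matrix(NA_real_, ns + 1, length(y0))
  y[1, ] <- y0
  tt <- t0 + (0:ns) * dt
  s <- y0
  for (i in seq_len(ns)) {
    t <- tt[i]
    k1 <- f(t, s)
    k2 <- f(t + dt / 2, s + dt / 2 * k1)
    k3 <- f(t + dt / 2, s + dt / 2 * k2)
    k4 <- f(t + dt, s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[i + 1, ] <- s
  }
  list(t = tt, y = y)
}
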