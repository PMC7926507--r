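# Shared fixture builders. Everything is generated in code; the random
# windows use small lengths so per-feature oracles stay cheap.

# a random 4-channel window with RV consistent with the axes
make_window <- function(n = 120, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, 0, 0.3); y <- rnorm(n, 0.2, 0.5); z <- 1 + rnorm(n, 0, 0.2)
  list(X = x, Y = y, Z = z, RV = sqrt(x^2 + y^2 + z^2))
}

# a tiny in-memory session: n_act activities of dur_s seconds at `rate`
# Hz with constant-ish vo2 per activity
make_tiny_session <- function(n_act = 2, dur_s = 120, rate = 20, seed = 1,
                              vo2_levels = seq(4, by = 2, length.out = n_act)) {
  set.seed(seed)
  gap <- 30
  n_per <- dur_s * rate
  idx0 <- 0
  tt <- xx <- yy <- zz <- numeric(0)
  starts <- ends <- numeric(n_act)
  vt <- vv <- numeric(0)
  for (i in seq_len(n_act)) {
    starts[i] <- idx0 / rate
    t_act <- (idx0 + seq_len(n_per) - 1) / rate
    ends[i] <- (idx0 + n_per) / rate
    tt <- c(tt, t_act)
    xx <- c(xx, 0.1 * sin(2 * pi * t_act) + rnorm(n_per, 0, 0.02))
    yy <- c(yy, 0.2 * sin(2 * pi * 1.3 * t_act) + rnorm(n_per, 0, 0.02))
    zz <- c(zz, 1 + rnorm(n_per, 0, 0.02))
    vt <- c(vt, starts[i] + seq(0, dur_s - 1, by = 5))
    vv <- c(vv, rep(vo2_levels[i], dur_s / 5))
    idx0 <- idx0 + n_per + gap * rate
    # quiet gap samples so the accel stream covers the whole session
    t_gap <- (idx0 - gap * rate + seq_len(gap * rate) - 1) / rate
    tt <- c(tt, t_gap)
    xx <- c(xx, rnorm(gap * rate, 0, 0.02))
    yy <- c(yy, rnorm(gap * rate, 0, 0.02))
    zz <- c(zz, 1 + rnorm(gap * rate, 0, 0.02))
    vt <- c(vt, t_gap[seq(1, length(t_gap), by = 5 * rate)])
    vv <- c(vv, rep(3.5, ceiling(gap / 5)))
  }
  o <- order(tt)
  session("T01",
          accel_recording(tt[o], xx[o], yy[o], zz[o], nominal_rate = rate),
          vo2_series(vt, vv, mass_kg = 70),
          activity_annotations(paste0("act", seq_len(n_act)),
                               rep(c("Sedentary", "Housework", "Locomotion"),
                                   length.out = n_act),
                               starts, ends))
}

# independent O(n^2) double-loop sample-entropy counter (test oracle)
sampen_bruteforce <- function(s, m = 2, r) {
  n <- length(s)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(s[i:(i + m - 1)] - s[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(s[i + m] - s[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}
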