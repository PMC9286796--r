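# Independent closed-form oracles used across the test files. These are
# deliberately separate implementations (plain-R Kalman recursions, O(n*m)
# scans, sort-based medians) against which the package's code is checked.

# Exact Kalman filter for the local-level model with known variances.
# Returns filtered means/variances and the one-step predictive moments.
# Missing observations skip the measurement update.
kalman_filter_oracle <- function(z, s2e, s2h, m0, C0) {
  T <- length(z)
  m <- C <- a <- R <- numeric(T)
  for (t in seq_len(T)) {
    a[t] <- if (t == 1) m0 else m[t - 1]
    R[t] <- if (t == 1) C0 else C[t - 1] + s2h
    if (!is.na(z[t])) {
      K <- R[t] / (R[t] + s2e)
      m[t] <- a[t] + K * (z[t] - a[t])
      C[t] <- R[t] * (1 - K)
    } else {
      m[t] <- a[t]
      C[t] <- R[t]
    }
  }
  list(m = m, C = C, a = a, R = R,
       forecast_mean = m[T], forecast_var = C[T] + s2h + s2e)
}

# Exact RTS smoother on top of the filter.
kalman_smoother_oracle <- function(z, s2e, s2h, m0, C0) {
  kf <- kalman_filter_oracle(z, s2e, s2h, m0, C0)
  T <- length(z)
  ms <- Cs <- numeric(T)
  ms[T] <- kf$m[T]; Cs[T] <- kf$C[T]
  for (t in (T - 1):1) {
    J <- kf$C[t] / kf$R[t + 1]
    ms[t] <- kf$m[t] + J * (ms[t + 1] - kf$a[t + 1])
    Cs[t] <- kf$C[t] + J^2 * (Cs[t + 1] - kf$R[t + 1])
  }
  list(mean = ms, var = Cs)
}

# Simulate a local-level series with known variances (transformed scale).
simulate_local_level <- function(T, s2e, s2h, mu0 = 0) {
  mu <- cumsum(c(mu0, rnorm(T - 1, 0, sqrt(s2h))))
  list(z = mu + rnorm(T, 0, sqrt(s2e)), mu = mu)
}

# The m0/C0 convention fit_local_level() uses, replicated independently so
# known-variance oracle comparisons condition on the same prior.
llm_init <- function(z, var_floor = 0.5, init_level_var = 10) {
  vz <- max(var(z, na.rm = TRUE), var_floor, 1e-3)
  list(m0 = z[which(!is.na(z))[1]], C0 = init_level_var * vz)
}

# Brute-force O(n*m) treatment-buffer scan.
buffer_scan_oracle <- function(traps, treatments, radius) {
  keep <- rep(TRUE, nrow(traps))
  for (i in seq_len(nrow(traps))) {
    for (j in seq_len(nrow(treatments))) {
      if (traps$year[i] != treatments$year[j]) next
      d <- sqrt((traps$x[i] - treatments$x[j])^2 +
                (traps$y[i] - treatments$y[j])^2) - treatments$radius[j]
      if (max(d, 0) < radius) keep[i] <- FALSE
    }
  }
  traps[keep, ]
}

# Exhaustive rectangle-membership quadrat assignment.
rect_assign_oracle <- function(x, y, origin, size, n_rows, n_cols) {
  row <- col <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    for (r in 0:(n_rows - 1)) {
      for (cc in 0:(n_cols - 1)) {
        if (x[i] >= origin[1] + cc * size && x[i] < origin[1] + (cc + 1) * size &&
            y[i] >= origin[2] + r * size && y[i] < origin[2] + (r + 1) * size) {
          row[i] <- r; col[i] <- cc
        }
      }
    }
  }
  list(row = row, col = col)
}

# Sort-based median (even n: mean of the two middle order statistics).
sort_median_oracle <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Exhaustive 8-neighbour scan for the neighbourhood mean.
neighborhood_scan_oracle <- function(df, include_focal = FALSE) {
  out <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    acc <- c()
    for (j in seq_len(nrow(df))) {
      dr <- df$row[j] - df$row[i]; dc <- df$col[j] - df$col[i]
      if (abs(dr) <= 1 && abs(dc) <= 1 &&
          (include_focal || !(dr == 0 && dc == 0)) &&
          !is.na(df$waiting_time[j]))
        acc <- c(acc, df$waiting_time[j])
    }
    out[i] <- if (length(acc)) mean(acc) else NA_real_
  }
  out
}

# Moran-type lag-k spatial autocorrelation of a matrix field, brute force
# over all pairs at L1 grid distance exactly k along rows/cols.
lag_autocor_oracle <- function(f, k) {
  v <- f - mean(f)
  num <- 0; cnt <- 0
  nr <- nrow(f); nc <- ncol(f)
  for (r in 1:nr) for (cc in 1:nc) {
    if (r + k <= nr) { num <- num + v[r, cc] * v[r + k, cc]; cnt <- cnt + 1 }
    if (cc + k <= nc) { num <- num + v[r, cc] * v[r, cc + k]; cnt <- cnt + 1 }
  }
  (num / cnt) / mean(v^2)
}

# A small gridded dataset with hand-checkable structure, used by several
# files: 2 traps in quadrat (0,0), 1 trap in (1,1).
tiny_trap_fixture <- function() {
  tibble::tibble(
    trap_id = c("A", "A", "B", "B", "C", "C"),
    x = c(100, 100, 4900, 4900, 9000, 9000),
    y = c(200, 200, 4800, 4800, 9900, 9900),
    year = c(2000L, 2001L, 2000L, 2001L, 2000L, 2001L),
    count = c(0L, 4L, 2L, 6L, 1L, 3L)
  )
}
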