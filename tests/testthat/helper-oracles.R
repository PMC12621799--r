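# Independent oracles used across the suite. Each is deliberately naive and
# shares no code path with the implementation it checks.

# Largest principal angle (degrees) between the column spans of A and B.
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  max(acos(pmin(svd(crossprod(qa, qb))$d, 1)) * 180 / pi)
}

# Classical NIPALS PLS2 with X and Y deflation; returns centred-data
# regression coefficients. Second-algorithm oracle for the SIMPLS fit.
nipals_pls <- function(X, Y, n_components, tol = 1e-13, maxit = 1000L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean)
  Yc <- sweep(Y, 2L, y_mean)
  W <- matrix(0, ncol(X), n_components)
  P <- matrix(0, ncol(X), n_components)
  Q <- matrix(0, ncol(Y), n_components)
  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    w <- crossprod(Xc, u)
    for (it in seq_len(maxit)) {
      w <- w / sqrt(sum(w^2))
      tt <- Xc %*% w
      q <- crossprod(Yc, tt) / sum(tt^2)
      u_new <- Yc %*% q / sum(q^2)
      w_new <- crossprod(Xc, u_new)
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sum((w_new - w)^2) < tol) {
        w <- w_new
        break
      }
      w <- w_new
      u <- u_new
    }
    tt <- Xc %*% w
    p <- crossprod(Xc, tt) / sum(tt^2)
    q <- crossprod(Yc, tt) / sum(tt^2)
    Xc <- Xc - tt %*% t(p)
    Yc <- Yc - tt %*% t(q)
    W[, a] <- w
    P[, a] <- p
    Q[, a] <- q
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(B = B, x_mean = x_mean, y_mean = y_mean)
}

nipals_predict <- function(fit, X) {
  sweep(sweep(as.matrix(X), 2L, fit$x_mean) %*% fit$B, 2L, fit$y_mean, "+")
}

# Fixed-step classical RK4 integration of a network's logic-based ODEs.
# Second-integrator oracle for the adaptive solver.
rk4_trajectories <- function(spec, t_end, dt, out_times) {
  sys <- build_odes(spec)
  f <- function(t, y) sys$rhs(t, y, NULL)[[1L]]
  y <- vapply(spec$nodes[sys$state_ids], `[[`, numeric(1L), "yinit")
  n_steps <- round(t_end / dt)
  out <- matrix(NA_real_, length(out_times), length(y),
                dimnames = list(NULL, sys$state_ids))
  record <- function(t, y) {
    hit <- which(abs(out_times - t) < dt / 2)
    if (length(hit)) out[hit, ] <<- y
  }
  record(0, y)
  for (k in seq_len(n_steps)) {
    t <- (k - 1L) * dt
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    record(k * dt, y)
  }
  out
}

# A batch of seeded random smooth-boundary masks for geometry checks.
random_blob_masks <- function(n = 20L, size_px = 20, amp = 0.15,
                              seed_base = 100L) {
  lapply(seq_len(n), function(i) {
    cfg <- shape_config("random_blob", size_px = size_px,
                        boundary_noise_amplitude = amp,
                        rotation_deg = 17 * i, seed = seed_base + i)
    gen_cell_masks(cfg, 1L)$masks[[1L]]
  })
}

# Fake per-cell feature table with the full metric panel, for summary ops.
synthetic_feature_table <- function(n, well_id = "w1", seed = 1L) {
  set.seed(seed)
  metrics <- morpho_metric_names()
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                   well_id = well_id, stringsAsFactors = FALSE)
  for (m in metrics) df[[m]] <- stats::rlnorm(n, meanlog = 3)
  df
}
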