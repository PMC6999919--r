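# Adaptive Dormand-Prince 5(4) integrator with event detection.
#
# No ODE-solver package ships with this toolchain, and the simulations need
# direction-constrained terminal events (torque switching, stopping), so the
# integrator is implemented here. Dense output for event location uses cubic
# Hermite interpolation on the accepted step, refined with uniroot; at the
# default tolerances (rtol 1e-8, atol 1e-10) the interpolation error is far
# below the event-location tolerance.

# Butcher tableau (Dormand & Prince 1980), FSAL.
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

# events: list of list(fun = function(t, y) scalar, direction = +1/-1/0).
# All events are terminal. Returns list(times, states, derivs, status,
# event = list(index, time, state) or NULL).
rk45_integrate <- function(deriv, y0, t0, t_max, rtol = 1e-8, atol = 1e-10,
                           events = list(), max_steps = 200000L) {
  stopifnot(t_max > t0)
  t <- t0
  y <- as.numeric(y0)
  f <- deriv(t, y)
  n_ev <- length(events)
  g_prev <- vapply(events, function(e) e$fun(t, y), numeric(1))

  ts <- list(t)
  ys <- list(y)
  fs <- list(f)
  i_store <- 1L

  # initial step: small fraction of the horizon, refined by the controller
  h <- min((t_max - t0) / 100, 0.1 / max(sqrt(sum(f^2)), 1e-8))
  h <- max(h, (t_max - t0) * 1e-12)

  status <- "running"
  event_hit <- NULL
  steps <- 0L

  while (status == "running") {
    steps <- steps + 1L
    if (steps > max_steps) {
      status <- "max_steps"
      break
    }
    if (t + h > t_max) h <- t_max - t

    k <- matrix(0, nrow = length(y), ncol = 7)
    k[, 1] <- f
    for (i in 2:6) {
      a <- .dp_a[[i - 1]]
      k[, i] <- deriv(t + .dp_c[i] * h,
                      y + h * as.numeric(k[, seq_along(a), drop = FALSE] %*% a))
    }
    y_new <- y + h * as.numeric(k[, 1:6, drop = FALSE] %*% .dp_a[[6]])
    f_new <- deriv(t + h, y_new)
    k[, 7] <- f_new
    err_vec <- h * as.numeric(k %*% (.dp_b5 - .dp_b4))
    scale <- atol + rtol * pmax(abs(y), abs(y_new))
    err <- sqrt(mean((err_vec / scale)^2))

    if (err <= 1 || h <= (t_max - t0) * 1e-13) {
      t_new <- t + h
      # event check on the accepted step
      if (n_ev > 0) {
        g_new <- vapply(events, function(e) e$fun(t_new, y_new), numeric(1))
        hit_t <- Inf
        hit_i <- 0L
        for (j in seq_len(n_ev)) {
          dir <- events[[j]]$direction
          crossed <-
            (g_prev[j] < 0 && g_new[j] >= 0 && dir >= 0) ||
            (g_prev[j] > 0 && g_new[j] <= 0 && dir <= 0)
          if (!crossed) next
          gfun <- events[[j]]$fun
          interp_g <- function(tt) {
            gfun(tt, hermite_state(tt, t, t_new, y, y_new, f, f_new))
          }
          te <- if (g_new[j] == 0) t_new else {
            stats::uniroot(interp_g, lower = t, upper = t_new,
                           f.lower = g_prev[j], f.upper = g_new[j],
                           tol = max(.Machine$double.eps * 8 * abs(t_new),
                                     1e-15))$root
          }
          if (te < hit_t) {
            hit_t <- te
            hit_i <- j
          }
        }
        if (hit_i > 0L) {
          y_e <- hermite_state(hit_t, t, t_new, y, y_new, f, f_new)
          i_store <- i_store + 1L
          ts[[i_store]] <- hit_t
          ys[[i_store]] <- y_e
          fs[[i_store]] <- deriv(hit_t, y_e)
          event_hit <- list(index = hit_i, time = hit_t, state = y_e)
          status <- "event"
          break
        }
        g_prev <- g_new
      }
      t <- t_new
      y <- y_new
      f <- f_new
      i_store <- i_store + 1L
      ts[[i_store]] <- t
      ys[[i_store]] <- y
      fs[[i_store]] <- f
      if (t >= t_max) status <- "t_max"
    }
    # step-size controller (applied after accept or reject)
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
  }

  list(times = unlist(ts),
       states = do.call(rbind, ys),
       derivs = do.call(rbind, fs),
       status = status,
       event = event_hit)
}

# cubic Hermite dense output on [ta, tb]
hermite_state <- function(tt, ta, tb, ya, yb, fa, fb) {
  hh <- tb - ta
  s <- (tt - ta) / hh
  s2 <- s * s
  s3 <- s2 * s
  (2 * s3 - 3 * s2 + 1) * ya + (s3 - 2 * s2 + s) * hh * fa +
    (-2 * s3 + 3 * s2) * yb + (s3 - s2) * hh * fb
}
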