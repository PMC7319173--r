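# State-space machinery for the continuous-time correlated random walk:
# per axis, the state is (position, velocity) with Ornstein-Uhlenbeck velocity
#   dv = -beta * v * dt + sigma * dW,   dx = v * dt.
# beta [1/hr] is the inverse velocity-autocorrelation time scale and sigma
# [km/hr^1.5] the square root of the velocity diffusion coefficient; the
# stationary velocity variance is sigma^2 / (2 beta).  The two planar axes are
# independent with shared parameters, so one covariance recursion serves both.

# Exact discrete transition over a step of dt hours.
#' @keywords internal
iou_step <- function(beta, sigma, dt) {
  phi <- exp(-beta * dt)
  Tm <- matrix(c(1, 0, (1 - phi) / beta, phi), 2, 2)
  s2 <- sigma^2
  Qxx <- s2 / beta^2 * (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta))
  Qxv <- s2 * (1 - phi)^2 / (2 * beta^2)
  Qvv <- s2 * (1 - phi^2) / (2 * beta)
  list(T = Tm, Q = matrix(c(Qxx, Qxv, Qxv, Qvv), 2, 2))
}

#' Kalman filter and smoother for the correlated random walk
#'
#' Runs the exact-discretisation Kalman filter (and, optionally, the
#' Rauch-Tung-Striebel smoother) for the integrated Ornstein-Uhlenbeck movement
#' model over an irregular time grid.  Rows with `NA` observations are pure
#' prediction steps, which is how off-data grid times are interpolated.
#'
#' The initial state is centred on the first observation with a diffuse
#' position variance, so the first observation's likelihood contribution is
#' dropped from `loglik`.
#'
#' @param t_hr Numeric vector of times in hours, strictly increasing.
#' @param Y Two-column matrix of observed planar coordinates (km); `NA` rows
#'   are prediction-only times.
#' @param err_var Numeric vector of per-observation error variances (km^2),
#'   one per row of `Y` (ignored where `Y` is `NA`).
#' @param beta,sigma Model parameters (see above).
#' @param smooth Logical; also run the backward smoother?
#' @return A list with `loglik`, filtered (`m_filt`, `P_filt`) and, when
#'   `smooth = TRUE`, smoothed (`m_smooth`, `P_smooth`) position/velocity means
#'   and covariances.  Means are `n x 2 x 2` arrays indexed
#'   `[time, state (pos, vel), axis]`; covariances `n x 2 x 2` arrays shared by
#'   both axes.
#' @keywords internal
ctcrw_kalman <- function(t_hr, Y, err_var, beta, sigma, smooth = FALSE) {
  n <- length(t_hr)
  stopifnot(nrow(Y) == n, length(err_var) == n, beta > 0, sigma >= 0)
  if (n >= 2 && any(diff(t_hr) <= 0)) stop("times must be strictly increasing")
  obs <- !is.na(Y[, 1]) & !is.na(Y[, 2])
  if (!any(obs)) stop("no observations")
  first <- which(obs)[1]

  m_pred <- m_filt <- array(NA_real_, c(n, 2, 2))
  P_pred <- P_filt <- array(NA_real_, c(n, 2, 2))

  # prior at the first time point: diffuse position, stationary velocity
  vvar <- if (beta > 0) sigma^2 / (2 * beta) else 0
  m <- matrix(0, 2, 2)           # columns = axes
  m[1, ] <- Y[first, ]
  P <- diag(c(1e6, max(vvar, 1e-10)))
  loglik <- 0
  H <- matrix(c(1, 0), 1, 2)

  prev_t <- t_hr[first]
  for (k in seq(first, n)) {
    if (k > first) {
      st <- iou_step(beta, sigma, t_hr[k] - prev_t)
      m <- st$T %*% m
      P <- st$T %*% P %*% t(st$T) + st$Q
      P <- (P + t(P)) / 2
      prev_t <- t_hr[k]
    }
    m_pred[k, , ] <- m
    P_pred[k, , ] <- P
    if (obs[k]) {
      R <- max(err_var[k], 1e-10)
      S <- P[1, 1] + R
      K <- P[, 1] / S
      innov <- Y[k, ] - m[1, ]
      m <- m_pred[k, , ] + outer(K, innov)
      P <- P - outer(K, P[1, ])
      P <- (P + t(P)) / 2
      if (k > first) {
        loglik <- loglik + sum(-0.5 * log(2 * pi * S) - 0.5 * innov^2 / S)
      }
    }
    m_filt[k, , ] <- m
    P_filt[k, , ] <- P
  }

  out <- list(loglik = loglik, m_filt = m_filt, P_filt = P_filt,
              m_pred = m_pred, P_pred = P_pred, first = first)
  if (smooth) {
    m_s <- m_filt
    P_s <- P_filt
    if (n > first) {
      for (k in seq(n - 1, first)) {
        st <- iou_step(beta, sigma, t_hr[k + 1] - t_hr[k])
        Pp <- P_pred[k + 1, , ]
        G <- P_filt[k, , ] %*% t(st$T) %*% solve(Pp)
        m_s[k, , ] <- m_filt[k, , ] + G %*% (m_s[k + 1, , ] - m_pred[k + 1, , ])
        Ps <- P_filt[k, , ] + G %*% (P_s[k + 1, , ] - Pp) %*% t(G)
        P_s[k, , ] <- (Ps + t(Ps)) / 2
      }
    }
    out$m_smooth <- m_s
    out$P_smooth <- P_s
  }
  out
}

# Negative log-likelihood as a function of log-parameters, for optim().
#' @keywords internal
ctcrw_nll <- function(logpar, t_hr, Y, err_var) {
  beta <- exp(logpar[1])
  sigma <- exp(logpar[2])
  scale <- if (length(logpar) >= 3) exp(logpar[3]) else 1
  if (!is.finite(beta) || !is.finite(sigma)) return(1e12)
  ll <- tryCatch(
    ctcrw_kalman(t_hr, Y, err_var * scale^2, beta, sigma)$loglik,
    error = function(e) -1e12)
  if (!is.finite(ll)) return(1e12)
  -ll
}

# Exact simulation of the integrated OU process at given (possibly irregular)
# times, one axis; returns n x 2 matrix (position, velocity).
#' @keywords internal
iou_simulate_axis <- function(t_hr, beta, sigma, x0 = 0, v0 = 0) {
  n <- length(t_hr)
  out <- matrix(0, n, 2)
  out[1, ] <- c(x0, v0)
  if (n == 1) return(out)
  dts <- diff(t_hr)
  for (k in 2:n) {
    st <- iou_step(beta, sigma, dts[k - 1])
    mu <- st$T %*% out[k - 1, ]
    if (sigma > 0) {
      L <- tryCatch(t(chol(st$Q + diag(1e-14, 2))), error = function(e) NULL)
      z <- if (is.null(L)) c(0, 0) else L %*% stats::rnorm(2)
      out[k, ] <- mu + z
    } else {
      out[k, ] <- mu
    }
  }
  out
}
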