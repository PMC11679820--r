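#' Kalman filter parameters
#'
#' Linear-Gaussian state-space parameters for trajectory smoothing. The
#' default is a per-axis constant-velocity model: state = (position,
#' velocity), transition `A = [[1,1],[0,1]]`, observation `H = [1,0]`,
#' discrete-white-noise process covariance scaled by `q`, and scalar
#' observation variance `r`. With one observed coordinate per axis the
#' filter is run independently on each column of the input series.
#' There is no control input (B and u are zero): the tracked person is
#' observed passively.
#'
#' @param A State-transition matrix.
#' @param H Observation matrix.
#' @param Q Process-noise covariance (symmetric PSD).
#' @param R Observation-noise covariance (symmetric PSD).
#' @param initial_state Optional initial state; default is built from the
#'   first observation (zero velocity).
#' @param initial_covariance Optional initial state covariance; default
#'   identity (large relative to R, so early observations dominate).
#' @param q Process-noise scale used by the default Q (units^2/frame).
#' @param r Observation variance used by the default R; the default
#'   0.005^2 matches the generator's default coordinate noise.
#' @return A `kalman_params` list.
#' @export
kalman_params <- function(A = NULL, H = NULL, Q = NULL, R = NULL,
                          initial_state = NULL, initial_covariance = NULL,
                          q = 1e-4, r = 2.5e-5) {
  if (is.null(A)) A <- matrix(c(1, 0, 1, 1), 2, 2) # [[1,1],[0,1]]
  if (is.null(H)) H <- matrix(c(1, 0), 1, 2)[, seq_len(ncol(A)), drop = FALSE]
  A <- as.matrix(A)
  H <- matrix(as.matrix(H), ncol = ncol(A))
  m <- ncol(A)
  if (is.null(Q)) {
    Q <- if (m == 2L) q * matrix(c(1 / 4, 1 / 2, 1 / 2, 1), 2, 2) else q * diag(m)
  }
  if (is.null(R)) R <- diag(r, nrow(H))
  Q <- as.matrix(Q)
  R <- as.matrix(R)
  if (nrow(A) != m || any(dim(Q) != m) || ncol(H) != m || any(dim(R) != nrow(H))) {
    stop("inconsistent Kalman parameter dimensions")
  }
  for (nm in c("Q", "R")) {
    M <- get(nm)
    if (max(abs(M - t(M))) > 1e-12) stop(nm, " must be symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      stop(nm, " must be positive semi-definite")
    }
  }
  structure(
    list(
      A = A, H = H, Q = Q, R = R,
      initial_state = initial_state, initial_covariance = initial_covariance
    ),
    class = "kalman_params"
  )
}

#' Kalman-filter smoothing of a trajectory
#'
#' Runs a causal Kalman filter over an ordered series of observations,
#' returning one filtered estimate (in observation space) per input
#' point. At each step the state is propagated through the transition
#' model, the gain is recomputed from the propagated covariance, and the
#' innovation against the predicted observation corrects the state.
#'
#' With a single-row observation matrix each column of `series` is
#' filtered independently (the per-axis case used for landmark
#' trajectories); a multi-row `H` filters the columns jointly as one
#' vector observation.
#'
#' @param series Numeric vector or T x d matrix of observations, ordered
#'   in time.
#' @param params A [kalman_params()] object.
#' @return Filtered estimates with the same shape as `series`.
#' @export
kalman_smooth <- function(series, params = kalman_params()) {
  vec_in <- is.null(dim(series))
  Z <- if (vec_in) matrix(series, ncol = 1L) else as.matrix(series)
  if (nrow(Z) < 1L) stop("series must have length >= 1")
  p <- nrow(params$H)
  if (p == 1L) {
    out <- apply(Z, 2L, function(col) kalman_run(matrix(col, ncol = 1L), params))
    out <- matrix(out, nrow = nrow(Z))
  } else {
    if (ncol(Z) != p) {
      stop(sprintf("dimension mismatch: H expects %d observed components, series has %d columns", p, ncol(Z)))
    }
    out <- kalman_run(Z, params)
  }
  dimnames(out) <- dimnames(Z)
  if (vec_in) as.numeric(out) else out
}

# core filter: Z is T x p, returns T x p observation-space estimates
kalman_run <- function(Z, params) {
  A <- params$A
  H <- params$H
  Q <- params$Q
  R <- params$R
  m <- ncol(A)
  p <- nrow(H)
  x <- params$initial_state
  if (is.null(x)) {
    # least-squares state consistent with the first observation
    x <- as.numeric(qr.solve(rbind(H, diag(1e-9, m)), c(Z[1, ], rep(0, m))))
  }
  x <- matrix(x, ncol = 1L)
  P <- params$initial_covariance
  if (is.null(P)) P <- diag(1, m)
  out <- matrix(0, nrow(Z), p)
  for (k in seq_len(nrow(Z))) {
    # predict
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
    # update (gain from the propagated covariance)
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (Z[k, ] - H %*% x)
    P <- (diag(1, m) - K %*% H) %*% P
    out[k, ] <- as.numeric(H %*% x)
  }
  out
}
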