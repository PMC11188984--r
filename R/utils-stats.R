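# Small statistical primitives shared by the generator and the SSF module.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic mixing keeps every pipeline stage independently seeded from a
#' single master seed while staying within R's 32-bit integer range.
#'
#' @param master Integer master seed.
#' @param offset Integer stage offset.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset) {
  x <- (as.double(master) %% 2147483647) * 48271 + as.double(offset) * 16807 + 7
  as.integer(x %% 2147483629 + 1)
}

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on `(-pi, pi]`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
    return(wrap_angle(th + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

#' Wrap angles to (-pi, pi]
#' @param theta Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta %% (2 * pi)
  w[which(w > pi)] <- w[which(w > pi)] - 2 * pi
  w[which(w <= -pi)] <- w[which(w <= -pi)] + 2 * pi
  w
}

#' Maximum-likelihood von Mises concentration from angles
#'
#' Estimates kappa by inverting the mean resultant length with the standard
#' piecewise approximation (Fisher 1993).
#'
#' @param theta Angles (radians).
#' @return List with `mu` (mean direction) and `kappa`.
#' @export
vonmises_mle <- function(theta) {
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  kappa <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
  list(mu = mu, kappa = max(kappa, 0))
}

#' Maximum-likelihood gamma fit
#'
#' Profile likelihood in the shape parameter (scale profiled out analytically),
#' solved by Newton steps on the digamma equation.
#'
#' @param x Positive observations.
#' @return List with `shape` and `scale`.
#' @export
gamma_mle <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || any(x <= 0)) stop("gamma_mle needs positive observations")
  if (stats::sd(x) < 1e-12 * mean(x)) stop("degenerate lengths: no variation")
  s <- log(mean(x)) - mean(log(x))
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka initialization
  for (i in 1:50) {
    step <- (log(shape) - digamma(shape) - s) / (1 / shape - trigamma(shape))
    shape_new <- shape - step
    if (shape_new <= 0) shape_new <- shape / 2
    if (abs(shape_new - shape) < 1e-10 * shape) { shape <- shape_new; break }
    shape <- shape_new
  }
  list(shape = shape, scale = mean(x) / shape)
}

#' Mann-Whitney AUC helper for raw score vectors
#' @keywords internal
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
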