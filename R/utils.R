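#' @importFrom rlang abort warn .data
#' @importFrom stats cor sd median quantile rnorm runif rbinom setNames
#' @importFrom stats p.adjust pt pnorm lm coef complete.cases fisher.test var
#' @importFrom utils head
NULL

# Internal: stop with a classed condition so callers/tests can match on class.
stop_msntx <- function(msg, class) {
  rlang::abort(msg, class = c(class, "msntx_error"))
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop_msntx(sprintf("`%s` must be a positive integer.", name), "invalid_argument")
  }
  as.integer(x)
}

check_prob <- function(x, name, open_left = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1) {
    stop_msntx(sprintf("`%s` must lie in %s0, 1].", name,
                       if (open_left) "(" else "["),
               "invalid_argument")
  }
  x
}

#' Great-circle distance matrix between unit-sphere points
#'
#' @param xyz numeric matrix with three columns (unit-norm rows).
#' @return square matrix of geodesic distances in radians.
#' @keywords internal
#' @noRd
greatcircle_dist <- function(xyz) {
  g <- tcrossprod(as.matrix(xyz))
  g[g > 1] <- 1
  g[g < -1] <- -1
  acos(g)
}

#' Sample smooth spatial fields over atlas centroids
#'
#' Draws zero-mean, unit-variance Gaussian random fields with a
#' squared-exponential covariance on great-circle distance. This is the
#' spatial-autocorrelation engine behind all synthetic maps: spin tests are
#' only meaningful on autocorrelated maps, so every generated map is smooth
#' at a controllable length-scale.
#'
#' @param centroids numeric matrix (n x 3) of unit-sphere centroids.
#' @param n_fields number of independent fields to draw.
#' @param lengthscale kernel length-scale in radians.
#' @param seed integer seed; the draw is deterministic given it.
#' @return n x n_fields matrix, one field per column.
#' @export
sample_smooth_fields <- function(centroids, n_fields, lengthscale, seed) {
  n_fields <- check_positive_int(n_fields, "n_fields")
  if (lengthscale <= 0) stop_msntx("`lengthscale` must be positive.", "invalid_argument")
  d <- greatcircle_dist(centroids)
  k <- exp(-d^2 / (2 * lengthscale^2))
  # eigendecomposition with clipping: the kernel matrix is numerically
  # rank-deficient for dense parcellations
  eg <- eigen(k, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  l <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
  withr::with_seed(seed, {
    z <- matrix(rnorm(nrow(k) * n_fields), nrow(k), n_fields)
  })
  l %*% z
}

# Internal: derive a stream-specific seed from a base seed, kept in 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9176) %% 2147483629) + 1L
}
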