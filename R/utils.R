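# Small shared numerics: polynomial curves and kNN lookups.

# Evaluate polynomial with coefficients c0 + c1 x + ... at x (vectorized).
polyval <- function(coeffs, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coeffs))) y <- y * x + coeffs[k]
  y
}

polyderiv <- function(coeffs) {
  if (length(coeffs) <= 1) return(0)
  coeffs[-1] * seq_len(length(coeffs) - 1)
}

# Arc length of y = f(x) from domain[1] to each x, by trapezoidal integration
# on a 1-um parameter grid.
arc_length_fun <- function(coeffs, domain, step = 1) {
  xs <- seq(domain[1], domain[2], by = step)
  if (xs[length(xs)] < domain[2]) xs <- c(xs, domain[2])
  dy <- polyval(polyderiv(coeffs), xs)
  sp <- sqrt(1 + dy^2)
  s <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(xs)))
  stats::approxfun(xs, s, rule = 2)
}

# Unit inward normal of y = f(x): points toward increasing depth (+y side).
curve_normal <- function(coeffs, x) {
  dy <- polyval(polyderiv(coeffs), x)
  n <- cbind(-dy, 1) / sqrt(1 + dy^2)
  n
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Least-squares polynomial fit of y on x, degree `deg`, computed on
# centered/scaled x for conditioning and expanded back to raw coefficients
# c0..c_deg of y = sum c_k x^k.
poly_fit <- function(x, y, deg = 4) {
  mx <- mean(x); sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) sx <- 1
  u <- (x - mx) / sx
  U <- outer(u, 0:deg, "^")
  b <- qr.coef(qr(U), y)
  b[is.na(b)] <- 0
  # compose with u = (x - mx)/sx: expand sum b_k (a0 + a1 x)^k
  a0 <- -mx / sx; a1 <- 1 / sx
  out <- numeric(deg + 1)
  pw <- 1  # (a0 + a1 x)^0
  for (k in 0:deg) {
    out[seq_along(pw)] <- out[seq_along(pw)] + b[k + 1] * pw
    if (k < deg) {
      # multiply pw by (a0 + a1 x)
      pw <- c(pw * a0, 0) + c(0, pw * a1)
    }
  }
  out
}

# k nearest neighbours of each row of `query` among rows of `data`.
knn_index <- function(data, query, k) {
  FNN::get.knnx(data, query, k = k)$nn.index
}

knn_dist <- function(data, query, k) {
  FNN::get.knnx(data, query, k = k)
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}
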