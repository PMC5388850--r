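# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(structure(class = c("qus_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_geometry <- function(...) {
  stop(structure(class = c("qus_geometry_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("qus_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0")
  invisible(x)
}

#' @noRd
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

# Analytic signal of a real vector via the frequency-domain Hilbert method.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Envelope (modulus of the analytic signal) per column of a matrix.
envelope_matrix <- function(m) {
  apply(m, 2L, function(col) Mod(analytic_signal(col)))
}

# Summed-area table with a zero row/col prepended, so that
# sat[i1+1, j1+1] - ... gives sums over half-open pixel rectangles.
summed_area <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

rect_sum <- function(sat, r0, r1, c0, c1) {
  # half-open [r0, r1) x [c0, c1), 1-based pixel indices
  sat[r1, c1] - sat[r0, c1] - sat[r1, c0] + sat[r0, c0]
}

# Exact Euclidean distance transform with anisotropic pixel sizes, by the
# separable lower-envelope (Felzenszwalb-Huttenlocher) algorithm on squared
# distances. `mask`: logical matrix, TRUE = feature pixels. Returns distances
# in physical units (row spacing dy, column spacing dx) from every pixel to
# the nearest TRUE pixel.
distance_transform <- function(mask, dy, dx) {
  nr <- nrow(mask); nc <- ncol(mask)
  # large finite sentinel: keeps the envelope-intersection arithmetic finite
  # even after division by small squared pixel spacings
  INF <- 1e15
  d <- matrix(INF, nr, nc)
  d[mask] <- 0
  # pass 1: along columns (spacing dy)
  for (j in seq_len(nc)) d[, j] <- dt_1d(d[, j], dy)
  # pass 2: along rows (spacing dx)
  for (i in seq_len(nr)) d[i, ] <- dt_1d(d[i, ], dx)
  sqrt(d)
}

# 1-D squared-distance transform of sampled function f at spacing h.
dt_1d <- function(f, h) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  h2 <- h * h
  for (q in 2:n) {
    p <- v[k]
    s <- ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h2 * (q - p))
    while (s <= z[k]) {
      k <- k - 1L
      p <- v[k]
      s <- ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h2 * (q - p))
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  out <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    out[q] <- h2 * (q - p)^2 + f[p]
  }
  out
}
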