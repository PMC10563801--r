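# Independent oracles kept deliberately naive: they share no code with
# the package implementations they check.

# O(n^2) Pettitt statistic by the literal sign double sum
# U_t = sum_{i <= t} sum_{j > t} sign(x_j - x_i).
bf_pettitt <- function(x) {
  n <- length(x)
  U <- vapply(seq_len(n - 1), function(t) {
    sum(sign(outer(x[seq(t + 1, n)], x[seq_len(t)], "-")))
  }, 0)
  K <- max(abs(U))
  list(U = U, K = K, change_index = which.max(abs(U)))
}

# Dense (universal) kriging solve assembled element by element.
bf_krige_one <- function(xy, z, model, target) {
  n <- nrow(xy)
  gam <- function(h) {
    if (h == 0) return(0)
    u <- min(h / model$range, 1)
    g <- switch(model$family,
      spherical = model$psill * (1.5 * u - 0.5 * u^3),
      exponential = model$psill * (1 - exp(-3 * h / model$range)),
      gaussian = model$psill * (1 - exp(-3 * (h / model$range)^2)),
      stop("oracle family"))
    model$nugget + g
  }
  basis <- function(x, y) {
    b <- 1
    if (model$drift_order >= 1) b <- c(b, x, y)
    if (model$drift_order >= 2) b <- c(b, x^2, x * y, y^2)
    b
  }
  p <- length(basis(0, 0))
  A <- matrix(0, n + p, n + p)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- gam(sqrt(sum((xy[i, ] - xy[j, ])^2)))
    }
    A[i, n + seq_len(p)] <- basis(xy[i, 1], xy[i, 2])
    A[n + seq_len(p), i] <- basis(xy[i, 1], xy[i, 2])
  }
  b <- numeric(n + p)
  for (i in seq_len(n)) {
    b[i] <- gam(sqrt(sum((xy[i, ] - unlist(target))^2)))
  }
  b[n + seq_len(p)] <- basis(target$x, target$y)
  sol <- solve(A, b)
  w <- sol[seq_len(n)]
  list(pred = sum(w * z), var = sum(sol * b), weights = w)
}

make_model <- function(family = "spherical", nugget = 0, psill = 1,
                       range = 50, drift_order = 0L) {
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, drift_order = drift_order,
                 rss = 0, fallback = FALSE), class = "variogram_model")
}
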