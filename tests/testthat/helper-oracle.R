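# Independent superposition oracle: minimize RMSD over rotations
# parameterized by Euler angles, via a coarse grid plus Nelder-Mead
# refinement.  Shares no code with the SVD-based implementation.

euler_rotation <- function(a, b, c) {
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

grid_min_rmsd <- function(A, B, step = 20) {
  A <- sweep(as.matrix(A), 2, colMeans(A))
  B <- sweep(as.matrix(B), 2, colMeans(B))
  f <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((B %*% t(R) - A)^2)))
  }
  best <- NULL
  for (a in seq(0, 2 * pi, by = step * pi / 180))
    for (b in seq(0, pi, by = step * pi / 180))
      for (c in seq(0, 2 * pi, by = step * pi / 180)) {
        v <- f(c(a, b, c))
        if (is.null(best) || v < best$value) best <- list(par = c(a, b, c), value = v)
      }
  o <- stats::optim(best$par, f, method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-12))
  min(best$value, o$value)
}

# random rigid transform applied to an n x 3 coordinate matrix
random_rigid <- function(X) {
  p <- stats::runif(3, 0, 2 * pi)
  R <- euler_rotation(p[1], p[2], p[3])
  sweep(as.matrix(X) %*% t(R), 2, stats::rnorm(3, 0, 5), "+")
}
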