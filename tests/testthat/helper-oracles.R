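# Brute-force oracle for the simplex-constrained reconstruction: dense grid
# over the 2-simplex at step 1e-3, refined locally at step 1e-5.
grid_simplex_ls <- function(N, x, ridge) {
  obj <- function(Wg) {
    G <- tcrossprod(N)
    a <- drop(N %*% x)
    rowSums((Wg %*% G) * Wg) - 2 * drop(Wg %*% a) +
      ridge * rowSums(Wg^2) + sum(x^2)
  }
  grid2 <- function(lo1, hi1, lo2, hi2, step) {
    w1 <- seq(max(0, lo1), min(1, hi1), by = step)
    w2 <- seq(max(0, lo2), min(1, hi2), by = step)
    g <- expand.grid(w1 = w1, w2 = w2)
    g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
    Wg <- cbind(g$w1, g$w2, pmax(1 - g$w1 - g$w2, 0))
    Wg[which.min(obj(Wg)), ]
  }
  w <- grid2(0, 1, 0, 1, 1e-3)
  grid2(w[1] - 2e-3, w[1] + 2e-3, w[2] - 2e-3, w[2] + 2e-3, 1e-5)
}
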