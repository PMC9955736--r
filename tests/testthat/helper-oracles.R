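# Independent reference implementations used as oracles. These are written
# from the published definitions, separately from the package code paths
# they check.

# sRGB -> CIELAB with the matrix derived from the sRGB primary
# chromaticities and D65 white (rather than hard-coded coefficients).
oracle_rgb_to_lab <- function(rgb) {
  prim <- matrix(
    c(
      0.64, 0.33, # R (x, y)
      0.30, 0.60, # G
      0.15, 0.06 # B
    ),
    ncol = 2, byrow = TRUE
  )
  white_xy <- c(0.3127, 0.3290) # D65
  xyz_col <- function(x, y) c(x / y, 1, (1 - x - y) / y)
  P <- sapply(seq_len(3), function(i) xyz_col(prim[i, 1], prim[i, 2]))
  w <- xyz_col(white_xy[1], white_xy[2])
  # explicit cofactor inversion (independent of solve())
  adj <- function(A) {
    co <- matrix(0, 3, 3)
    for (i in 1:3) {
      for (j in 1:3) {
        co[i, j] <- (-1)^(i + j) * det(A[-i, -j, drop = FALSE])
      }
    }
    t(co) / det(A)
  }
  s <- as.vector(adj(P) %*% w)
  M <- P %*% diag(s) # columns scaled so M %*% (1,1,1) == white
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- as.vector(M %*% lin)
  t <- xyz / w
  f <- ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  c(116 * f[2] - 16, 500 * (f[1] - f[2]), 200 * (f[2] - f[3]))
}

# Brute-force nearest-pixel mask: sort every pixel of the image by distance
# to the centre, ties in row-major order.
oracle_spot_mask <- function(cx, cy, h, w, m) {
  px <- expand.grid(col = seq_len(w), row = seq_len(h))
  d2 <- (px$col - cx)^2 + (px$row - cy)^2
  ord <- order(d2, (px$row - 1) * w + px$col)
  cbind(row = px$row[ord[seq_len(m)]], col = px$col[ord[seq_len(m)]])
}

# Exhaustive SPXY selection on a precomputed joint distance matrix.
oracle_spxy_order <- function(d, n_cal) {
  n <- nrow(d)
  pairs <- which(d == max(d), arr.ind = TRUE)
  pairs <- pairs[order(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])), , drop = FALSE]
  sel <- sort(unique(as.integer(pairs[1, ])))
  while (length(sel) < n_cal) {
    rem <- setdiff(seq_len(n), sel)
    mind <- vapply(rem, function(i) min(d[i, sel]), 0)
    sel <- c(sel, rem[which.max(mind)])
  }
  sort(utils::head(sel, n_cal))
}

# eps-SVR dual solved as an explicit QP with kernlab::ipop:
# min 1/2 u' H u + c' u, u = (alpha; alpha*), constraint sum(alpha-alpha*)=0.
oracle_svr_qp <- function(K, y, cost, epsilon) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cvec <- c(epsilon - y, epsilon + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sol <- kernlab::ipop(
    c = cvec, H = H, A = A, b = 0, r = 0,
    l = rep(0, 2 * n), u = rep(cost, 2 * n),
    sigf = 9, maxiter = 200
  )
  u <- kernlab::primal(sol)
  coef <- u[1:n] - u[(n + 1):(2 * n)]
  # bias from free support vectors (0 < alpha < C)
  tol <- cost * 1e-5
  f0 <- as.vector(K %*% coef)
  up <- which(u[1:n] > tol & u[1:n] < cost - tol)
  lo <- which(u[(n + 1):(2 * n)] > tol & u[(n + 1):(2 * n)] < cost - tol)
  b <- mean(c(y[up] - epsilon - f0[up], y[lo] + epsilon - f0[lo]))
  list(coef = coef, b = b)
}

rbf_kernel <- function(x1, x2, gamma) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  exp(-gamma * pmax(d2, 0))
}
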