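# independent oracles, kept free of the package's Kabsch path

# quaternion-eigenvalue RMSD (Kearsley 4x4 key matrix, largest eigenvalue)
quaternion_rmsd_oracle <- function(a, b) {
  n <- nrow(a)
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  m <- crossprod(b, a)   # sum over atoms of b_i a_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# brute-force rotation search: random scan plus zooming random refinement.
# RMSD^2 under rotation R is |a|^2 + |b|^2 - 2<R, H> with H = t(a) %*% b,
# so each candidate rotation costs one 9-term dot product.
rotation_search_rmsd_oracle <- function(a, b, n_scan = 1e6) {
  n <- nrow(a)
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  h <- crossprod(a, b)
  ssq <- sum(a^2) + sum(b^2)
  quat_batch_score <- function(q) {
    # q: m x 4 (rows unit quaternions); returns <R(q), H> per row
    w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
    r11 <- 1 - 2 * (y^2 + z^2); r12 <- 2 * (x * y - w * z); r13 <- 2 * (x * z + w * y)
    r21 <- 2 * (x * y + w * z); r22 <- 1 - 2 * (x^2 + z^2); r23 <- 2 * (y * z - w * x)
    r31 <- 2 * (x * z - w * y); r32 <- 2 * (y * z + w * x); r33 <- 1 - 2 * (x^2 + y^2)
    # note <R, H> pairs R[i,j] with H[j,i] (trace of R H)
    r11 * h[1, 1] + r12 * h[2, 1] + r13 * h[3, 1] +
    r21 * h[1, 2] + r22 * h[2, 2] + r23 * h[3, 2] +
    r31 * h[1, 3] + r32 * h[2, 3] + r33 * h[3, 3]
  }
  qs <- matrix(stats::rnorm(4 * n_scan), ncol = 4)
  qs <- qs / sqrt(rowSums(qs^2))
  sc <- quat_batch_score(qs)
  best_q <- qs[which.max(sc), ]
  best <- max(sc)
  # zooming refinement around the incumbent
  for (scale in c(0.1, 0.03, 0.01, 0.003, 0.001)) {
    m <- 2e4
    pert <- matrix(stats::rnorm(3 * m, sd = scale), ncol = 3)
    ang <- sqrt(rowSums(pert^2))
    axis <- pert / pmax(ang, 1e-300)
    dq <- cbind(cos(ang / 2), sin(ang / 2) * axis)
    # compose best_q (x) dq rows
    w1 <- best_q[1]; x1 <- best_q[2]; y1 <- best_q[3]; z1 <- best_q[4]
    w2 <- dq[, 1]; x2 <- dq[, 2]; y2 <- dq[, 3]; z2 <- dq[, 4]
    qc <- cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
                w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
                w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
                w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
    sc <- quat_batch_score(qc)
    if (max(sc) > best) { best <- max(sc); best_q <- qc[which.max(sc), ] }
  }
  sqrt(max(0, (ssq - 2 * best) / n))
}

# Boltzmann marginal of the radial translation coordinate in a single
# orientation-coupled Gaussian well, by 2-D grid quadrature over (r, theta):
# p(r, theta) propto r^2 sin^2(theta/2) exp(-beta U(d)),
# d^2 = r^2 + (lambda theta)^2, U = -depth exp(-d^2/(2 w^2)) + wall(r)
boltzmann_radial_oracle <- function(depth, width, lambda, conf_r, wall_k,
                                    temperature, nr = 600, nth = 400) {
  beta <- 1 / (decoysieve::kB * temperature)
  r <- seq(1e-6, conf_r + 4, length.out = nr)
  th <- seq(1e-6, pi, length.out = nth)
  wall <- ifelse(r > conf_r, wall_k * (r - conf_r)^4, 0)
  d2 <- outer(r^2, (lambda * th)^2, "+")
  u <- -depth * exp(-d2 / (2 * width^2)) + wall
  dens <- exp(-beta * u) * outer(r^2, sin(th / 2)^2)
  pr <- rowSums(dens)            # unnormalized marginal on the r grid
  pr <- pr / sum(pr)
  m1 <- sum(pr * r)
  list(mean = m1, var = sum(pr * (r - m1)^2))
}
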