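# Independent oracles used across the suite. None of these call the
# package's solver paths: the QP oracle is a sparse KKT solve of the
# discrete-time quadratic program, the Gramian oracle uses fine-grid
# quadrature of e^(At) B B' e^(A't), the scalar oracle is the closed-form
# Euler-Lagrange solution, and the continuous integrator is plain RK4.

expm_m <- function(x) as.matrix(Matrix::expm(Matrix::Matrix(x, sparse = FALSE)))

rand_sysmat <- function(n, seed, density = 0.6, n_modules = 1L) {
  stabilize(make_connectome(n, n_modules, density = density, seed = seed))
}

# Dense discrete-time quadratic program: ZOH dynamics x_{t+1} = Ad x_t +
# Bd u_t, left-Riemann cost dt*sum(x'x + rho u'u), endpoints fixed. Solved
# as one sparse KKT system in (x_1..x_{K-1}, u_0..u_{K-1}, multipliers).
qp_oracle <- function(A, B, x0, xT, Th, rho, K) {
  n <- nrow(A); m <- ncol(B); dt <- Th / K
  Ad <- expm_m(A * dt)
  Bd <- solve(A, Ad - diag(n)) %*% B
  nx <- (K - 1L) * n; nu <- K * m; nv <- nx + nu
  xi <- function(t) (t - 1L) * n + 1:n      # x_t variables, t = 1..K-1
  tl <- list(); ct <- 1L
  add <- function(r, c, M) {
    w <- which(M != 0, arr.ind = TRUE)
    if (nrow(w)) { tl[[ct]] <<- cbind(r[w[, 1]], c[w[, 2]], M[w]); ct <<- ct + 1L }
  }
  b <- numeric(K * n)
  I_n <- diag(n)
  for (t in 0:(K - 1L)) {
    r <- t * n + 1:n                        # constraint block for step t
    if (t < K - 1L) add(r, xi(t + 1L), I_n)
    if (t >= 1L) add(r, xi(t), -Ad)
    add(r, nx + t * m + 1:m, -Bd)
    if (t == 0L) b[r] <- Ad %*% x0
    if (t == K - 1L) b[r] <- b[r] - xT
  }
  tm <- do.call(rbind, tl)
  Aeq <- Matrix::sparseMatrix(i = tm[, 1], j = tm[, 2], x = tm[, 3],
                              dims = c(K * n, nv))
  hd <- c(rep(2 * dt, nx), rep(2 * rho * dt, nu))
  KKT <- rbind(cbind(Matrix::Diagonal(x = hd), Matrix::t(Aeq)),
               cbind(Aeq, Matrix::Matrix(0, K * n, K * n)))
  sol <- Matrix::solve(KKT, c(numeric(nv), b))
  z <- as.numeric(sol)[1:nv]
  xs <- cbind(x0, matrix(z[seq_len(nx)], n, K - 1L), xT)
  us <- matrix(z[nx + seq_len(nu)], m, K)
  list(cost = dt * sum(xs[, 1:K]^2) + rho * dt * sum(us^2),
       energy = dt * sum(us^2),
       x = xs, u = us, Ad = Ad, Bd = Bd, dt = dt)
}

# Cost of an explicit discrete control sequence under the QP's dynamics.
qp_cost_of <- function(orc, x0, us, rho) {
  K <- ncol(us); n <- length(x0)
  xs <- matrix(0, n, K + 1L); xs[, 1L] <- x0
  for (t in seq_len(K)) xs[, t + 1L] <- orc$Ad %*% xs[, t] + orc$Bd %*% us[, t]
  list(cost = orc$dt * sum(xs[, 1:K]^2) + rho * orc$dt * sum(us^2),
       xK = xs[, K + 1L])
}

# Minimum-energy cost via the finite-horizon controllability Gramian,
# computed by fine trapezoid quadrature of e^(At) BB' e^(A't).
gramian_energy <- function(A, B, x0, xT, Th, K = 2000L) {
  n <- nrow(A); dt <- Th / K
  W <- matrix(0, n, n)
  Ed <- expm_m(A * dt)
  e <- diag(n)
  BBt <- B %*% t(B)
  for (k in 0:K) {
    w <- if (k == 0L || k == K) 0.5 else 1
    W <- W + w * (e %*% BBt %*% t(e)) * dt
    e <- Ed %*% e
  }
  eT <- expm_m(A * Th)
  v <- xT - eT %*% x0
  drop(t(v) %*% solve(W, v))
}

# Closed-form Euler-Lagrange solution of the scalar problem (A = -a,
# B = 1): x'' = (a^2 + 1/rho) x, u = x' + a x, energy integrated exactly.
scalar_oracle <- function(a, rho, Th, x0, xT) {
  om <- sqrt(a^2 + 1 / rho)
  cc <- solve(rbind(c(1, 1), c(exp(om * Th), exp(-om * Th))), c(x0, xT))
  al <- cc[1] * (om + a); be <- cc[2] * (a - om)
  energy <- al^2 * (exp(2 * om * Th) - 1) / (2 * om) + 2 * al * be * Th +
    be^2 * (1 - exp(-2 * om * Th)) / (2 * om)
  x_of <- function(t) cc[1] * exp(om * t) + cc[2] * exp(-om * t)
  u_of <- function(t) al * exp(om * t) + be * exp(-om * t)
  list(energy = energy, x_of = x_of, u_of = u_of)
}

# RK4 integration of dx/dt = A x + B u(t) with zero-order-hold input.
rk4_zoh <- function(A, B, x0, u_seq, Ts, substeps = 100L) {
  n <- length(x0); K <- ncol(u_seq)
  h <- Ts / substeps
  X <- matrix(0, n, K + 1L); X[, 1L] <- x0
  x <- x0
  f <- function(x, u) A %*% x + B %*% u
  for (k in seq_len(K)) {
    u <- u_seq[, k]
    for (s in seq_len(substeps)) {
      k1 <- f(x, u); k2 <- f(x + h / 2 * k1, u)
      k3 <- f(x + h / 2 * k2, u); k4 <- f(x + h * k3, u)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    X[, k + 1L] <- x
  }
  X
}
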