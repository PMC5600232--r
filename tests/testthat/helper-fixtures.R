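# shared fixtures: small simulator configs, exact-moment data, and an
# independent bivariate-normal CDF for oracle computations

small_sim <- function(n_hospitals = 3, departments_per_hospital = 3,
                      respondents_per_department = 25, seed = 1L, ...) {
  simulate_survey(sim_config(n_hospitals = n_hospitals,
                             departments_per_hospital = departments_per_hospital,
                             respondents_per_department = respondents_per_department,
                             seed = seed, ...))
}

# data matrix whose *sample* covariance equals Sigma exactly
exact_cov_data <- function(n, Sigma, seed = 1L) {
  set.seed(seed)
  p <- ncol(Sigma)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(cov(X)))
  X %*% chol(Sigma)
}

# Independent bivariate normal CDF on a grid of correlations, using the
# correlation-integral identity
#   Phi2(h, k, rho) = Phi(h)Phi(k) + (2*pi)^-1 Int_0^rho f(r) dr
# evaluated by cumulative trapezoid over the rho grid (an algorithm
# unrelated to the package's conditional-CDF quadrature).
phi2_grid_oracle <- function(h, k, rho_grid) {
  f <- function(r) exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
    sqrt(1 - r^2)
  base <- pnorm(h) * pnorm(k)
  cumtrap <- function(x, y) cumsum(diff(x) * (head(y, -1) + y[-1]) / 2)
  o <- order(rho_grid)
  rg <- rho_grid[o]
  pos <- rg[rg >= 0]
  neg_abs <- abs(rev(rg[rg < 0]))          # ascending |rho|
  cp <- if (length(pos)) cumtrap(c(0, pos), f(c(0, pos))) else numeric(0)
  cn <- if (length(neg_abs))
    cumtrap(c(0, neg_abs), f(-c(0, neg_abs))) else numeric(0)
  out_sorted <- c(base - rev(cn) / (2 * pi), base + cp / (2 * pi))
  out <- numeric(length(rho_grid))
  out[o] <- out_sorted
  out
}

# independent brute-force polychoric oracle: grid search of the
# contingency likelihood over rho
polychoric_grid_oracle <- function(tab, rho_grid = seq(-0.99, 0.99, by = 0.001)) {
  n <- sum(tab)
  tx <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n)
  ty <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / n)
  ax <- c(-Inf, tx, Inf); by <- c(-Inf, ty, Inf)
  Kx <- nrow(tab); Ky <- ncol(tab)
  # cumulative CDF at every inner threshold pair, for all rho at once
  C <- array(0, c(Kx + 1, Ky + 1, length(rho_grid)))
  for (r in 2:Kx) for (s in 2:Ky)
    C[r, s, ] <- phi2_grid_oracle(ax[r], by[s], rho_grid)
  for (r in 2:(Kx + 1)) C[r, Ky + 1, ] <- pnorm(ax[r])
  for (s in 2:(Ky + 1)) C[Kx + 1, s, ] <- pnorm(by[s])
  nll <- vapply(seq_along(rho_grid), function(g) {
    pr <- C[2:(Kx + 1), 2:(Ky + 1), g] - C[1:Kx, 2:(Ky + 1), g] -
      C[2:(Kx + 1), 1:Ky, g] + C[1:Kx, 1:Ky, g]
    -sum(tab * log(pmax(pr, 1e-12)))
  }, numeric(1))
  rho_grid[which.min(nll)]
}

# random ordinal contingency table from a latent bivariate normal
random_ordinal_table <- function(n = 500, k = 4) {
  repeat {
    rho <- runif(1, -0.85, 0.85)
    tx <- sort(runif(k - 1, -1.5, 1.5))
    ty <- sort(runif(k - 1, -1.5, 1.5))
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    x <- findInterval(z1, tx); y <- findInterval(z2, ty)
    if (length(unique(x)) == k && length(unique(y)) == k)
      return(table(x, y))
  }
}
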