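#' @keywords internal
#' Standard bivariate normal CDF P(X <= a, Y <= b) with correlation rho.
#' Computed by Gauss-Legendre quadrature of
#'   integral_{-Inf}^{a} phi(x) Phi((b - rho x)/sqrt(1-rho^2)) dx,
#' vectorized over b. Accurate to ~1e-10 for |rho| <= 0.999.
.pbinorm <- function(a, b, rho, n_nodes = 48L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (!is.finite(a) && a > 0) return(pnorm(b))
  if (!is.finite(a) && a < 0) return(rep(0, length(b)))
  s <- sqrt(1 - rho^2)
  lo <- -8.5; hi <- min(a, 8.5)
  if (hi <= lo) return(rep(0, length(b)))
  gl <- .gauss_legendre(n_nodes)
  x <- (hi - lo) / 2 * gl$nodes + (hi + lo) / 2
  w <- (hi - lo) / 2 * gl$weights * dnorm(x)
  out <- numeric(length(b))
  fin <- is.finite(b)
  if (any(fin)) {
    z <- outer(rho * x, b[fin], function(rx, bb) (bb - rx) / s)
    out[fin] <- as.vector(w %*% pnorm(z))
  }
  out[!fin & b > 0] <- pnorm(a)
  out[!fin & b < 0] <- 0
  out
}

# cached Gauss-Legendre rule on [-1, 1]
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  # Golub-Welsch: eigen decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  rule <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- rule
  rule
}

# Cell probabilities of the discretized bivariate normal: matrix pi[r, s]
# for thresholds tau_x (length Kx-1), tau_y (length Ky-1), correlation rho.
.bvn_cell_probs <- function(tau_x, tau_y, rho) {
  ax <- c(-Inf, tau_x, Inf)
  by <- c(-Inf, tau_y, Inf)
  Kx <- length(ax) - 1L; Ky <- length(by) - 1L
  # cumulative C[r, s] = P(X <= ax[r+1], Y <= by[s+1])
  C <- matrix(0, Kx + 1L, Ky + 1L)
  for (r in 2:(Kx + 1L))
    C[r, 2:(Ky + 1L)] <- .pbinorm(ax[r], by[2:(Ky + 1L)], rho)
  C[, Ky + 1L][-1] <- pnorm(ax[-1])          # b = +Inf margin
  C[Kx + 1L, -1] <- pnorm(by[-1])            # a = +Inf margin
  C[Kx + 1L, Ky + 1L] <- 1
  C[2:(Kx + 1L), 2:(Ky + 1L)] - C[1:Kx, 2:(Ky + 1L)] -
    C[2:(Kx + 1L), 1:Ky] + C[1:Kx, 1:Ky]
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum-likelihood estimator assuming a latent bivariate
#' normal: thresholds are the standard-normal quantiles of the cumulative
#' marginal proportions; given the thresholds, the correlation maximizes
#' the contingency-table likelihood \eqn{\sum_{rs} n_{rs} \log
#' \pi_{rs}(\rho, \tau)} by one-dimensional search on (-0.999, 0.999).
#' For two binary variables this is the tetrachoric correlation.
#'
#' @param x,y Ordinal vectors (integer codes); pairs with missing values
#'   are dropped.
#' @return List of class `cqi_polychoric`: `rho`, `tau_x`, `tau_y`,
#'   `var_rho` (the approximation \eqn{(1-\hat\rho^2)^2/N}), `n`,
#'   `loglik`.
#' @examples
#' x <- findInterval(rnorm(500), c(-1, 0, 1))
#' y <- findInterval(rnorm(500), c(-1, 0, 1))
#' estimate_polychoric(x, y)$rho  # near 0 for independent variables
#' @export
estimate_polychoric <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("too few complete pairs", call. = FALSE)
  lx <- sort(unique(x)); ly <- sort(unique(y))
  if (length(lx) < 2L || length(ly) < 2L)
    stop("degenerate variable: fewer than 2 observed categories",
         call. = FALSE)
  tab <- table(factor(x, levels = lx), factor(y, levels = ly))
  tau_x <- qnorm(cumsum(rowSums(tab))[-length(lx)] / n)
  tau_y <- qnorm(cumsum(colSums(tab))[-length(ly)] / n)
  nll <- function(rho) {
    p <- .bvn_cell_probs(tau_x, tau_y, rho)
    -sum(tab * log(pmax(p, 1e-12)))
  }
  opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  structure(list(rho = rho, tau_x = unname(tau_x), tau_y = unname(tau_y),
                 var_rho = (1 - rho^2)^2 / n, n = n,
                 loglik = -opt$objective),
            class = "cqi_polychoric")
}

#' Pairwise polychoric correlation matrix with precision weights
#'
#' Estimates every pairwise polychoric (tetrachoric where both items are
#' binary) correlation among the given items, together with precision
#' weights on the root-n asymptotic scale, \eqn{w_{ij} = 1/(1 -
#' \hat\rho_{ij}^2)^2} — i.e. the reciprocal of
#' \eqn{N \cdot \widehat{Var}(\hat\rho_{ij})} under the approximation
#' \eqn{\widehat{Var}(\hat\rho) \approx (1-\hat\rho^2)^2/N}.  If the
#' assembled matrix is not positive semi-definite it is repaired by
#' flooring its eigenvalues and rescaling to unit diagonal (logged via a
#' warning and the `repaired` field).
#'
#' @param ds A `cqi_survey` or data frame of ordinal columns.
#' @param items Character vector of item columns (default: all mapped
#'   items for a `cqi_survey`).
#' @return List with `rho` (symmetric correlation matrix), `weights`
#'   (symmetric weight matrix), `n` (median pairwise N), `repaired`.
#' @export
polychoric_matrix <- function(ds, items = NULL) {
  d <- if (inherits(ds, "cqi_survey")) ds$data else ds
  if (is.null(items)) {
    if (inherits(ds, "cqi_survey")) items <- intersect(map_items(ds$item_map),
                                                       names(d))
    else items <- names(d)
  }
  p <- length(items)
  R <- diag(p); W <- matrix(0, p, p)
  dimnames(R) <- dimnames(W) <- list(items, items)
  ns <- numeric(0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    est <- estimate_polychoric(d[[items[i]]], d[[items[j]]])
    R[i, j] <- R[j, i] <- est$rho
    W[i, j] <- W[j, i] <- 1 / (1 - est$rho^2)^2
    ns <- c(ns, est$n)
  }
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    repaired <- TRUE
    vals <- pmax(ev$values, 1e-6)
    R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    Dinv <- diag(1 / sqrt(diag(R2)))
    R <- Dinv %*% R2 %*% Dinv
    dimnames(R) <- list(items, items)
    warning("polychoric matrix was not positive semi-definite; ",
            "nearest-PSD repair applied", call. = FALSE)
  }
  list(rho = R, weights = W, n = if (length(ns)) median(ns) else nrow(d),
       repaired = repaired)
}
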