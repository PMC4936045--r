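# Shared fixtures: tiny deterministic landscapes, toy GLMM datasets, and an
# independent adaptive Gauss-Hermite quadrature oracle for the marginal
# likelihood of a single-factor logistic mixed model.

# Small landscape with fully known layers on an n x n grid of 100 m cells.
tiny_landscape <- function(n = 10, cell = 100) {
  g <- grid_spec(n, n, cell_size = cell)
  cc <- cell_centers(g)
  xs <- matrix(rep(cc$x, each = n), n, n)   # [row, col] = x of col
  ys <- matrix(rep(cc$y, times = n), n, n)  # [row, col] = y of row
  continuous <- list(
    dist_habitation = xs / 1000,            # increases eastwards, km
    dist_road = ys / 1000,
    dist_forest_road = (xs + ys) / 2000,
    ndvi = 0.8 * (xs / max(xs)) - 0.2)
  landcover <- matrix(rep_len(1:7, n * n), n, n)
  list(grid = g,
       stack = landscape_stack(g, continuous, landcover),
       xs = xs, ys = ys)
}

# Single-factor logistic mixed data with known generating parameters.
make_toy_glmm <- function(seed, n_g = 8, n_per = 20, sigma2 = 0.15,
                          beta = c(-0.2, 0.5, -0.4)) {
  set.seed(seed)
  g <- rep(sprintf("g%d", seq_len(n_g)), each = n_per)
  x1 <- stats::rnorm(n_g * n_per)
  x2 <- stats::rnorm(n_g * n_per)
  u <- stats::rnorm(n_g, 0, sqrt(sigma2))
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + u[match(g, unique(g))]
  y <- stats::rbinom(n_g * n_per, 1, stats::plogis(eta))
  tibble::tibble(is_used = y, bear_id = g, year = 1L, survival = 0,
                 x1 = x1, x2 = x2)
}

toy_spec <- function() model_spec(c("x1", "x2"), character(),
                                  random_factors = "bear_id")

# Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-t^2)).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = (e$vectors[1, ]^2) * sqrt(pi))
}

# Adaptive GH marginal log-likelihood for y ~ logistic(X beta + u[g]),
# u ~ N(0, sigma2), independent groups. Entirely separate from the package's
# Laplace path.
aghq_loglik <- function(beta, sigma2, y, X, g, n_nodes = 64) {
  gh <- gauss_hermite(n_nodes)
  groups <- unique(g)
  off <- drop(X %*% beta)
  total <- 0
  for (gr in groups) {
    sel <- g == gr
    f <- function(u)
      sum(y[sel] * (off[sel] + u) - log1p(exp(off[sel] + u))) +
        stats::dnorm(u, 0, sqrt(sigma2), log = TRUE)
    # 1-D mode by Newton
    u <- 0
    for (it in 1:50) {
      eta <- off[sel] + u
      mu <- stats::plogis(eta)
      g1 <- sum(y[sel] - mu) - u / sigma2
      h <- sum(mu * (1 - mu)) + 1 / sigma2
      step <- g1 / h
      u <- u + step
      if (abs(step) < 1e-12) break
    }
    tau <- 1 / sqrt(sum(stats::plogis(off[sel] + u) *
                          (1 - stats::plogis(off[sel] + u))) + 1 / sigma2)
    t_k <- u + sqrt(2) * tau * gh$nodes
    logf <- vapply(t_k, f, 0) + gh$nodes^2 + log(gh$weights)
    m <- max(logf)
    total <- total + log(sqrt(2) * tau) + m + log(sum(exp(logf - m)))
  }
  total
}

# One small prepared synthetic study shared by prep/pipeline tests.
small_truth <- function() {
  truth_config(n_bear_years = c(successful = 5, unsuccessful = 4),
               n_individuals = c(successful = 4, unsuccessful = 3),
               fixes_per_day = 12, home_radius = 800)
}

small_study <- function(seed = 42) {
  simulate_study(truth = small_truth(),
                 grid = grid_spec(120, 120, cell_size = 25),
                 seed = seed)
}
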