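test_that("the logistic log-likelihood has its closed forms and stays stable", {
  tt <- make_toy_glmm(1)
  sp <- toy_spec()
  # null model: beta = 0, u = 0 -> -n log 2
  b0 <- c(0, 0, 0)
  expect_equal(logistic_loglik(b0, NULL, tt, sp), -nrow(tt) * log(2))

  # extreme eta does not overflow; a y = 1 row at eta = +50 contributes ~ 0
  ext <- tibble::tibble(is_used = 1, bear_id = "g", year = 1L, survival = 0,
                        x1 = 50, x2 = 0)
  ll <- logistic_loglik(c(0, 1, 0), NULL, ext, sp)
  expect_true(is.finite(ll))
  expect_lt(abs(ll), 1e-20)
  # and a y = 0 row at eta = +50 contributes -50
  ext0 <- ext; ext0$is_used <- 0
  expect_equal(logistic_loglik(c(0, 1, 0), NULL, ext0, sp), -50)

  # random instance equals a direct per-row summation oracle
  set.seed(2)
  beta <- rnorm(3); u <- list(bear_id = rnorm(8))
  X <- cbind(1, tt$x1, tt$x2)
  eta <- drop(X %*% beta) + u$bear_id[match(tt$bear_id, unique(tt$bear_id))]
  oracle <- sum(ifelse(tt$is_used == 1, eta, 0) - log(1 + exp(eta)))
  expect_equal(logistic_loglik(beta, u, tt, sp), oracle, tolerance = 1e-12)
})

test_that("the random-effect mode behaves in limits and matches a search oracle", {
  tt <- make_toy_glmm(3)
  sp <- toy_spec()
  beta <- c(-0.2, 0.5, -0.4)

  # vanishing variance pins the intercepts at zero
  jm0 <- joint_mode(beta, 1e-9, 0, tt, sp)
  expect_lt(max(abs(jm0$u$bear_id)), 1e-6)

  # single group with balanced outcomes and no covariate effect: u* = 0
  sym <- tibble::tibble(is_used = rep(c(0, 1), 10), bear_id = "g", year = 1L,
                        survival = 0, x1 = 0, x2 = 0)
  jms <- joint_mode(c(0, 0, 0), 1, 0, sym, sp)
  expect_equal(unname(jms$u$bear_id), 0, tolerance = 1e-9)

  # 3 groups, 10 rows: matches a derivative-free search on the penalized
  # objective coded from scratch
  set.seed(4)
  small <- tibble::tibble(is_used = rbinom(10, 1, 0.5),
                          bear_id = rep(c("a", "b", "c"), c(4, 3, 3)),
                          year = 1L, survival = 0,
                          x1 = rnorm(10), x2 = rnorm(10))
  s2 <- 0.8
  jm <- joint_mode(beta, s2, 0, small, sp)
  X <- cbind(1, small$x1, small$x2)
  gi <- match(small$bear_id, unique(small$bear_id))
  pen_obj <- function(u) {
    eta <- drop(X %*% beta) + u[gi]
    sum(small$is_used * eta - log(1 + exp(eta))) - sum(u^2) / (2 * s2)
  }
  opt <- optim(c(0, 0, 0), function(u) -pen_obj(u), method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(jm$u$bear_id), opt$par, tolerance = 1e-6)
})

test_that("the Laplace marginal reduces to plain logistic at zero variance", {
  tt <- make_toy_glmm(5)
  sp <- toy_spec()
  beta <- c(0.1, 0.3, -0.2)
  expect_equal(laplace_marginal_loglik(beta, 0, 0, tt, sp),
               logistic_loglik(beta, NULL, tt, sp), tolerance = 1e-9)
  # near-zero variance converges to the same limit
  expect_equal(laplace_marginal_loglik(beta, 1e-9, 0, tt, sp),
               logistic_loglik(beta, NULL, tt, sp), tolerance = 1e-5)
})

test_that("the Laplace marginal tracks an adaptive Gauss-Hermite oracle", {
  for (s in 1:10) {
    tt <- make_toy_glmm(100 + s)
    sp <- toy_spec()
    X <- cbind(1, tt$x1, tt$x2)
    beta <- c(-0.2, 0.5, -0.4) + rnorm(3, 0, 0.1)
    s2 <- runif(1, 0.05, 0.5)
    lap <- laplace_marginal_loglik(beta, s2, 0, tt, sp)
    agq <- aghq_loglik(beta, s2, tt$is_used, X, tt$bear_id)
    expect_lt(abs(lap - agq), 0.05)
  }
})

test_that("duplicating every row doubles the data term of the likelihood", {
  tt <- make_toy_glmm(7)
  sp <- toy_spec()
  beta <- c(0.2, -0.3, 0.4); u <- list(bear_id = rnorm(8, 0, 0.3))
  dup <- tt[rep(seq_len(nrow(tt)), each = 2), ]
  expect_equal(logistic_loglik(beta, u, dup, sp),
               2 * logistic_loglik(beta, u, tt, sp), tolerance = 1e-9)
})

test_that("fitting recovers null data and matches the IRLS logistic oracle", {
  set.seed(11)
  n <- 800
  tt <- tibble::tibble(is_used = rbinom(n, 1, 0.5),
                       bear_id = rep(sprintf("b%d", 1:8), each = n / 8),
                       year = rep(1:4, n / 4), survival = 0,
                       x1 = rnorm(n), x2 = rnorm(n))
  sp <- model_spec(c("x1", "x2"), character())
  fit <- fit_rsf(tt, sp)
  expect_true(fit$converged)
  expect_true(all(abs(fit$beta) < 3 * fit$se))
  expect_lt(fit$sigma2[["bear_id"]], 0.05)
  expect_lt(fit$sigma2[["year"]], 0.05)

  # variance components forced to zero reproduce glm exactly
  f0 <- fit_rsf(tt, sp, fix_sigma2 = c(0, 0))
  gl <- glm(is_used ~ x1 + x2, family = binomial, data = tt)
  expect_lt(max(abs(f0$beta - coef(gl))), 1e-6)
  expect_lt(abs(f0$loglik - as.numeric(logLik(gl))), 1e-6)
  expect_equal(unname(f0$se), unname(summary(gl)$coefficients[, 2]),
               tolerance = 1e-5)

  # dropping the random factors altogether takes the same path
  spf <- model_spec(c("x1", "x2"), character(), random_factors = character())
  ff <- fit_rsf(tt, spf)
  expect_lt(max(abs(ff$beta - coef(gl))), 1e-6)
  expect_equal(ff$k, 3L)

  # rank deficiency is reported with the aliased term
  tt$x3 <- tt$x1
  expect_error(fit_rsf(tt, model_spec(c("x1", "x2", "x3"), character())),
               "aliased.*x3")
})

test_that("the fitted crossed model agrees with the glmer Laplace reference", {
  set.seed(17)
  n <- 1200
  id <- rep(sprintf("b%d", 1:12), each = n / 12)
  yr <- sprintf("y%d", (seq_len(n) - 1) %% 6 + 1)
  u_id <- rnorm(12, 0, 0.4); u_yr <- rnorm(6, 0, 0.25)
  x1 <- rnorm(n)
  eta <- -0.1 + 0.6 * x1 + u_id[match(id, unique(id))] +
    u_yr[match(yr, unique(yr))]
  y <- rbinom(n, 1, plogis(eta))
  tt <- tibble::tibble(is_used = y, bear_id = id, year = yr, survival = 0,
                       x1 = x1, x2 = 0)
  sp <- model_spec("x1", character())
  fit <- fit_rsf(tt, sp)
  gm <- lme4::glmer(y ~ x1 + (1 | id) + (1 | yr), family = binomial)
  # same approximation family: near-identical estimates and likelihood
  expect_lt(max(abs(fit$beta - lme4::fixef(gm))), 0.02)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(gm))), 0.1)
  vc <- as.data.frame(lme4::VarCorr(gm))
  expect_equal(fit$sigma2[["bear_id"]], vc$vcov[vc$grp == "id"],
               tolerance = 0.1)
})

test_that("the profiled marginal peaks at the fitted variance components", {
  tt <- make_toy_glmm(19, sigma2 = 0.4)
  sp <- toy_spec()
  fit <- fit_rsf(tt, sp)
  s2_hat <- max(fit$sigma2[["bear_id"]], 1e-6)
  at <- function(s2) laplace_marginal_loglik(fit$beta, s2, 0, tt, sp)
  expect_gte(at(s2_hat) + 1e-8, at(s2_hat * 3))
  expect_gte(at(s2_hat) + 1e-8, at(s2_hat / 3 + 1e-8))
  expect_gte(at(s2_hat) + 1e-8, at(s2_hat * 9))
})

test_that("AICc and Akaike weights follow their closed forms", {
  expect_equal(aicc(-100, 3, 100), 206.25)
  expect_error(aicc(-100, 10, 11), "n must exceed")
  # AICc -> AIC as n grows
  expect_lt(abs(aicc(-500, 5, 1e7) - (2 * 500 + 2 * 5)), 1e-3)
  set.seed(23)
  for (i in 1:20) {
    ll <- runif(1, -500, -10); k <- sample(2:10, 1); n <- k + 1 + sample(5:500, 1)
    expect_equal(aicc(ll, k, n), -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }

  expect_equal(akaike_weights(123.4), 1)
  expect_equal(akaike_weights(c(50, 50)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(0.731, 0.269), tolerance = 1e-3)
  set.seed(24)
  v <- runif(6, 100, 140)
  expect_equal(sum(akaike_weights(v)), 1)
  expect_equal(akaike_weights(v + 17.3), akaike_weights(v), tolerance = 1e-12)
})
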