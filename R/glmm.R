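# Use-availability logistic GLMM with crossed random intercepts for bear
# identity and year, fitted by maximum likelihood with a Laplace-approximated
# marginal likelihood. The inner problem (fixed effects + random-effect modes)
# is solved by penalized Newton iterations; the outer problem optimizes the
# two variance components on the log scale.

#' Candidate model specification
#'
#' @param fixed_terms Covariate column names entering as main effects.
#' @param interaction_terms Subset of `fixed_terms` interacted with the
#'   litter-survival flag.
#' @param random_factors Grouping columns receiving random intercepts
#'   (default crossed `bear_id` and `year`); may be `character(0)` for a
#'   plain logistic fit.
#' @param include_survival_main Include the survival main effect; defaults to
#'   TRUE whenever any interaction is present (hierarchical well-formedness).
#'   With per-bear matched availability this effect is design-confounded and
#'   expected near zero.
#' @param label Optional model label.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed_terms, interaction_terms = character(),
                       random_factors = c("bear_id", "year"),
                       include_survival_main = length(interaction_terms) > 0,
                       label = NULL) {
  if (!all(interaction_terms %in% fixed_terms))
    stop("interaction_terms must be a subset of fixed_terms")
  if (length(interaction_terms) && !include_survival_main)
    stop("interactions require the survival main effect")
  if (is.null(label))
    label <- paste0("m(", paste(fixed_terms, collapse = "+"),
                    if (length(interaction_terms))
                      paste0(" | x surv: ",
                             paste(interaction_terms, collapse = "+")), ")")
  structure(list(fixed_terms = fixed_terms,
                 interaction_terms = interaction_terms,
                 random_factors = random_factors,
                 include_survival_main = include_survival_main,
                 label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$label, "\n")
  cat("  random intercepts:",
      if (length(x$random_factors)) paste(x$random_factors, collapse = " + ")
      else "(none)", "\n")
  invisible(x)
}

# Fixed-effects design matrix from a use_avail_table and a model_spec.
# Rank is only enforced when fitting; evaluation-only callers may pass
# degenerate designs (constant columns, single rows).
build_design <- function(table, spec, check_rank = FALSE) {
  cols <- list("(Intercept)" = rep(1, nrow(table)))
  for (t in spec$fixed_terms) {
    if (!t %in% colnames(table)) stop("term not in table: ", t)
    cols[[t]] <- table[[t]]
  }
  if (spec$include_survival_main) {
    if (length(unique(table$survival)) < 2)
      stop("survival has no variation")
    cols[["survival"]] <- table$survival
  }
  for (t in spec$interaction_terms)
    cols[[paste0(t, "_x_survival")]] <- table[[t]] * table$survival
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (check_rank) {
    qr_ <- qr(X)
    if (qr_$rank < ncol(X)) {
      aliased <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
      stop("rank-deficient design; aliased terms: ",
           paste(aliased, collapse = ", "))
    }
  }
  X
}

# 0/1 indicator matrix for one grouping factor (levels in first-appearance
# order), plus the level index per row.
group_structure <- function(table, factors) {
  Zs <- list(); idx <- list(); levels <- list()
  for (f in factors) {
    g <- as.character(table[[f]])
    lev <- unique(g)
    i <- match(g, lev)
    Z <- matrix(0, nrow(table), length(lev))
    Z[cbind(seq_along(i), i)] <- 1
    colnames(Z) <- paste0(f, ":", lev)
    Zs[[f]] <- Z; idx[[f]] <- i; levels[[f]] <- lev
  }
  list(Z = Zs, idx = idx, levels = levels)
}

# log(1 + exp(eta)) without overflow
log1pexp <- function(eta) {
  out <- eta
  small <- eta <= 33
  out[small] <- log1p(exp(eta[small]))
  out
}

#' Logistic log-likelihood at given coefficients and random intercepts
#'
#' `sum(y * eta - log(1 + exp(eta)))` with
#' `eta = X beta + u_id[bear] + u_year[year]`, computed in a form stable for
#' large `|eta|`.
#'
#' @param beta Named fixed-effect coefficients matching the design implied by
#'   `spec` (intercept first).
#' @param u Named list of random-intercept vectors, one per random factor
#'   (entries per level, first-appearance order), or NULL for none.
#' @param table A use-availability table.
#' @param spec A [model_spec()].
#' @return The log-likelihood (a scalar).
#' @export
logistic_loglik <- function(beta, u = NULL, table, spec) {
  X <- build_design(table, spec)
  if (!all(is.finite(X))) stop("non-finite covariates in design")
  eta <- drop(X %*% beta)
  if (length(spec$random_factors) && !is.null(u)) {
    gs <- group_structure(table, spec$random_factors)
    for (f in spec$random_factors)
      eta <- eta + u[[f]][gs$idx[[f]]]
  }
  y <- table$is_used
  sum(y * eta - log1pexp(eta))
}

# Penalized Newton solver. Maximizes
#   sum(y*eta - log1pexp(eta)) - 0.5 * v' P v
# over v, where eta = C v and P is a diagonal penalty (zero on unpenalized
# coordinates). Returns the mode, the (dense) curvature C'WC + P at the mode,
# and the penalized objective value.
penalized_newton <- function(C, y, pen_diag, v0 = NULL, tol = 1e-9,
                             max_iter = 100) {
  d <- ncol(C)
  v <- if (is.null(v0)) numeric(d) else v0
  obj <- function(v) {
    eta <- drop(C %*% v)
    sum(y * eta - log1pexp(eta)) - 0.5 * sum(pen_diag * v^2)
  }
  f <- obj(v)
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(C %*% v)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(C, y - mu)) - pen_diag * v
    w <- mu * (1 - mu)
    H <- crossprod(C, C * w)
    diag(H) <- diag(H) + pen_diag
    step <- tryCatch(solve(H, g), error = function(e) {
      diag(H) <- diag(H) + 1e-8 * max(diag(H))
      solve(H, g)
    })
    # step halving
    t <- 1; f_new <- obj(v + step)
    while (!is.finite(f_new) || f_new < f - 1e-12) {
      t <- t / 2
      if (t < 1e-10) break
      f_new <- obj(v + t * step)
    }
    v <- v + t * step
    moved <- max(abs(t * step))
    f <- f_new
    if (moved < tol) break
  }
  list(v = v, H = H, obj = f, n_iter = it, converged = moved < tol * 10)
}

#' Joint mode of the random intercepts
#'
#' For fixed coefficients and variance components, maximizes the penalized
#' log-likelihood `loglik(beta, u) - sum(u^2 / (2 sigma^2))` over the random
#' intercepts by Newton iterations, and returns the curvature at the mode
#' (the negative second derivative of the penalized objective in `u`).
#' A variance component of zero pins that factor's intercepts at zero.
#'
#' @param beta Fixed-effect coefficients.
#' @param sigma2_id,sigma2_year Variance components (>= 0).
#' @param table A use-availability table.
#' @param spec A [model_spec()] with non-empty `random_factors`.
#' @param max_iter,tol Newton controls.
#' @return List with `u` (named list per factor), `H` (curvature matrix over
#'   the active random levels), `penalized` (objective value at the mode).
#' @export
joint_mode <- function(beta, sigma2_id, sigma2_year, table, spec,
                       max_iter = 100, tol = 1e-9) {
  stopifnot(sigma2_id >= 0, sigma2_year >= 0)
  X <- build_design(table, spec)
  offset <- drop(X %*% beta)
  gs <- group_structure(table, spec$random_factors)
  sig <- c(bear_id = sigma2_id, year = sigma2_year)[spec$random_factors]
  active <- spec$random_factors[sig > 0]
  u <- lapply(gs$levels, function(l) numeric(length(l)))
  if (!length(active)) {
    return(list(u = u, H = matrix(0, 0, 0),
                penalized = sum(table$is_used * offset - log1pexp(offset))))
  }
  Z <- do.call(cbind, gs$Z[active])
  pen <- unlist(lapply(active, function(f)
    rep(1 / sig[[f]], length(gs$levels[[f]]))))
  y <- table$is_used
  d <- ncol(Z)
  v <- numeric(d)
  obj <- function(v) {
    eta <- offset + drop(Z %*% v)
    sum(y * eta - log1pexp(eta)) - 0.5 * sum(pen * v^2)
  }
  f <- obj(v); H <- NULL; moved <- Inf
  for (it in seq_len(max_iter)) {
    eta <- offset + drop(Z %*% v)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(Z, y - mu)) - pen * v
    w <- mu * (1 - mu)
    H <- crossprod(Z, Z * w)
    diag(H) <- diag(H) + pen
    step <- solve(H, g)
    t <- 1; f_new <- obj(v + step)
    while (!is.finite(f_new) || f_new < f - 1e-12) {
      t <- t / 2
      if (t < 1e-10) break
      f_new <- obj(v + t * step)
    }
    v <- v + t * step; f <- f_new
    moved <- max(abs(t * step))
    if (moved < tol) break
  }
  if (moved >= tol * 100)
    stop("joint_mode did not converge; gradient norm ",
         format(sqrt(sum(g^2))))
  pos <- 0
  for (f_ in active) {
    k <- length(gs$levels[[f_]])
    u[[f_]] <- v[pos + seq_len(k)]
    pos <- pos + k
  }
  list(u = u, H = H, penalized = f)
}

#' Laplace-approximated marginal log-likelihood
#'
#' Integrates the random intercepts out of the logistic likelihood by the
#' Laplace approximation: the penalized objective (data log-likelihood plus
#' Gaussian log-density of the random effects) at the joint mode, plus
#' `(q/2) log(2 pi) - 0.5 log det H`, where `q` is the number of active
#' random levels and `H` the curvature at the mode. With both variance
#' components zero this reduces exactly to the plain logistic
#' log-likelihood.
#'
#' @inheritParams joint_mode
#' @return The approximate marginal log-likelihood.
#' @export
laplace_marginal_loglik <- function(beta, sigma2_id, sigma2_year, table, spec) {
  jm <- joint_mode(beta, sigma2_id, sigma2_year, table, spec)
  sig <- c(bear_id = sigma2_id, year = sigma2_year)[spec$random_factors]
  active <- spec$random_factors[sig > 0]
  if (!length(active)) return(jm$penalized)
  q <- sum(vapply(active, function(f) length(jm$u[[f]]), 0L))
  # Gaussian normalizing constants of the active factors
  norm_const <- -0.5 * sum(vapply(active, function(f)
    length(jm$u[[f]]) * log(2 * pi * sig[[f]]), 0))
  ch <- tryCatch(chol(jm$H), error = function(e)
    stop("curvature at the mode is not positive definite"))
  logdet <- 2 * sum(log(diag(ch)))
  jm$penalized + norm_const + q / 2 * log(2 * pi) - 0.5 * logdet
}

#' Fit the use-availability logistic GLMM
#'
#' Maximizes the Laplace-approximated marginal likelihood over the fixed
#' effects and the two variance components: an inner penalized Newton solve
#' for the joint mode of (beta, u) at given variance components, and an outer
#' quasi-Newton (L-BFGS-B) search over `log(sigma^2)`, bounded below at
#' 1e-10 (boundary fits are reported as 0). Standard errors come from the
#' fixed-effect block of the inverse curvature of the joint penalized
#' objective at the optimum. With no random factors (or variance components
#' fixed at zero) the fit reduces to plain maximum-likelihood logistic
#' regression.
#'
#' @param table A use-availability table with `is_used`, covariate columns,
#'   `survival`, and grouping columns.
#' @param spec A [model_spec()].
#' @param fix_sigma2 Optional length-2 numeric `c(id, year)` to hold the
#'   variance components fixed (e.g. `c(0, 0)` for the fixed-effects limit).
#' @param tol_inner,tol_outer Convergence tolerances for the inner Newton and
#'   outer variance-component search.
#' @param max_outer Outer iteration cap.
#' @return An object of class `rsf_fit`: named `beta`, `se`, `vcov`,
#'   `sigma2` (named id/year), `loglik` (maximized marginal), `k`, `n`,
#'   `aicc`, `converged`, `n_iter`, `u` (random-intercept modes), `spec`.
#' @export
fit_rsf <- function(table, spec, fix_sigma2 = NULL,
                    tol_inner = 1e-9, tol_outer = 1e-7, max_outer = 200) {
  X <- build_design(table, spec, check_rank = TRUE)
  y <- table$is_used
  p <- ncol(X)
  n <- nrow(X)
  has_re <- length(spec$random_factors) > 0 &&
    (is.null(fix_sigma2) || any(fix_sigma2 > 0))

  if (!has_re) {
    fit0 <- penalized_newton(X, y, rep(0, p), tol = tol_inner)
    vcov <- solve(fit0$H)
    beta <- stats::setNames(fit0$v, colnames(X))
    n_var <- if (length(spec$random_factors) && !is.null(fix_sigma2)) 0L else 0L
    k <- p
    ll <- fit0$obj
    out <- list(beta = beta, se = sqrt(diag(vcov)), vcov = vcov,
                sigma2 = stats::setNames(rep(0, length(spec$random_factors)),
                                         spec$random_factors),
                loglik = ll, k = k, n = n,
                aicc = aicc(ll, k, n), converged = fit0$converged,
                n_iter = fit0$n_iter, u = NULL, spec = spec,
                sign_reversed = FALSE)
    class(out) <- "rsf_fit"
    return(check_separation(out))
  }

  gs <- group_structure(table, spec$random_factors)
  Z <- do.call(cbind, gs$Z)
  C <- cbind(X, Z)
  q_per <- vapply(gs$levels, length, 0L)
  q <- sum(q_per)
  n_rf <- length(spec$random_factors)
  floor_s2 <- 1e-10

  warm <- numeric(p + q)
  inner_fit <- NULL

  marginal_at <- function(log_s2) {
    s2 <- exp(log_s2)
    pen <- c(rep(0, p),
             unlist(lapply(seq_along(spec$random_factors), function(i)
               rep(1 / s2[i], q_per[i]))))
    fit <- penalized_newton(C, y, pen, v0 = warm, tol = tol_inner)
    warm <<- fit$v
    inner_fit <<- fit
    # Laplace: penalized objective + Gaussian constants + 0.5*q*log(2pi)
    #          - 0.5 * log det(H_uu)
    Huu <- fit$H[(p + 1):(p + q), (p + 1):(p + q), drop = FALSE]
    ch <- chol(Huu)
    norm_const <- -0.5 * sum(q_per * log(2 * pi * s2))
    fit$obj + norm_const + q / 2 * log(2 * pi) - sum(log(diag(ch)))
  }

  if (is.null(fix_sigma2)) {
    opt <- stats::optim(rep(log(0.1), n_rf), function(ls2) -marginal_at(ls2),
                        method = "L-BFGS-B",
                        lower = log(floor_s2), upper = log(1e4),
                        control = list(maxit = max_outer, factr = 1e9))
    log_s2 <- opt$par
    outer_conv <- opt$convergence == 0
    n_outer <- opt$counts[1]
  } else {
    log_s2 <- log(pmax(fix_sigma2[seq_len(n_rf)], floor_s2))
    outer_conv <- TRUE
    n_outer <- 0L
  }
  marginal_at(log_s2)

  # Refinement: the joint-mode profile above drops the beta-dependence of the
  # log-determinant, biasing beta by O(1/group size). Maximize the exact
  # Laplace marginal over (beta, log sigma^2) with the random effects profiled
  # out, using the analytic envelope gradient in beta and central differences
  # in the (two) variance parameters.
  u_warm <- warm[(p + 1):(p + q)]

  solve_u <- function(beta, log_s2) {
    s2 <- exp(log_s2)
    pen_u <- unlist(lapply(seq_len(n_rf), function(i)
      rep(1 / s2[i], q_per[i])))
    offset <- drop(X %*% beta)
    v <- u_warm
    f <- -Inf
    for (it in 1:100) {
      eta <- offset + drop(Z %*% v)
      mu <- stats::plogis(eta)
      g <- drop(crossprod(Z, y - mu)) - pen_u * v
      w <- mu * (1 - mu)
      H <- crossprod(Z, Z * w)
      diag(H) <- diag(H) + pen_u
      step <- solve(H, g)
      obj_at <- function(v) {
        e <- offset + drop(Z %*% v)
        sum(y * e - log1pexp(e)) - 0.5 * sum(pen_u * v^2)
      }
      t <- 1; f_new <- obj_at(v + step)
      while (!is.finite(f_new) || f_new < obj_at(v) - 1e-12) {
        t <- t / 2; if (t < 1e-10) break
        f_new <- obj_at(v + t * step)
      }
      v <- v + t * step; f <- f_new
      if (max(abs(t * step)) < 1e-10) break
    }
    u_warm <<- v
    eta <- offset + drop(Z %*% v)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(Z, Z * w)
    diag(H) <- diag(H) + pen_u
    ch <- chol(H)
    list(u = v, eta = eta, mu = mu, w = w, H = H, ch = ch, pen_u = pen_u,
         obj = f,
         lap = f - 0.5 * sum(q_per * log(2 * pi * s2)) +
           q / 2 * log(2 * pi) - sum(log(diag(ch))))
  }

  last_par <- NULL; last_sol <- NULL
  solve_cached <- function(par) {
    if (!is.null(last_par) && identical(par, last_par)) return(last_sol)
    sol <- solve_u(par[1:p], par[p + seq_len(n_rf)])
    last_par <<- par; last_sol <<- sol
    sol
  }
  lap_at <- function(par) solve_cached(par)$lap

  lap_grad <- function(par) {
    ls2 <- par[p + seq_len(n_rf)]
    sol <- solve_cached(par)
    Hinv <- chol2inv(sol$ch)
    ZS <- Z %*% Hinv
    c_i <- rowSums(ZS * Z)                     # z_i' H^-1 z_i
    wdot <- sol$w * (1 - 2 * sol$mu)           # d w_i / d eta_i
    Tmat <- X - ZS %*% crossprod(Z, X * sol$w) # total d eta / d beta
    g_beta <- drop(crossprod(X, y - sol$mu)) -
      0.5 * drop(crossprod(Tmat, c_i * wdot))
    # analytic variance-parameter gradient (envelope + trace identity)
    hdiag <- diag(Hinv)
    pos <- 0
    g_ls2 <- numeric(n_rf)
    for (i in seq_len(n_rf)) {
      idx <- pos + seq_len(q_per[i]); pos <- pos + q_per[i]
      s2_i <- exp(ls2[i])
      g_ls2[i] <- 0.5 * (sum(sol$u[idx]^2) + sum(hdiag[idx])) / s2_i -
        q_per[i] / 2
    }
    c(g_beta, g_ls2)
  }

  start <- c(warm[1:p], log_s2)
  ref <- stats::optim(start, function(par) -lap_at(par),
                      gr = function(par) -lap_grad(par),
                      method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), rep(log(floor_s2), n_rf)),
                      upper = c(rep(Inf, p), rep(log(1e4), n_rf)),
                      control = list(maxit = max_outer, factr = 1e4))
  beta_hat <- ref$par[1:p]
  log_s2 <- ref$par[p + seq_len(n_rf)]
  outer_conv <- outer_conv && ref$convergence %in% c(0, 52)
  n_outer <- n_outer + ref$counts[1]
  sol <- solve_u(beta_hat, log_s2)
  ll <- sol$lap

  # curvature of the joint penalized objective at the optimum, for SEs
  Hfull <- crossprod(C, C * sol$w)
  diag(Hfull) <- diag(Hfull) + c(rep(0, p), sol$pen_u)
  fit <- list(v = c(beta_hat, sol$u), H = Hfull,
              converged = TRUE)
  s2 <- exp(log_s2)
  s2_rep <- ifelse(s2 <= floor_s2 * 10, 0, s2)

  vcov_full <- solve(fit$H)
  vcov <- vcov_full[1:p, 1:p, drop = FALSE]
  beta <- stats::setNames(fit$v[1:p], colnames(X))
  u <- list()
  pos <- p
  for (f in spec$random_factors) {
    u[[f]] <- stats::setNames(fit$v[pos + seq_len(length(gs$levels[[f]]))],
                              gs$levels[[f]])
    pos <- pos + length(gs$levels[[f]])
  }
  n_var_free <- if (is.null(fix_sigma2)) length(spec$random_factors) else 0L
  k <- p + length(spec$random_factors)
  out <- list(beta = beta, se = sqrt(diag(vcov)), vcov = vcov,
              sigma2 = stats::setNames(s2_rep, spec$random_factors),
              loglik = ll, k = k, n = n, aicc = aicc(ll, k, n),
              converged = outer_conv && fit$converged,
              n_iter = n_outer, u = u, spec = spec, sign_reversed = FALSE)
  class(out) <- "rsf_fit"
  check_separation(out)
}

check_separation <- function(fit) {
  big <- abs(fit$beta) > 10
  if (any(big))
    warning("possible separation: |beta| > 10 for ",
            paste(names(fit$beta)[big], collapse = ", "))
  fit
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %s\n", x$spec$label))
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f%s\n",
              x$n, x$k, x$loglik, x$aicc,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  if (length(x$sigma2))
    cat("  variance components:",
        paste(sprintf("%s %.4f", names(x$sigma2), x$sigma2), collapse = ", "),
        "\n")
  tab <- data.frame(beta = round(x$beta, 4), se = round(x$se, 4))
  print(tab)
  if (isTRUE(x$sign_reversed))
    cat("  (distance signs reversed for reporting)\n")
  invisible(x)
}

#' Coefficient table of a fit
#'
#' @param fit An `rsf_fit`.
#' @return Tibble with `term`, `beta`, `se`, and the reporting-scale
#'   `reported_beta` (distance signs reversed).
#' @export
coef_table <- function(fit) {
  rep_fit <- if (isTRUE(fit$sign_reversed)) fit else reverse_distance_signs(fit)
  raw_fit <- if (isTRUE(fit$sign_reversed)) reverse_distance_signs(fit) else fit
  tibble::tibble(term = names(raw_fit$beta), beta = unname(raw_fit$beta),
                 se = unname(raw_fit$se),
                 reported_beta = unname(rep_fit$beta))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Parameter count (fixed effects including intercept and
#'   interactions, plus variance components).
#' @param n Number of rows (used + available points).
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1)
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}
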