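#' Equidistant starting means on the transformed scale
#'
#' Five equally spaced component means from 0.142 to 1.429 (the transforms of
#' signal ratios 0.02 and 0.98), one of the two default start configurations
#' of the EM algorithm.
#'
#' @return Numeric 5-vector of transformed-scale means.
#' @export
start_means_equidistant <- function() {
  seq(0.142, 1.429, length.out = 5)
}

#' Starting means from hierarchical clustering of the transformed ratios
#'
#' Complete-linkage hierarchical clustering of the transformed signal ratios,
#' cut at five groups; the sorted group means are the start configuration.
#' When fewer than five distinct groups emerge (ties, near-constant data) the
#' mean set is padded by inserting midpoints between adjacent distinct means,
#' so five values are always returned (possibly degenerate when the data are
#' constant).
#'
#' @param y Numeric vector of transformed ratios, length >= 5.
#' @return Numeric 5-vector of ascending start means.
#' @export
start_means_clustering <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 5) stop("start_means_clustering(): need at least 5 observations")
  cl <- cutree(hclust(dist(y), method = "complete"), k = 5)
  m <- sort(tapply(y, cl, mean))
  m <- as.numeric(m)
  # pad degenerate configurations (duplicate cluster means) with midpoints
  while (length(unique(m)) < 5 && diff(range(m)) > 0) {
    u <- sort(unique(m))
    gaps <- diff(u)
    i <- which.max(gaps)
    m <- sort(c(u, u[i] + gaps[i] / 2, recursive = TRUE))
    m <- m[seq_len(min(5, length(m)))]
    if (length(m) < 5) m <- c(m, rep(m[length(m)], 5 - length(m)))
  }
  if (diff(range(m)) == 0) m <- rep(m[1], 5)
  sort(m)[1:5]
}

# log densities of each observation under each component: n x 5 matrix
.log_component_dens <- function(y, mu, sigma) {
  outer(y, mu, function(yy, mm) dnorm(yy, mm, sigma, log = TRUE))
}

#' E-step: posterior dosage-class membership probabilities
#'
#' Computes, for each observation, the posterior probability of membership in
#' each of the five dosage components, `post_ij` proportional to
#' `pi_j * Normal(y_i; mu_j, sigma)`. Computed in log space with
#' log-sum-exp normalisation; if every component underflows for an
#' observation the row falls back to the prior `pi`.
#'
#' @param y Numeric vector of transformed ratios.
#' @param mu Numeric 5-vector of component means.
#' @param sigma Positive common standard deviation.
#' @param pi Numeric 5-vector of mixing proportions.
#' @return An `n x 5` matrix with rows summing to 1.
#' @export
e_step <- function(y, mu, sigma, pi) {
  stopifnot(sigma > 0, length(mu) == 5, length(pi) == 5)
  lp <- sweep(.log_component_dens(y, mu, sigma), 2, log(pmax(pi, 0)), "+")
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  rs <- rowSums(post)
  post <- post / rs
  bad <- !is.finite(mx) | !is.finite(rs) | rs == 0
  if (any(bad)) post[bad, ] <- matrix(pi, sum(bad), 5, byrow = TRUE)
  unname(post)
}

# observed-data log-likelihood via log-sum-exp
.loglik <- function(y, mu, sigma, pi) {
  lp <- sweep(.log_component_dens(y, mu, sigma), 2, log(pmax(pi, 0)), "+")
  mx <- apply(lp, 1, max)
  sum(mx + log(rowSums(exp(lp - mx))))
}

#' M-step for the mixing proportions
#'
#' Free proportions are the posterior column means. Under the HWE constraint
#' the allele-b frequency is the closed-form dosage-weighted binomial MLE
#' `p = sum_ij post_ij * (4 - x_j) / (4n)` (with `x_j` the allele-a dosage of
#' component `j`), and the proportions are [hwe_proportions()] of that
#' estimate.
#'
#' @param post Posterior matrix from [e_step()].
#' @param hwe Logical; constrain to HWE ratios?
#' @return A list with elements `pi` (5-vector) and `p` (allele-b frequency,
#'   `NA` when unconstrained).
#' @export
m_step_proportions <- function(post, hwe) {
  if (!is.matrix(post) || nrow(post) == 0 || ncol(post) != 5) {
    stop("m_step_proportions(): post must be a non-empty n x 5 matrix")
  }
  if (isTRUE(hwe)) {
    p <- sum(post %*% (4 - 0:4)) / (4 * nrow(post))
    p <- min(1, max(0, p))
    list(pi = hwe_proportions(p), p = p)
  } else {
    list(pi = colMeans(post), p = NA_real_)
  }
}

# free parameter layout per model (names within mean_model_params)
.free_params <- function(model) {
  switch(model,
    c("c1", "c2", "r"),           # model 1
    c("c1", "r"),                 # model 2 (c1 == c2 == c)
    c("c1", "c2", "r", "d"),      # model 3
    c("c1", "r", "d")             # model 4
  )
}

.params_to_theta <- function(params) {
  params[.free_params(params$model)]
}

.theta_to_params <- function(theta, model) {
  th <- as.list(theta)
  names(th) <- .free_params(model)
  c1 <- th$c1
  c2 <- if (model %in% c(2, 4)) th$c1 else th$c2
  d <- if (model %in% c(1, 2)) 0 else th$d
  mean_model_params(model, c1 = c1, c2 = c2, r = th$r, d = d)
}

# component means straight from a named full theta vector (hot path:
# no object construction, no validation beyond the admissibility checks)
.theta_means <- function(theta, model) {
  c1 <- theta[["c1"]]
  c2 <- if (model %in% c(2, 4)) c1 else theta[["c2"]]
  d <- if (model %in% c(1, 2)) 0 else theta[["d"]]
  x <- 0:4
  num <- c1 + x + d * x^2
  den <- num + c2 + theta[["r"]] * (4 - x) + theta[["r"]] * d * (4 - x)^2
  if (any(den <= 0) || any(num < 0) || any(num > den)) {
    return(NULL)
  }
  asin(sqrt(num / den))
}

# Reduced weighted-NLS objective. The full weighted residual sum of squares
# sum_ij w_ij (y_i - mu_j)^2 splits into a theta-free within-component term
# plus sum_j W_j (ybar_j - mu_j(theta))^2 with W_j the posterior mass and
# ybar_j the posterior-weighted mean of component j, so the optimiser only
# sees a 5-point problem.
.wnls_objective <- function(W, ybar, model, fixed) {
  force(fixed)
  function(theta) {
    th <- if (length(fixed)) .apply_fixed(theta, model, fixed) else theta
    mu <- .theta_means(th, model)
    if (is.null(mu)) return(1e10)
    sum(W * (ybar - mu)^2)
  }
}

.apply_fixed <- function(theta_free, model, fixed) {
  nm <- .free_params(model)
  full <- setNames(numeric(length(nm)), nm)
  full[names(fixed)] <- unlist(fixed)
  full[setdiff(nm, names(fixed))] <- theta_free
  full
}

#' M-step for the mean-model parameters and common standard deviation
#'
#' Minimises the posterior-weighted residual sum of squares
#' `sum_ij post_ij (y_i - mu_j(theta))^2` over the mean-model parameters
#' (bounded: backgrounds and curvature >= 0, sensitivity ratio > 0),
#' warm-started from the current parameters, then sets
#' `sigma^2 = weighted RSS / n` with a small positive floor. The update is
#' guarded never to increase the weighted RSS, so the EM objective cannot
#' deteriorate; if the optimiser fails the current parameters are kept.
#'
#' @param y Numeric vector of transformed ratios.
#' @param post Posterior matrix from [e_step()].
#' @param params Current [mean_model_params()] (warm start).
#' @param fixed Optional named list of mean-model parameters to hold fixed
#'   (e.g. `list(c1 = 0, c2 = 0)`), mainly for validation against restricted
#'   oracles.
#' @param sigma_floor Lower bound for `sigma` on the transformed scale.
#' @return A list with elements `params`, `mu`, `sigma` and `rss`.
#' @export
m_step_means <- function(y, post, params, fixed = list(), sigma_floor = 1e-4) {
  stopifnot(inherits(params, "mean_model_params"))
  model <- params$model
  n <- length(y)
  W <- colSums(post)
  ybar <- ifelse(W > 0, colSums(post * y) / pmax(W, .Machine$double.eps), 0)
  within <- sum(post * (y - matrix(ybar, n, 5, byrow = TRUE))^2)

  nm <- .free_params(model)
  if (length(fixed) && !all(names(fixed) %in% nm)) {
    stop("m_step_means(): fixed names must be among ", paste(nm, collapse = ", "))
  }
  free_nm <- setdiff(nm, names(fixed))
  lower <- setNames(c(c1 = 0, c2 = 0, r = 1e-6, d = 0)[nm], nm)
  obj <- .wnls_objective(W, ybar, model, fixed)

  theta0_full <- unlist(.params_to_theta(params))
  if (length(fixed)) theta0_full[names(fixed)] <- unlist(fixed)
  theta0 <- theta0_full[free_nm]
  f0 <- obj(theta0)

  theta_hat <- theta0
  if (length(free_nm) > 0) {
    fit <- tryCatch(
      optim(theta0, obj,
        method = "L-BFGS-B", lower = lower[free_nm],
        # factr and the finite-difference step tightened because the
        # objective approaches 0 on clean data, where the default settings
        # cannot resolve the optimum finely enough
        control = list(
          maxit = 200, factr = 1e4,
          ndeps = rep(1e-6, length(free_nm))
        )
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$value) && fit$value <= f0) {
      theta_hat <- fit$par
    }
  }
  full <- if (length(fixed)) .apply_fixed(theta_hat, model, fixed) else theta_hat
  new_params <- .theta_to_params(full, model)
  mu <- mean_model(new_params, 0:4)
  rss <- within + sum(W * (ybar - mu)^2)
  sigma <- max(sqrt(rss / n), sigma_floor)
  list(params = new_params, mu = mu, sigma = sigma, rss = rss)
}

# initial params: unweighted NLS of the 5 start means against dosages 0..4
.init_params_from_means <- function(start_means, model, fixed = list()) {
  post <- diag(5)
  res <- m_step_means(start_means, post,
    params = mean_model_params(model, c1 = 0.05, c2 = 0.05, r = 1, d = 0),
    fixed = fixed
  )
  # second pass from a different warm start; keep the better projection
  res2 <- m_step_means(start_means, post,
    params = mean_model_params(model,
      c1 = 0.2, c2 = 0.2,
      r = 2, d = if (model >= 3) 0.1 else 0
    ),
    fixed = fixed
  )
  if (res2$rss < res$rss) res2 else res
}

# pooled within-group SD of the nearest-start-mean assignment
.init_sigma <- function(y, mu, sigma_floor) {
  g <- apply(abs(outer(y, mu, "-")), 1, which.min)
  dev <- y - mu[g]
  max(sqrt(sum(dev^2) / length(y)), sigma_floor)
}

#' EM control settings
#'
#' @param tol Convergence tolerance on the absolute change in log-likelihood.
#' @param max_iter Maximum number of EM iterations.
#' @param sigma_floor Lower bound for the common standard deviation on the
#'   transformed scale, preventing degenerate spike components.
#' @param min_n Minimum number of observations required to attempt a fit.
#' @return A list of control settings.
#' @export
em_control <- function(tol = 1e-6, max_iter = 500, sigma_floor = 1e-4, min_n = 10) {
  list(tol = tol, max_iter = max_iter, sigma_floor = sigma_floor, min_n = min_n)
}

#' Fit one five-component dosage mixture by EM
#'
#' Fits a five-component normal mixture to transformed allele signal ratios,
#' with component means constrained by the dosage-response model `model` and
#' mixing proportions either free or constrained to Hardy-Weinberg ratios.
#' Parameters are initialised by least-squares projection of the start means
#' onto the mean model; proportions start uniform (free) or at allele
#' frequency 0.5 (HWE). E- and M-steps alternate until the log-likelihood
#' changes by less than `control$tol` or `control$max_iter` is reached. The
#' fit is deterministic: no random numbers are used anywhere.
#'
#' @param y Numeric vector of transformed ratios (length >= `control$min_n`).
#' @param model Integer dosage-response model id in `1:4`.
#' @param hwe Logical; constrain mixing proportions to HWE ratios?
#' @param start_means Numeric 5-vector of starting component means (see
#'   [start_means_clustering()], [start_means_equidistant()]).
#' @param start_label Label recorded on the fit (`"clustering"`,
#'   `"equidistant"` or `"rescue"`).
#' @param fixed Optional named list of mean-model parameters held fixed.
#' @param control See [em_control()].
#' @return An object of class `mixture_fit`: a list with the fitted
#'   parameters (`params`, `mu`, `sigma`, `pi`, `p`), the log-likelihood
#'   trace, `loglik`, `k`, `bic`, `n`, the posterior matrix, and convergence
#'   information. Numerical failure signals a condition of class
#'   `tetradose_fit_failure`.
#' @examples
#' set.seed(1)
#' truth <- mean_model(mean_model_params(2, c = 0.1, r = 1), 0:4)
#' y <- truth[sample(1:5, 200, TRUE, hwe_proportions(0.5))] + rnorm(200, 0, 0.04)
#' fit <- fit_mixture(pmin(pi / 2, pmax(0, y)), model = 2, hwe = TRUE)
#' glance(fit)
#' @export
fit_mixture <- function(y, model, hwe,
                        start_means = start_means_clustering(y),
                        start_label = "clustering",
                        fixed = list(),
                        control = em_control()) {
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < control$min_n) {
    .fit_failure(sprintf("need at least %d observations, got %d", control$min_n, n))
  }
  if (diff(range(start_means)) <= 0 || diff(range(y)) == 0) {
    .fit_failure("degenerate data or start means (no spread)")
  }

  init <- tryCatch(
    .init_params_from_means(start_means, model, fixed),
    error = function(e) NULL
  )
  if (is.null(init)) .fit_failure("start-mean projection failed")
  params <- init$params
  mu <- init$mu
  sigma <- .init_sigma(y, mu, control$sigma_floor)
  if (isTRUE(hwe)) {
    p <- 0.5
    pi <- hwe_proportions(p)
  } else {
    p <- NA_real_
    pi <- rep(0.2, 5)
  }

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  post <- NULL
  while (iter < control$max_iter) {
    iter <- iter + 1
    post <- e_step(y, mu, sigma, pi)
    prop <- m_step_proportions(post, hwe)
    pi <- prop$pi
    p <- prop$p
    ms <- tryCatch(
      m_step_means(y, post, params, fixed = fixed, sigma_floor = control$sigma_floor),
      error = function(e) NULL
    )
    if (is.null(ms)) .fit_failure("weighted NLS M-step failed")
    params <- ms$params
    mu <- ms$mu
    sigma <- ms$sigma
    ll <- .loglik(y, mu, sigma, pi)
    if (!is.finite(ll)) .fit_failure("non-finite log-likelihood")
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_old) < control$tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # collapsed solutions (adjacent means within one sigma) are boundary
  # degeneracies: the affected components are unresolvable, no observation
  # near them can attain a decisive posterior, and the solution carries no
  # genotype information. Treated as numerical failure, like a sigma collapse.
  if (min(diff(mu)) < sigma) {
    .fit_failure("collapsed components (adjacent means closer than sigma)")
  }
  post <- e_step(y, mu, sigma, pi)
  ll <- .loglik(y, mu, sigma, pi)
  k <- n_parameters(model, hwe)
  structure(
    list(
      model = as.integer(model), hwe = isTRUE(hwe),
      params = params, mu = mu, sigma = sigma, pi = as.numeric(pi), p = p,
      loglik = ll, k = k, bic = -2 * ll + k * log(n), n = n,
      posteriors = post, converged = converged, n_iter = iter,
      start_label = start_label, loglik_trace = ll_trace
    ),
    class = "mixture_fit"
  )
}

.fit_failure <- function(msg) {
  cnd <- structure(
    class = c("tetradose_fit_failure", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cnd)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> model %d (%s), n = %d\n  mu = %s\n  sigma = %.4f, BIC = %.1f%s\n",
    x$model, if (x$hwe) "HWE" else "free pi", x$n,
    paste(sprintf("%.3f", x$mu), collapse = ", "),
    x$sigma, x$bic,
    if (x$hwe) sprintf(", p(b) = %.3f", x$p) else ""
  ))
  invisible(x)
}

#' Tidy a fitted dosage mixture
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble with one row per dosage component: transformed and
#'   back-transformed means, mixing proportion and posterior mass.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    dosage = 0:4,
    mean = x$mu,
    mean_ratio = asr_inv(x$mu),
    pi = x$pi,
    posterior_mass = colSums(x$posteriors)
  )
}

#' Glance at a fitted dosage mixture
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the model id, constraint, parameter
#'   estimates, log-likelihood, BIC and convergence information.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, hwe = x$hwe,
    c1 = x$params$c1, c2 = x$params$c2, r = x$params$r, d = x$params$d,
    sigma = x$sigma, p_allele_b = x$p, p_allele_a = 1 - x$p,
    loglik = x$loglik, k = x$k, bic = x$bic, n = x$n,
    converged = x$converged, n_iter = x$n_iter, start = x$start_label
  )
}
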