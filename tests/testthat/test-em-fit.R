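# deterministic synthetic ratios for one marker on the transformed scale
sim_y <- function(n, model = 2, c = 0.05, c2 = NULL, r = 1, d = 0, p = 0.5,
                  sigma = 0.04, seed = 1) {
  prm <- if (model %in% c(2, 4)) {
    mean_model_params(model, c = c, r = r, d = d)
  } else {
    mean_model_params(model, c1 = c, c2 = if (is.null(c2)) c else c2, r = r, d = d)
  }
  mu <- mean_model(prm, 0:4)
  set.seed(seed)
  x <- sample(0:4, n, replace = TRUE, prob = hwe_proportions(p))
  list(
    y = pmin(pi / 2, pmax(0, mu[x + 1] + rnorm(n, 0, sigma))),
    dosage = x, params = prm, mu = mu
  )
}

test_that("equidistant start means span the transformed 2%-98% interval", {
  m <- start_means_equidistant()
  expect_equal(m[1], 0.142)
  expect_equal(m[5], 1.429)
  expect_equal(unique(round(diff(m), 10)), (1.429 - 0.142) / 4)
  expect_true(all(diff(m) > 0))
})

test_that("clustering start recovers well-separated group centres", {
  centres <- c(0.1, 0.4, 0.8, 1.1, 1.4)
  set.seed(3)
  y <- rep(centres, each = 20) + rnorm(100, 0, 0.01)
  expect_lt(max(abs(start_means_clustering(y) - centres)), 0.02)
  # five distinct points are their own clusters
  expect_equal(start_means_clustering(centres), centres)
  # constant data degenerates to identical means (caller falls back)
  expect_equal(start_means_clustering(rep(0.5, 10)), rep(0.5, 5))
  expect_error(start_means_clustering(c(1, 2)), "at least 5")
})

test_that("E-step posteriors match direct density computation", {
  mu <- c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2)
  # indistinguishable components return the prior
  post <- e_step(c(0.3, 0.9), rep(0.5, 5), 0.1, c(0.1, 0.2, 0.4, 0.2, 0.1))
  expect_equal(post[1, ], c(0.1, 0.2, 0.4, 0.2, 0.1))
  # dominance: observation at a mean, components 20 sigma apart
  post <- e_step(pi / 4, mu, 0.015, rep(0.2, 5))
  expect_equal(post[1, ], c(0, 0, 1, 0, 0), tolerance = 1e-12)
  # hand-computed density ratios
  y0 <- 0
  direct <- dnorm(y0, mu, 0.1) / sum(dnorm(y0, mu, 0.1))
  expect_equal(e_step(y0, mu, 0.1, rep(0.2, 5))[1, ], direct, tolerance = 1e-12)
  # rows always sum to 1
  set.seed(5)
  post <- e_step(runif(50, 0, pi / 2), mu, 0.05, c(0.3, 0.1, 0.2, 0.1, 0.3))
  expect_equal(rowSums(post), rep(1, 50), tolerance = 1e-9)
})

test_that("proportion M-step: column means when free, binomial MLE under HWE", {
  hard <- function(counts) {
    do.call(rbind, lapply(which(counts > 0), function(j) {
      matrix(diag(5)[j, ], counts[j], 5, byrow = TRUE)
    }))
  }
  post <- hard(c(10, 20, 40, 20, 10))
  expect_equal(m_step_proportions(post, hwe = FALSE)$pi, c(0.1, 0.2, 0.4, 0.2, 0.1))
  # all mass in the nulliplex-a class: allele b fixed
  res <- m_step_proportions(hard(c(16, 0, 0, 0, 0)), hwe = TRUE)
  expect_equal(res$p, 1)
  expect_equal(res$pi, c(1, 0, 0, 0, 0))
  # binomial counts at p = 0.5: MLE is the mean b-dosage / 4
  res <- m_step_proportions(hard(c(1, 4, 6, 4, 1)), hwe = TRUE)
  expect_equal(res$p, 0.5)
  expect_equal(res$pi, c(0.0625, 0.25, 0.375, 0.25, 0.0625))
  expect_error(m_step_proportions(matrix(0, 0, 5), TRUE), "non-empty")
})

test_that("mean M-step recovers generating parameters from noiseless data", {
  prm <- mean_model_params(1, c1 = 0.1, c2 = 0.1, r = 1)
  mu <- mean_model(prm, 0:4)
  y <- rep(mu, each = 10)
  post <- do.call(rbind, lapply(1:5, function(j) {
    matrix(diag(5)[j, ], 10, 5, byrow = TRUE)
  }))
  res <- m_step_means(y, post, mean_model_params(1, c1 = 0.3, c2 = 0.05, r = 1.5))
  expect_lt(max(abs(res$mu - mu)), 1e-6)
  expect_equal(res$sigma, 1e-4) # floored: data are exactly on the means
})

test_that("mean M-step with degenerate weights keeps a bounded sane update", {
  # all weight on one component: direction underdetermined, update must not blow up
  set.seed(9)
  y <- rnorm(50, 1.4, 0.02)
  post <- matrix(rep(c(0, 0, 0, 0, 1), each = 50), 50, 5)
  cur <- mean_model_params(2, c = 0.05, r = 1)
  res <- m_step_means(y, post, cur)
  expect_true(all(is.finite(res$mu)))
  expect_true(all(diff(res$mu) > 0))
  expect_gt(res$sigma, 0)
})

test_that("fixing parameters restricts the M-step to the requested subspace", {
  sim <- sim_y(100, model = 1, c = 0, r = 1.5, seed = 4)
  post <- e_step(sim$y, sim$mu, 0.04, hwe_proportions(0.5))
  res <- m_step_means(sim$y, post,
    mean_model_params(1, c1 = 0, c2 = 0, r = 2),
    fixed = list(c1 = 0, c2 = 0)
  )
  expect_equal(res$params$c1, 0)
  expect_equal(res$params$c2, 0)
  expect_error(
    m_step_means(sim$y, post, mean_model_params(2, c = 0, r = 1),
      fixed = list(c2 = 0)
    ),
    "fixed names"
  )
})

test_that("EM recovers the generating mixture on clean data", {
  sim <- sim_y(400, model = 1, c = 0.05, r = 1, p = 0.5, sigma = 0.04, seed = 11)
  fit <- fit_mixture(sim$y, model = 1, hwe = TRUE)
  expect_s3_class(fit, "mixture_fit")
  expect_true(fit$converged)
  expect_lt(abs(fit$p - 0.5), 0.05)
  expect_lt(max(abs(fit$mu - sim$mu)), 0.03)
  # posterior rows sum to one; pi consistent with the HWE constraint
  expect_equal(rowSums(fit$posteriors), rep(1, fit$n), tolerance = 1e-9)
  expect_equal(fit$pi, hwe_proportions(fit$p))
  # stored means re-derive exactly from the stored parameters
  expect_identical(fit$mu, mean_model(fit$params, 0:4))
})

test_that("EM log-likelihood is non-decreasing for all 8 variants", {
  set.seed(21)
  grid <- expand.grid(model = 1:4, hwe = c(TRUE, FALSE))
  n_checked <- 0
  for (rep in 1:7) {
    sim <- sim_y(150,
      model = sample(1:4, 1), c = runif(1, 0, 0.2),
      r = exp(runif(1, log(0.5), log(2))), p = runif(1, 0.2, 0.8),
      sigma = runif(1, 0.02, 0.08), seed = 100 + rep
    )
    for (i in seq_len(nrow(grid))) {
      fit <- tryCatch(
        fit_mixture(sim$y, grid$model[i], grid$hwe[i]),
        tetradose_fit_failure = function(e) NULL
      )
      if (is.null(fit)) next
      expect_true(all(diff(fit$loglik_trace) > -1e-8))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 40)
})

test_that("BIC identity holds exactly on returned fits", {
  sim <- sim_y(120, seed = 31)
  for (hwe in c(TRUE, FALSE)) {
    fit <- fit_mixture(sim$y, model = 2, hwe = hwe)
    expect_identical(fit$bic, -2 * fit$loglik + fit$k * log(fit$n))
    expect_identical(fit$k, n_parameters(2, hwe))
  }
})

test_that("the HWE constraint can only lose likelihood against free proportions", {
  for (seed in 41:44) {
    sim <- sim_y(200, model = 2, p = 0.35, seed = seed)
    start <- start_means_clustering(sim$y)
    free <- fit_mixture(sim$y, 2, hwe = FALSE, start_means = start)
    hwe <- fit_mixture(sim$y, 2, hwe = TRUE, start_means = start)
    expect_gte(free$loglik, hwe$loglik - 1e-6)
  }
})

test_that("EM is deterministic: identical data give bit-identical fits", {
  sim <- sim_y(150, seed = 51)
  f1 <- fit_mixture(sim$y, 3, hwe = TRUE)
  f2 <- fit_mixture(sim$y, 3, hwe = TRUE)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$posteriors, f2$posteriors)
})

test_that("parameter recovery holds across all 8 model variants", {
  # n = 500, sigma = 0.04 per variant; median relative error of r < 10%,
  # median absolute error of p < 0.05 over replicates
  grid <- expand.grid(model = 1:4, hwe = c(TRUE, FALSE))
  reps <- 5
  for (i in seq_len(nrow(grid))) {
    model <- grid$model[i]
    r_err <- p_err <- numeric(0)
    for (rep in seq_len(reps)) {
      r_true <- c(0.8, 1.25)[(rep %% 2) + 1]
      sim <- sim_y(500,
        model = model, c = 0.05, r = r_true,
        d = if (model >= 3) 0.05 else 0,
        p = 0.5, sigma = 0.04, seed = 1000 * i + rep
      )
      fit <- fit_mixture(sim$y, model, grid$hwe[i])
      r_err <- c(r_err, abs(fit$params$r - r_true) / r_true)
      if (grid$hwe[i]) p_err <- c(p_err, abs(fit$p - 0.5))
    }
    expect_lt(median(r_err), 0.10)
    if (grid$hwe[i]) expect_lt(median(p_err), 0.05)
  }
})

test_that("EM matches a brute-force grid search on small instances", {
  # model 1 with c1 = c2 = 0 fixed: likelihood over (r, sigma, p) is cheap to
  # scan exhaustively; EM restricted to the same subspace must reach it
  scan <- function(y, rs, sigmas, ps) {
    best <- c(ll = -Inf, r = NA, sigma = NA, p = NA)
    for (r in rs) {
      mu <- asin(sqrt((0:4) / ((0:4) + r * (4 - (0:4)))))
      for (sigma in sigmas) {
        dens <- sapply(1:5, function(j) dnorm(y, mu[j], sigma))
        for (p in ps) {
          ll <- sum(log(dens %*% hwe_proportions(p)))
          if (ll > best["ll"]) best <- c(ll = ll, r = r, sigma = sigma, p = p)
        }
      }
    }
    best
  }
  grid_loglik <- function(y) {
    coarse <- scan(
      y, exp(seq(log(0.4), log(2.5), length.out = 50)),
      seq(0.02, 0.12, by = 0.005), seq(0.05, 0.95, by = 0.02)
    )
    # refine around the coarse optimum until the grid error is far below the
    # comparison tolerance
    fine <- scan(
      y,
      coarse["r"] * exp(seq(-0.03, 0.03, length.out = 31)),
      coarse["sigma"] + seq(-0.004, 0.004, length.out = 31),
      pmin(1, pmax(0, coarse["p"] + seq(-0.02, 0.02, length.out = 41)))
    )
    unname(fine["ll"])
  }
  for (seed in 61:63) {
    sim <- sim_y(25, model = 1, c = 0, r = 1.2, p = 0.5, sigma = 0.05, seed = seed)
    fit <- fit_mixture(sim$y,
      model = 1, hwe = TRUE,
      fixed = list(c1 = 0, c2 = 0)
    )
    expect_lt(abs(fit$loglik - grid_loglik(sim$y)), 1e-3)
  }
})

test_that("degenerate inputs are signalled as fit failures, not errors", {
  expect_error(
    fit_mixture(rep(0.5, 50), model = 1, hwe = TRUE),
    class = "tetradose_fit_failure"
  )
  expect_error(
    fit_mixture(runif(5), model = 1, hwe = TRUE),
    class = "tetradose_fit_failure"
  )
})

test_that("tidy and glance summarise a fit in broom style", {
  sim <- sim_y(150, seed = 71)
  fit <- fit_mixture(sim$y, 2, hwe = TRUE)
  td <- tidy(fit)
  expect_equal(td$dosage, 0:4)
  expect_equal(td$mean_ratio, asr_inv(td$mean))
  expect_equal(sum(td$pi), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$bic, fit$bic)
  expect_equal(gl$p_allele_a, 1 - fit$p)
})
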