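test_that("key functions match closed forms and are monotone", {
  expect_equal(key_g(0, 100, "half_normal"), 1)
  expect_equal(key_g(100, 100, "half_normal"), exp(-0.5))
  # hazard-rate at x = sigma is 1 - exp(-1) for any shape
  for (b in c(1, 2, 5)) {
    expect_equal(key_g(150, 150, "hazard_rate", shape = b), 1 - exp(-1))
  }
  expect_equal(key_g(0, 150, "hazard_rate", shape = 2), 1)
  x <- seq(0, 600, by = 5)
  for (key in c("half_normal", "hazard_rate")) {
    g <- key_g(x, 140, key, shape = 2.5)
    expect_true(all(diff(g) <= 1e-12))
    expect_true(all(g >= 0 & g <= 1))
  }
  expect_error(key_g(10, -1, "half_normal"), "sigma")
  expect_error(key_g(10, 100, "hazard_rate"), "shape")
})

test_that("log-linear scale model reproduces coefficient ratios", {
  df <- data.frame(canopy = factor(c("hardwood", "mixed", "open"),
                                   levels = c("hardwood", "mixed", "open")))
  # intercept-only: constant sigma
  expect_equal(detection_scale(c(log(100)), df, ~1), rep(100, 3))
  # canopy contrasts: sigma ratios are exp(beta)
  beta <- c(-1.680, 0.054, 0.321)
  s <- detection_scale(beta, df, ~canopy)
  expect_equal(s[2] / s[1], exp(0.054))
  expect_equal(s[3] / s[1], exp(0.321), tolerance = 1e-12)
  # unseen level is a domain error naming the level
  expect_error(
    detection_scale(beta, data.frame(canopy = "pine"), ~canopy,
                    xlevels = list(canopy = c("hardwood", "mixed", "open"))),
    "pine")
})

test_that("average detection probability matches the erf closed form", {
  # perfect detection limit
  expect_equal(average_p(1e9, 350, "half_normal"), 1, tolerance = 1e-10)
  # half-normal with sigma = w: p = sqrt(2*pi)*(pnorm(1)-0.5)
  p_oracle <- sqrt(2 * pi) * (pnorm(1) - 0.5)
  expect_equal(average_p(350, 350, "half_normal"), p_oracle,
               tolerance = 1e-9)
  expect_equal(round(p_oracle, 4), 0.8556)
  # quadrature converged: halving node count changes nothing material
  p64 <- average_p(c(100, 200, 400), 350, "hazard_rate", shape = 2.5)
  p32 <- average_p(c(100, 200, 400), 350, "hazard_rate", shape = 2.5,
                   n_nodes = 32L)
  expect_equal(p64, p32, tolerance = 1e-8)
  expect_error(average_p(100, 0, "half_normal"), "> 0")
})

test_that("p is monotone in truncation and in sigma", {
  ws <- seq(100, 700, by = 50)
  for (key in c("half_normal", "hazard_rate")) {
    p_w <- vapply(ws, function(w) average_p(150, w, key, shape = 2.5),
                  numeric(1))
    expect_true(all(diff(p_w) <= 1e-12))          # non-increasing in w
    p_s <- average_p(seq(50, 500, by = 25), 350, key, shape = 2.5)
    expect_true(all(diff(p_s) >= -1e-12))         # non-decreasing in sigma
  }
})

test_that("likelihood properties: duplication and order invariance", {
  set.seed(41)
  obs <- make_obs(distances = sample_distances(120, 350, "half_normal", 150),
                  along = runif(120, 0, 10000))
  fit <- fit_detection(obs, 350, key = "half_normal", formula = ~1)
  # duplicated data: same MLE, doubled log-likelihood
  obs2 <- rbind(obs, obs)
  obs2$obs_id <- seq_len(nrow(obs2))
  fit2 <- fit_detection(obs2, 350, key = "half_normal", formula = ~1)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-4)
  expect_equal(fit2$loglik, 2 * fit$loglik, tolerance = 1e-6)
  # row order does not change the fit
  obs3 <- obs[rev(seq_len(nrow(obs))), ]
  fit3 <- fit_detection(obs3, 350, key = "half_normal", formula = ~1)
  expect_equal(fit3$beta, fit$beta, tolerance = 1e-8)
  expect_equal(fit3$loglik, fit$loglik, tolerance = 1e-10)
  # sample-size floor
  expect_error(fit_detection(obs[1:5, ], 350), "at least")
})

test_that("returned MLE beats random admissible parameter draws", {
  set.seed(42)
  obs <- make_obs(
    distances = sample_distances(150, 350, "hazard_rate", 150, 2.5),
    canopy = sample(c("hardwood", "mixed", "open"), 150, replace = TRUE),
    along = runif(150, 0, 10000))
  fit <- fit_detection(obs, 350, key = "hazard_rate", formula = ~canopy)
  nll <- function(theta) {
    dsurf:::.det_nll(theta,
                     model.matrix(~canopy, obs), obs$perp_distance, 350,
                     "hazard_rate", dsurf:::gauss_legendre(64, 0, 350))
  }
  at_mle <- nll(fit$theta)
  for (i in 1:32) {
    draw <- fit$theta + rnorm(length(fit$theta), 0, 0.5)
    expect_gte(nll(draw), at_mle - 1e-6)
  }
})

test_that("C-vM statistic matches a direct oracle and bounds", {
  n <- 12
  u <- (1:n) / (n + 1)
  # direct evaluation of the definition
  oracle <- sum((sort(u) - (2 * (1:n) - 1) / (2 * n))^2) + 1 / (12 * n)
  expect_equal(dsurf:::cvm_statistic(u), oracle)
  # the minimum over samples of size n is 1/(12n), attained at the
  # mid-quantiles; random samples can only do worse
  expect_gte(dsurf:::cvm_statistic(u), 1 / (12 * n))
  expect_equal(dsurf:::cvm_statistic((2 * (1:n) - 1) / (2 * n)),
               1 / (12 * n))
  set.seed(9)
  for (i in 1:20) {
    expect_gte(dsurf:::cvm_statistic(runif(n)), 1 / (12 * n))
  }
  # asymptotic tail probabilities at standard critical values
  expect_equal(dsurf:::cvm_pvalue(0.4614), 0.05, tolerance = 1e-3)
  expect_equal(dsurf:::cvm_pvalue(0.3473), 0.10, tolerance = 1e-3)
})

test_that("C-vM p-values are approximately uniform under the null", {
  # distances drawn from a fixed fitted model, GOF computed at the same
  # (fixed) parameters: p-values must be uniform
  set.seed(73)
  obs0 <- make_obs(distances = sample_distances(80, 350, "half_normal", 160),
                   along = runif(80, 0, 10000))
  fit <- fit_detection(obs0, 350, key = "half_normal", formula = ~1)
  pvals <- vapply(1:200, function(i) {
    obs <- make_obs(
      distances = sample_distances(60, 350, "half_normal",
                                   unname(exp(fit$beta[1]))),
      along = runif(60, 0, 10000))
    unname(cvm_gof(fit, obs)["p_value"])
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("parsimony selection matches a brute-force oracle", {
  # the documented case: {100.0, 100.77} with K {4, 3} -> the K=3 model
  expect_equal(parsimony_select(c(100, 100.77), c(4, 3), c("a", "b")), 2L)
  # single model selects itself
  expect_equal(parsimony_select(105.2, 3, "only"), 1L)
  oracle <- function(aic, k, labels, delta = 2) {
    comp <- data.frame(i = seq_along(aic), aic = aic, k = k,
                       lab = labels)[aic <= min(aic) + delta, ]
    comp <- comp[comp$k == min(comp$k), ]
    comp <- comp[comp$aic == min(comp$aic), ]
    comp$i[order(comp$lab)][1]
  }
  set.seed(31)
  for (i in 1:50) {
    m <- sample(2:8, 1)
    aic <- round(100 + runif(m, 0, 6), 2)
    k <- sample(2:6, m, replace = TRUE)
    labels <- paste0("m", sample(m))
    expect_equal(parsimony_select(aic, k, labels), oracle(aic, k, labels))
  }
})

test_that("all-subsets candidate set has the right size and ranking", {
  set.seed(5)
  obs <- make_obs(
    distances = sample_distances(100, 350, "half_normal", 150),
    canopy = sample(c("hardwood", "mixed", "open"), 100, replace = TRUE),
    along = runif(100, 0, 10000))
  obs$cloud_cover <- runif(100, 0, 100)
  fits <- all_subsets_detection(obs, 350,
                                covariates = c("canopy", "cloud_cover"),
                                keys = c("half_normal"))
  expect_length(fits, 4L)  # {}, canopy, cloud, canopy+cloud
  rk <- attr(fits, "ranking")
  expect_equal(nrow(rk), 4L)
  expect_equal(rk$delta_AIC[1], 0)
  expect_true(!is.unsorted(rk$AIC))
  sel <- select_detection(fits)
  expect_s3_class(sel, "dsurf_detfit")
})
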