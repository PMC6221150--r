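test_that("single-datum two-treatment fit with flat prior returns the datum", {
  net <- k2_network(0.7, 0.2)
  fit <- fit_fe(net, nma_prior(2, improper = TRUE))
  expect_equal(unname(coef(fit)), 0.7)
  expect_equal(unname(vcov(fit)[1, 1]), 0.2)
})

test_that("two-treatment flat-prior fit is the inverse-variance-weighted mean", {
  y <- c(0.4, 0.9); v <- c(0.1, 0.3)
  fit <- fit_fe(k2_network(y, v), nma_prior(2, improper = TRUE))
  expect_equal(unname(coef(fit)), sum(y / v) / sum(1 / v))
  expect_equal(unname(vcov(fit)[1, 1]), 1 / sum(1 / v))
})

test_that("flat-prior fixed-effect fit equals GLS solved from the normal equations", {
  for (seed in c(2, 9)) {
    net <- random_network(seed)$network
    fit <- fit_fe(net, nma_prior(net$K, improper = TRUE))
    X <- build_design_matrix(net)
    Vinv <- solve(net$V)
    d_gls <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% net$y)
    expect_rel_equal(unname(coef(fit)), drop(d_gls), 1e-10)
  }
})

test_that("random-effects fit converges to the fixed-effect fit as tau2 -> 0", {
  net <- random_network(4, need_three_arm = TRUE)$network
  fe <- fit_fe(net)
  gaps <- vapply(c(1e-2, 1e-4, 1e-6), function(t2)
    max(abs(coef(fit_re_fixed_tau(net, tau2 = t2)) - coef(fe))), 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-5)
})

test_that("joint RE posterior agrees with the marginalised closed form", {
  # independent oracle: integrating delta out gives y | d ~ N(Xd, V + S_tau2),
  # a fixed-effect fit with inflated covariance
  for (seed in c(5, 11)) {
    sim <- random_network(seed, K = 4, need_three_arm = TRUE)
    net <- sim$network
    pr <- nma_prior(net$K, d0 = 0.1, Sigma_d = diag(2, net$K - 1))
    tau2 <- 0.08
    fit <- fit_re_fixed_tau(net, pr, tau2)
    X <- build_design_matrix(net)
    Vm <- net$V + build_re_covariance(net, tau2)
    prec <- pr$prec + t(X) %*% solve(Vm) %*% X
    cov_m <- solve(prec)
    mean_m <- drop(cov_m %*% (pr$prec %*% rep(0.1, net$K - 1) +
                                t(X) %*% solve(Vm) %*% net$y))
    expect_rel_equal(unname(coef(fit)), mean_m, 1e-8)
    expect_rel_equal(unname(vcov(fit)), unname(cov_m), 1e-8)
  }
})

test_that("huge tau2 behaves per the scalar closed form in a two-treatment network", {
  y <- c(0.2, 1.4); v <- c(0.1, 0.4); tau2 <- 1e4
  sd2 <- 50
  fit <- fit_re_fixed_tau(k2_network(y, v), nma_prior(2, Sigma_d = sd2), tau2)
  w <- 1 / (v + tau2)
  prec <- 1 / sd2 + sum(w)
  expect_equal(unname(coef(fit)), sum(w * y) / prec, tolerance = 1e-8)
})

test_that("external partitioning slices the joint covariance as the fit stores it", {
  sim <- random_network(6, K = 4, need_three_arm = TRUE)
  fit <- fit_re_fixed_tau(sim$network, tau2 = 0.05)
  p <- sim$network$K - 1L
  ext <- partition_external_posterior(
    fit$joint$mean, fit$joint$cov,
    layout = list(d = 1:p, delta = (p + 1):(p + sim$network$N)))
  expect_equal(ext$mean_d, fit$mean_d)
  expect_equal(ext$cov_d, fit$cov_d)
  expect_equal(unname(ext$B_star), unname(fit$B_star))
  expect_equal(ext$model, "external")
})

test_that("draws input uses empirical moments before partitioning", {
  set.seed(42)
  S <- matrix(c(1, 0.6, 0.3, 0.6, 1.5, 0.2, 0.3, 0.2, 0.8), 3)
  mu <- c(0.5, -0.2, 1)
  draws <- MASS::mvrnorm(20000, mu, S)
  ext <- partition_external_posterior(draws = draws,
                                      layout = list(d = 1:2, mu = 3))
  expect_equal(unname(ext$mean_d), mu[1:2], tolerance = 0.05)
  expect_equal(unname(ext$cov_d), S[1:2, 1:2], tolerance = 0.1)
  expect_equal(unname(drop(ext$D_star)), S[1:2, 3], tolerance = 0.1)
})

test_that("contrast means follow the consistency equations", {
  fit <- fit_fe(random_network(7)$network)
  K <- length(coef(fit)) + 1L
  expect_equal(contrast_mean(fit, 2, 2), 0)
  expect_equal(contrast_mean(fit, 1, 3), unname(coef(fit)[2]))
  E <- c(0, coef(fit))
  for (a in 1:K) for (b in 1:K)
    expect_equal(contrast_mean(fit, a, b), unname(E[b] - E[a]))
})

test_that("posterior covariance never exceeds the proper prior covariance", {
  net <- random_network(8)$network
  Sd <- diag(0.5, net$K - 1)
  fit <- fit_fe(net, nma_prior(net$K, Sigma_d = Sd))
  ev <- eigen(Sd - vcov(fit), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("external posterior summaries round-trip through CSV", {
  fit <- fit_fe(random_network(9)$network)
  p <- length(coef(fit))
  df <- data.frame(label = 2:(p + 1), mean = unname(coef(fit)))
  cv <- as.data.frame(unname(vcov(fit)))
  names(cv) <- paste0("cov_", 2:(p + 1))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(cbind(df, cv), path, row.names = FALSE)
  ext <- read_posterior(path)
  expect_equal(unname(ext$mean_d), unname(coef(fit)), tolerance = 1e-12)
  expect_equal(unname(ext$cov_d), unname(vcov(fit)), tolerance = 1e-12)
  expect_error(read_posterior(path = {
    bad <- tempfile(fileext = ".csv")
    utils::write.csv(df, bad, row.names = FALSE)
    bad
  }), "not square")
})

test_that("analysis configuration files materialise rule, prior and tau2", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("outcome_direction: lower_better", "mcid: 0.2", "tau2: 0.05",
               "prior:", "  d0: 0", "  sd: 10"), y)
  cfg <- read_config(y, K = 4)
  expect_equal(cfg$rule$direction, "lower_better")
  expect_equal(cfg$rule$mcid, 0.2)
  expect_equal(cfg$tau2, 0.05)
  expect_equal(cfg$prior$Sigma_d, diag(100, 3))
  j <- tempfile(fileext = ".json")
  writeLines('{"outcome_direction": "higher_better", "prior": {"improper": true}}', j)
  cfg2 <- read_config(j, K = 3)
  expect_true(cfg2$prior$improper)
  expect_null(cfg2$tau2)
})
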