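test_that("optimal treatment follows the decision rule with deterministic tie-breaks", {
  net <- random_network(20)$network
  fit <- fit_fe(net)
  E <- c(0, coef(fit))
  expect_equal(as.integer(optimal_treatment(fit)), unname(which.max(E)))
  expect_equal(as.integer(optimal_treatment(fit, decision_rule("lower_better"))),
               unname(which.min(E)))
  tied <- list(mean_d = c(0, 0, 0))
  class(tied) <- "nma_fit"
  k <- optimal_treatment(tied)
  expect_equal(as.integer(k), 1L)
  expect_true(attr(k, "tie"))
})

test_that("a single two-treatment datum must be shifted to minus itself to tie", {
  y1 <- 0.8
  fit <- fit_fe(k2_network(y1, 0.25), nma_prior(2, improper = TRUE))
  H <- nma_influence(fit)
  s <- solution_set(fit, H, m = 1)
  expect_equal(s$a, 1L)
  expect_equal(s$u, -y1)
})

test_that("each finite solution is exactly where the refitted contrast changes sign", {
  for (seed in c(21, 22)) {
    sim <- random_network(seed, need_three_arm = TRUE)
    fit <- fit_fe(sim$network)
    H <- nma_influence(fit)
    ks <- as.integer(optimal_treatment(fit))
    for (m in sample(sim$network$N, 3)) {
      s <- solution_set(fit, H, ks, m)
      for (i in which(is.finite(s$u))) {
        a <- s$a[i]
        at <- fit_adjusted(fit, m = m, value = s$u[i])
        expect_lt(abs(contrast_mean(at, a, ks)), 1e-9)
        eps <- 1e-6 * max(1, abs(s$u[i]))
        beyond <- fit_adjusted(fit, m = m, value = s$u[i] + sign(s$u[i]) * eps)
        expect_lt(contrast_mean(beyond, a, ks), 0)  # a now beats k*
      }
    }
  }
})

test_that("thresholds are the smallest positive and largest negative solutions", {
  s <- structure(data.frame(a = c(1L, 2L, 4L), u = c(-3, 0.7, -0.4)),
                 kstar = 3L, m = 1L, class = c("solution_set", "data.frame"))
  th <- thresholds_from_solutions(s)
  expect_equal(th$beta_pos, 0.7)
  expect_equal(th$new_opt_pos, 2L)
  expect_equal(th$beta_neg, -0.4)
  expect_equal(th$new_opt_neg, 4L)
  s2 <- structure(data.frame(a = c(1L, 2L), u = c(Inf, -1)),
                  kstar = 3L, m = 1L, class = c("solution_set", "data.frame"))
  th2 <- thresholds_from_solutions(s2)
  expect_equal(th2$beta_pos, Inf)   # open side, reported NT
  expect_true(is.na(th2$new_opt_pos))
})

test_that("MCID thresholds move away from zero monotonically and rho = 0 is the plain analysis", {
  sim <- random_network(23, need_three_arm = TRUE)
  fit <- fit_fe(sim$network)
  H <- nma_influence(fit)
  ks <- as.integer(optimal_treatment(fit))
  m <- 2L
  base <- solution_set(fit, H, ks, m, decision_rule(mcid = 0))
  plain <- solution_set(fit, H, ks, m)
  expect_identical(base$u, plain$u)
  prev <- abs(base$u)
  for (rho in c(0.05, 0.1, 0.2)) {
    cur <- abs(solution_set(fit, H, ks, m, decision_rule(mcid = rho))$u)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("at the MCID threshold the alternative beats the optimum by exactly rho", {
  sim <- random_network(24, need_three_arm = TRUE)
  fit <- fit_fe(sim$network)
  H <- nma_influence(fit)
  ks <- as.integer(optimal_treatment(fit))
  rho <- 0.15
  s <- solution_set(fit, H, ks, 1L, decision_rule(mcid = rho))
  i <- which(is.finite(s$u))[1]
  at <- fit_adjusted(fit, m = 1L, value = s$u[i])
  # contrast d_{a k*} = d_{k*} - d_a driven to -rho: a better by rho
  expect_equal(contrast_mean(at, s$a[i], ks), -rho, tolerance = 1e-9)
})

test_that("lower-better outcomes reproduce the mirrored analysis of negated data", {
  sim <- random_network(25, need_three_arm = TRUE)
  net <- sim$network
  neg <- net
  neg$y <- -neg$y
  neg$outcome_direction <- "lower_better"
  res_hi <- run_study_level(net, model = "fe")
  res_lo <- run_study_level(neg, model = "fe",
                            rule = decision_rule("lower_better"))
  expect_equal(attr(res_lo, "kstar"), attr(res_hi, "kstar"))
  # adjustments mirror: thresholds on negated data are the negated thresholds
  expect_equal(res_lo$beta_pos, -res_hi$beta_neg, tolerance = 1e-9)
  expect_equal(res_lo$beta_neg, -res_hi$beta_pos, tolerance = 1e-9)
  expect_equal(res_lo$new_opt_pos, res_hi$new_opt_neg)
})

test_that("common-bias solutions combine harmonically and singletons are unchanged", {
  sim <- random_network(26, need_three_arm = TRUE)
  fit <- fit_fe(sim$network)
  H <- nma_influence(fit)
  ks <- as.integer(optimal_treatment(fit))
  s1 <- solution_set(fit, H, ks, 1L)
  c1 <- common_bias_solution_set(fit, H, ks, M = 1L)
  expect_equal(c1$u, s1$u)
  s2 <- solution_set(fit, H, ks, 2L)
  c12 <- common_bias_solution_set(fit, H, ks, M = c(1L, 2L))
  inv <- ifelse(is.finite(s1$u), 1 / s1$u, 0) +
    ifelse(is.finite(s2$u), 1 / s2$u, 0)
  expect_equal(c12$u, ifelse(inv == 0, Inf, 1 / inv))
  expect_error(common_bias_solution_set(fit, H, ks, M = integer(0)), "empty")
})

test_that("a common bias on all data of a two-treatment flat-prior network is minus the pooled mean", {
  y <- c(0.6, 0.9, 0.3); v <- c(0.1, 0.2, 0.4)
  fit <- fit_fe(k2_network(y, v), nma_prior(2, improper = TRUE))
  H <- nma_influence(fit)
  cb <- common_bias_solution_set(fit, H, M = 1:3)
  expect_equal(cb$u, -sum(y / v) / sum(1 / v), tolerance = 1e-10)
})

test_that("thresholds scale linearly with the data scale", {
  sim <- random_network(27, need_three_arm = TRUE)
  net <- sim$network
  c0 <- 3.7
  scaled <- net
  scaled$y <- c0 * scaled$y
  pr <- nma_prior(net$K, d0 = 0.2, Sigma_d = diag(5, net$K - 1))
  pr_s <- nma_prior(net$K, d0 = c0 * 0.2, Sigma_d = diag(5, net$K - 1))
  r1 <- run_study_level(net, prior = pr, model = "fe",
                        rule = decision_rule(mcid = 0.1))
  r2 <- run_study_level(scaled, prior = pr_s, model = "fe",
                        rule = decision_rule(mcid = c0 * 0.1))
  expect_equal(r2$beta_pos, c0 * r1$beta_pos, tolerance = 1e-6)
  expect_equal(r2$beta_neg, c0 * r1$beta_neg, tolerance = 1e-6)
})

test_that("the decision is invariant strictly inside the interval", {
  sim <- random_network(28, need_three_arm = TRUE)
  res <- run_study_level(sim$network, model = "fe")
  fit <- attr(res, "fit")
  ks <- attr(res, "kstar")
  set.seed(28)
  for (m in sample(nrow(res), 3)) {
    lo <- max(res$beta_neg[m], -5); hi <- min(res$beta_pos[m], 5)
    for (b in runif(5, lo + 1e-6 * (hi - lo), hi - 1e-6 * (hi - lo))) {
      probe <- fit_adjusted(fit, m = m, value = b)
      expect_equal(as.integer(optimal_treatment(probe)), ks)
    }
  }
})

test_that("an exact tie at the unadjusted data is reported as threshold zero with a warning", {
  fit <- fit_fe(k2_network(0, 1), nma_prior(2, improper = TRUE))
  H <- nma_influence(fit)
  expect_warning(s <- solution_set(fit, H, m = 1L), "tied")
  expect_equal(s$u, 0)
  th <- thresholds_from_solutions(s)
  expect_equal(th$beta_pos, 0)
})

test_that("study-level results table carries intervals, flags and sorting", {
  sim <- random_network(29, need_three_arm = TRUE)
  res <- run_study_level(sim$network, model = "fe", sort = TRUE)
  expect_s3_class(res, "nma_thresh")
  expect_equal(nrow(res), sim$network$N)
  expect_equal(res$int_lo, res$estimate + res$beta_neg)
  expect_equal(res$int_hi, res$estimate + res$beta_pos)
  expect_equal(res$sensitive,
               res$ci_lo < res$int_lo | res$ci_hi > res$int_hi)
  sm <- pmin(abs(res$beta_neg), abs(res$beta_pos))
  expect_true(all(diff(sm) >= 0))
})
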