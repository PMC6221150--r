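two_point_setup <- function(seed) {
  sim <- random_network(seed, K = 5, n = 10, need_three_arm = TRUE)
  fit <- fit_fe(sim$network)
  H <- nma_influence(fit)
  ks <- as.integer(optimal_treatment(fit))
  list(net = sim$network, fit = fit, H = H, ks = ks,
       s1 = suppressWarnings(solution_set(fit, H, ks, 1L)),
       s2 = suppressWarnings(solution_set(fit, H, ks, 2L)))
}

test_that("threshold-line axis intercepts are the one-dimensional thresholds", {
  st <- two_point_setup(41)
  lines <- threshold_lines_2d(st$s1, st$s2)
  for (i in seq_len(nrow(lines))) {
    # beta2 = 0 => beta1 = u1; beta1 = 0 => beta2 = u2
    if (is.finite(lines$u1[i]))
      expect_equal(lines$w1[i] * lines$u1[i], 1, tolerance = 1e-10)
    else expect_equal(lines$w1[i], 0)
    if (is.finite(lines$u2[i]))
      expect_equal(lines$w2[i] * lines$u2[i], 1, tolerance = 1e-10)
  }
  expect_error(threshold_lines_2d(st$s1,
                                  structure(st$s2, kstar = st$ks + 1L)),
               "inconsistent")
})

test_that("the invariant region is convex with the origin inside, and axis crossings match 1-D intervals", {
  for (seed in c(41, 43)) {
    st <- two_point_setup(seed)
    reg <- invariant_region_2d(threshold_lines_2d(st$s1, st$s2))
    v <- reg$vertices
    # convexity: all cross products of consecutive CCW edges non-negative
    n <- nrow(v)
    e <- v[c(2:n, 1), ] - v
    cross <- e[, 1] * e[c(2:n, 1), 2] - e[, 2] * e[c(2:n, 1), 1]
    expect_true(all(cross > -1e-9))
    expect_true(all(st$s1$u[is.finite(st$s1$u)] != 0))
    # restriction to each axis equals the 1-D invariant interval
    th1 <- thresholds_from_solutions(st$s1)
    th2 <- thresholds_from_solutions(st$s2)
    crossings <- function(dim) {
      tt <- numeric(0)
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        a <- v[i, 3 - dim]; b <- v[j, 3 - dim]
        if (a * b < 0) {
          t0 <- a / (a - b)
          tt <- c(tt, v[i, dim] + t0 * (v[j, dim] - v[i, dim]))
        }
      }
      sort(tt)
    }
    cx <- crossings(1)
    expect_equal(cx[1], max(th1$beta_neg, -reg$bound), tolerance = 1e-6)
    expect_equal(cx[2], min(th1$beta_pos, reg$bound), tolerance = 1e-6)
    cy <- crossings(2)
    expect_equal(cy[1], max(th2$beta_neg, -reg$bound), tolerance = 1e-6)
    expect_equal(cy[2], min(th2$beta_pos, reg$bound), tolerance = 1e-6)
  }
})

test_that("probes just inside and outside each labelled boundary segment behave as labelled", {
  st <- two_point_setup(44)
  reg <- invariant_region_2d(threshold_lines_2d(st$s1, st$s2))
  v <- reg$vertices
  for (i in seq_len(nrow(reg$edges))) {
    a <- reg$edges$a[i]
    if (is.na(a)) next
    mid <- (v[reg$edges$from[i], ] + v[reg$edges$to[i], ]) / 2
    for (f in c(0.999, 1.001)) {
      probe <- f * mid
      refit <- fit_adjusted(st$fit, beta = `[<-`(numeric(st$net$N), 1:2,
                                                 probe))
      kk <- as.integer(optimal_treatment(refit))
      if (f < 1) expect_equal(kk, st$ks)
      else expect_equal(kk, a)
    }
  }
})

test_that("monte-carlo membership agrees with refit classification", {
  st <- two_point_setup(45)
  lines <- threshold_lines_2d(st$s1, st$s2)
  reg <- invariant_region_2d(lines)
  set.seed(45)
  span <- max(abs(reg$vertices)) * 1.5
  for (r in 1:40) {
    pt <- runif(2, -span, span)
    inside <- all(lines$w1 * pt[1] + lines$w2 * pt[2] <= 1)
    if (min(abs(lines$w1 * pt[1] + lines$w2 * pt[2] - 1)) < 1e-3) next
    refit <- fit_adjusted(st$fit, beta = `[<-`(numeric(st$net$N), 1:2, pt))
    unchanged <- as.integer(optimal_treatment(refit)) == st$ks
    expect_equal(unchanged, inside)
  }
})

test_that("beta_min is the closest point of each hyperplane and ties the treatments there", {
  st <- two_point_setup(46)
  bm <- beta_min(list(st$s1, st$s2))
  expect_true(all(diff(bm$norm) >= 0))
  for (i in seq_len(nrow(bm))) {
    a <- bm$a[i]
    w <- c(1 / st$s1$u[st$s1$a == a], 1 / st$s2$u[st$s2$a == a])
    w[!is.finite(w)] <- 0
    b <- c(bm$beta_1[i], bm$beta_2[i])
    expect_equal(sum(b * w), 1, tolerance = 1e-10)     # on the plane
    expect_equal(bm$norm[i], 1 / sqrt(sum(w^2)), tolerance = 1e-10)
    # no sampled point on the plane is closer to the origin
    set.seed(100 + i)
    for (t in rnorm(20, 0, 3)) {
      pt <- b + t * c(-w[2], w[1]) / max(sqrt(sum(w^2)), 1e-12)
      expect_gte(sqrt(sum(pt^2)) + 1e-12, bm$norm[i])
    }
    # refit at beta_min: treatment a ties the current optimum
    refit <- fit_adjusted(st$fit, beta = `[<-`(numeric(st$net$N), 1:2, b))
    expect_lt(abs(contrast_mean(refit, a, st$ks)), 1e-8)
  }
})

test_that("r = 1 beta_min is the scalar threshold set", {
  st <- two_point_setup(47)
  bm <- beta_min(list(st$s1))
  fin <- st$s1[is.finite(st$s1$u), ]
  expect_setequal(bm$a, fin$a)
  expect_equal(bm$beta_1[match(fin$a, bm$a)], fin$u)
})

test_that("common-bias regions reduce to plain lines for singletons and reject overlap", {
  st <- two_point_setup(48)
  reg1 <- common_bias_region_2d(st$fit, st$H, st$ks, M1 = 1L, M2 = 2L)
  reg2 <- invariant_region_2d(threshold_lines_2d(st$s1, st$s2))
  expect_equal(reg1$vertices, reg2$vertices, tolerance = 1e-10)
  expect_error(common_bias_region_2d(st$fit, st$H, st$ks, M1 = c(1L, 2L),
                                     M2 = 2L), "overlap")
})
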