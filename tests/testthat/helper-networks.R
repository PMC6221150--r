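# Shared fixtures: all synthetic, built in code.

# Random connected network with at least one three-arm study (when asked),
# drawn from the generator's stated hierarchy.
random_network <- function(seed, K = NULL, n = NULL, tau2 = 0,
                           need_three_arm = FALSE) {
  set.seed(seed)
  K <- K %||% sample(3:6, 1)
  n <- n %||% sample(5:20, 1)
  for (s in seq_len(100)) {
    sim <- generate(sim_spec(K, n, multi_arm_fraction = 0.4, tau2 = tau2,
                             seed = seed * 100 + s))
    has3 <- any(vapply(sim$network$studies,
                       function(st) length(st$treatments) == 3L, logical(1)))
    if (!need_three_arm || has3) return(sim)
  }
  stop("could not draw a network with a three-arm study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-treatment network from explicit estimates/variances.
k2_network <- function(y, v) {
  nma_data(data.frame(study = seq_along(y), treatment = 2, comparator = 1,
                      estimate = y, variance = v))
}

# A fit for each influence variant on the same random backbone, paired with
# its expected influence object. Used by the refit-identity tests.
variant_fits <- function(seed) {
  net <- random_network(seed, need_three_arm = TRUE)$network
  pr <- nma_prior(net$K, Sigma_d = diag(4, net$K - 1))
  N <- net$N
  set.seed(seed + 7)
  # extended designs: a study-level shift parameter shared by two studies
  M <- matrix(0, N, 1)
  M[net$contrasts$study %in% c(1, 2), 1] <- 1
  ext <- extended_spec(M, mu0 = 0, Sigma_mu = 2)
  Z <- class_membership(net$K)
  list(
    fe = fit_fe(net, pr),
    re = fit_re_fixed_tau(net, pr, tau2 = 0.04),
    fe_extended = fit_fe_extended(net, pr, ext),
    re_extended = fit_re_extended(net, pr, ext, tau2 = 0.04),
    class_re = fit_class_re(net, class_spec(Z, Sigma_class = 0.1), 0.04)
  )
}

# Assign non-reference treatments to two classes.
class_membership <- function(K) {
  p <- K - 1L
  Z <- matrix(0, p, 2)
  Z[cbind(seq_len(p), rep_len(1:2, p))] <- 1
  Z
}

expect_rel_equal <- function(got, want, tol = 1e-8) {
  expect_lt(max(abs(got - want)) / max(1, max(abs(want))), tol)
}
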