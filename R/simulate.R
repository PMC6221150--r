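#' Specification for a synthetic NMA data set
#'
#' Describes the data-generating hierarchy used throughout the test suite:
#' a connected network of two- and three-arm studies with normal
#' relative-effect data drawn exactly from
#' \eqn{\delta | d, \tau^2 \sim N(Xd, \Sigma_{\tau^2})},
#' \eqn{y | \delta \sim N(\delta, V)}. Sampling covariances \eqn{V_j} are
#' induced from per-arm variances (so three-arm blocks carry the shared
#' baseline-arm variance off the diagonal), and the between-study blocks
#' carry the 0.5 multi-arm correlation.
#'
#' @param K number of treatments (>= 2).
#' @param n_studies number of studies.
#' @param multi_arm_fraction probability a study has three arms (when
#'   \code{K >= 3}).
#' @param d_true true basic effects (length \code{K - 1}); default draws
#'   them once from \code{N(0, 0.5^2)} under the spec's seed.
#' @param variance_range range of the uniform per-arm variances.
#' @param tau2 true between-study variance (0 gives fixed-effect data).
#' @param seed RNG seed; \code{generate()} is reproducible given the spec.
#' @return An object of class \code{"sim_spec"}.
#' @export
sim_spec <- function(K, n_studies, multi_arm_fraction = 0.25, d_true = NULL,
                     variance_range = c(0.05, 0.3), tau2 = 0, seed = 1L) {
  K <- as.integer(K)
  if (K < 2L) stop("a network needs at least 2 treatments", call. = FALSE)
  stopifnot(n_studies >= 1L, tau2 >= 0,
            multi_arm_fraction >= 0, multi_arm_fraction <= 1,
            length(variance_range) == 2L, all(variance_range > 0))
  structure(list(K = K, n_studies = as.integer(n_studies),
                 multi_arm_fraction = multi_arm_fraction, d_true = d_true,
                 variance_range = variance_range, tau2 = tau2,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a synthetic network and data from a specification
#'
#' Draws study designs (which treatments each study compares) until the
#' network is connected, then draws study effects and data from the stated
#' hierarchy. The ground truth is returned for recovery tests.
#'
#' @param spec a [sim_spec].
#' @return List with \code{network} (an [nma_data]) and \code{truth} (list
#'   with \code{d_true}, \code{tau2}, \code{delta}).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  K <- spec$K
  d_true <- spec$d_true %||% stats::rnorm(K - 1L, 0, 0.5)
  stopifnot(length(d_true) == K - 1L)
  d_full <- c(0, d_true)

  for (attempt in seq_len(1000L)) {
    arms <- ifelse(stats::runif(spec$n_studies) < spec$multi_arm_fraction &
                     K >= 3L, 3L, 2L)
    designs <- lapply(arms, function(a) sort(sample.int(K, a)))
    edges <- do.call(rbind, lapply(designs, function(tr)
      t(utils::combn(tr, 2L))))
    g <- igraph::add_vertices(
      igraph::graph_from_edgelist(edges, directed = FALSE),
      max(0L, K - max(edges)))
    if (igraph::components(g)$no == 1L && max(edges) == K) break
    if (attempt == 1000L)
      stop("failed to generate a connected network; increase n_studies",
           call. = FALSE)
  }

  rows <- NULL
  delta_all <- numeric(0)
  for (j in seq_along(designs)) {
    tr <- designs[[j]]
    nr <- length(tr) - 1L
    s_arm <- stats::runif(length(tr), spec$variance_range[1],
                          spec$variance_range[2])
    Vj <- diag(s_arm[-1L], nr, nr) + s_arm[1L]
    mu <- d_full[tr[-1L]] - d_full[tr[1L]]
    St_j <- spec$tau2 * (diag(0.5, nr, nr) + matrix(0.5, nr, nr))
    delta <- drop(mu + chol_sample(St_j))
    yj <- drop(delta + chol_sample(Vj))
    rec <- data.frame(study = j, treatment = tr[-1L], comparator = tr[1L],
                      estimate = yj, variance = diag(Vj))
    if (nr > 1L) for (cc in seq_len(nr - 1L))
      rec[[paste0("cov_with_prev", cc)]] <-
        c(rep(NA_real_, cc), Vj[cbind((cc + 1L):nr, 1L:(nr - cc))])
    rows <- rbind_fill(rows, rec)
    delta_all <- c(delta_all, delta)
  }
  network <- suppressWarnings(nma_data(rows))
  list(network = network,
       truth = list(d_true = d_true, tau2 = spec$tau2, delta = delta_all))
}

# one multivariate normal draw with covariance S (allows S = 0)
chol_sample <- function(S) {
  S <- as.matrix(S)
  if (all(S == 0)) return(numeric(nrow(S)))
  e <- eigen(symmetrize(S), symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * stats::rnorm(nrow(S)))
}

#' Numerical bias-adjustment threshold by iterative refitting
#'
#' The expensive route the algebraic thresholds replace, kept as an
#' independent oracle: grow a bracket for \eqn{\beta_m} geometrically from
#' \eqn{\pm 10^{-6}} to \eqn{\pm 10^6} until the refitted optimal treatment
#' changes, then bisect to locate the change point. Used to verify the
#' influence-matrix thresholds.
#'
#' @param network an [nma_data].
#' @param prior an [nma_prior].
#' @param model \code{"fe"} or \code{"re"}.
#' @param rule a [decision_rule].
#' @param m datum index to adjust.
#' @param direction \code{"positive"} or \code{"negative"} side.
#' @param tau2 between-study variance for the RE model.
#' @param tol relative bisection tolerance.
#' @return The threshold (signed), or \code{Inf}/\code{-Inf} when the
#'   optimum never changes within the bracket (open side).
#' @export
numerical_threshold_oracle <- function(network, prior = NULL,
                                       model = c("fe", "re"), rule = NULL,
                                       m, direction = c("positive", "negative"),
                                       tau2 = NULL, tol = 1e-10) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  rule <- rule %||% decision_rule(network$outcome_direction)
  fit0 <- nma_fit(network, model, prior = prior, tau2 = tau2)
  k0 <- as.integer(optimal_treatment(fit0, rule))
  changed <- function(beta) {
    f <- fit_adjusted(fit0, m = m, value = beta)
    as.integer(optimal_treatment(f, rule)) != k0
  }
  s <- if (direction == "positive") 1 else -1
  beta <- s * 1e-6
  lo <- 0
  while (abs(beta) <= 1e6) {
    if (changed(beta)) break
    lo <- beta
    beta <- beta * 2
  }
  if (abs(beta) > 1e6) return(s * Inf)
  hi <- beta
  while (abs(hi - lo) > tol * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (changed(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Parameter recovery summary for the generator and the conjugate fits
#'
#' Repeatedly generates data under a specification, fits the matching
#' model, and summarises recovery of the true basic effects: root-mean-
#' square error and empirical coverage of the central 95\% posterior
#' intervals.
#'
#' @param spec a [sim_spec]; replicate \code{r} uses seed
#'   \code{spec$seed + r}.
#' @param reps number of replicates (>= 1).
#' @param prior an [nma_prior] (default vague).
#' @return List with \code{rmse}, \code{coverage}, \code{reps}.
#' @export
parameter_recovery <- function(spec, reps, prior = NULL) {
  stopifnot(reps >= 1L)
  err2 <- 0
  cover <- 0
  n_par <- 0
  for (r in seq_len(reps)) {
    sp <- spec
    sp$seed <- spec$seed + r
    sim <- generate(sp)
    fit <- nma_fit(sim$network, if (spec$tau2 > 0) "re" else "fe",
                   prior = prior, tau2 = spec$tau2)
    sd_d <- sqrt(diag(fit$cov_d))
    err2 <- err2 + sum((fit$mean_d - sim$truth$d_true)^2)
    cover <- cover + sum(abs(fit$mean_d - sim$truth$d_true) <= 1.96 * sd_d)
    n_par <- n_par + length(sim$truth$d_true)
  }
  list(rmse = sqrt(err2 / n_par), coverage = cover / n_par, reps = reps)
}
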