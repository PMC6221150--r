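#' Normal prior for the basic treatment effects
#'
#' The basic parameters \eqn{d = (d_2, \dots, d_K)} receive a multivariate
#' normal prior \eqn{d \sim N(d_0, \Sigma_d)}. The default is the
#' conventional vague choice \eqn{d_0 = 0}, \eqn{\Sigma_d = 10^6 I}. With
#' \code{improper = TRUE} the prior precision is the zero matrix (improper
#' flat prior), under which the fixed-effect posterior mean equals the
#' frequentist generalised-least-squares estimate.
#'
#' @param K number of treatments in the network.
#' @param d0 prior mean, recycled to length \code{K - 1}.
#' @param Sigma_d prior covariance, \code{(K-1) x (K-1)} symmetric positive
#'   definite; a scalar is expanded to \code{scalar * I}. Ignored when
#'   \code{improper = TRUE}.
#' @param improper if \code{TRUE}, use the improper flat prior.
#' @return An object of class \code{"nma_prior"}.
#' @export
nma_prior <- function(K, d0 = 0, Sigma_d = NULL, improper = FALSE) {
  K <- as.integer(K)
  stopifnot(K >= 2L)
  p <- K - 1L
  d0 <- rep_len(as.numeric(d0), p)
  if (improper) {
    prec <- matrix(0, p, p)
    Sigma_d <- NULL
  } else {
    if (is.null(Sigma_d)) Sigma_d <- diag(1e6, p)
    if (length(Sigma_d) == 1L) Sigma_d <- diag(as.numeric(Sigma_d), p)
    Sigma_d <- as.matrix(Sigma_d)
    if (!all(dim(Sigma_d) == p))
      stop("Sigma_d must be (K-1) x (K-1)", call. = FALSE)
    if (!is_spd(Sigma_d))
      stop("Sigma_d must be symmetric positive definite", call. = FALSE)
    prec <- spd_inv(Sigma_d, "prior covariance")
  }
  structure(list(K = K, d0 = d0, Sigma_d = Sigma_d, improper = improper,
                 prec = prec, prec_mean = drop(prec %*% d0)),
            class = "nma_prior")
}

#' @export
print.nma_prior <- function(x, ...) {
  if (x$improper) cat("Improper flat prior on", x$K - 1L, "basic effects\n")
  else cat(sprintf("Normal prior on %d basic effects (max prior sd %.3g)\n",
                   x$K - 1L, sqrt(max(diag(x$Sigma_d)))))
  invisible(x)
}

new_nma_fit <- function(mean_d, cov_d, model, ...) {
  extras <- list(...)
  p <- length(mean_d)
  names(mean_d) <- paste0("d", 2:(p + 1L))
  dimnames(cov_d) <- list(names(mean_d), names(mean_d))
  structure(c(list(mean_d = mean_d, cov_d = symmetrize(cov_d), model = model),
              extras),
            class = "nma_fit")
}

#' Fit an NMA model with closed-form conjugate posteriors
#'
#' Front end dispatching to [fit_fe()] (fixed effect) or
#' [fit_re_fixed_tau()] (random effects with known between-study variance).
#'
#' @param network an [nma_data] object.
#' @param model \code{"fe"} or \code{"re"}.
#' @param prior an [nma_prior]; defaults to the vague prior.
#' @param tau2 between-study variance, required (and > 0) for \code{"re"}.
#' @return An object of class \code{"nma_fit"} with elements \code{mean_d}
#'   (posterior means of \eqn{d_2..d_K}), \code{cov_d} (posterior
#'   covariance), \code{model}, and for random-effects fits the partition
#'   \code{B_star} of the joint \eqn{(d, \delta)} covariance needed by the
#'   influence matrix. Supports \code{coef}, \code{vcov}, \code{print},
#'   \code{summary}.
#' @examples
#' net <- example_network()
#' fit <- nma_fit(net, "fe")
#' coef(fit)
#' @export
nma_fit <- function(network, model = c("fe", "re"), prior = NULL, tau2 = NULL) {
  model <- match.arg(model)
  prior <- prior %||% nma_prior(network$K)
  if (model == "fe") fit_fe(network, prior)
  else {
    if (is.null(tau2)) stop("tau2 must be supplied for the RE model",
                            call. = FALSE)
    if (tau2 == 0) fit_fe(network, prior) else
      fit_re_fixed_tau(network, prior, tau2)
  }
}

#' Fixed-effect conjugate posterior
#'
#' With likelihood \eqn{y \sim N(Xd, V)} and prior \eqn{d \sim N(d_0,
#' \Sigma_d)}, the posterior is \eqn{d | y \sim N(\Sigma_n(\Sigma_d^{-1} d_0
#' + X^T V^{-1} y), \Sigma_n)} with \eqn{\Sigma_n = (\Sigma_d^{-1} + X^T
#' V^{-1} X)^{-1}}.
#'
#' @inheritParams nma_fit
#' @return An \code{"nma_fit"} object (\code{model = "fe"}).
#' @export
fit_fe <- function(network, prior = NULL) {
  validate_nma_data(network)
  prior <- prior %||% nma_prior(network$K)
  stopifnot(prior$K == network$K)
  X <- build_design_matrix(network)
  Vinv <- spd_inv(network$V, "within-study covariance V")
  Sn <- spd_inv(prior$prec + t(X) %*% Vinv %*% X, "posterior precision")
  mean_d <- drop(Sn %*% (prior$prec_mean + t(X) %*% Vinv %*% network$y))
  new_nma_fit(mean_d, Sn, "fe", network = network, prior = prior,
              tau2 = 0, X = X, Vinv = Vinv, source = "fitted_fe")
}

#' Random-effects conjugate posterior with fixed between-study variance
#'
#' Treats \eqn{\tau^2} as known and unchanged by bias adjustment, preserving
#' conjugacy. The joint posterior of \eqn{(d, \delta)} is obtained by
#' inverting the assembled joint precision; the cross-covariance partition
#' \eqn{B^*} (covariance of \eqn{d} with the study-specific effects
#' \eqn{\delta}) is retained because the influence matrix of this model is
#' \eqn{H = B^* V^{-1}}.
#'
#' @inheritParams nma_fit
#' @param tau2 between-study variance, strictly positive (use [fit_fe()] for
#'   the \eqn{\tau^2 = 0} limit).
#' @return An \code{"nma_fit"} object (\code{model = "re"}) carrying
#'   \code{B_star} and the joint mean/covariance in \code{joint}.
#' @export
fit_re_fixed_tau <- function(network, prior = NULL, tau2) {
  validate_nma_data(network)
  prior <- prior %||% nma_prior(network$K)
  stopifnot(prior$K == network$K)
  if (!is.numeric(tau2) || tau2 <= 0)
    stop("tau2 must be > 0 for the random-effects fit", call. = FALSE)
  X <- build_design_matrix(network)
  N <- network$N; p <- network$K - 1L
  Vinv <- spd_inv(network$V, "within-study covariance V")
  St_inv <- spd_inv(build_re_covariance(network, tau2),
                    "between-study covariance")
  P <- rbind(
    cbind(t(X) %*% St_inv %*% X + prior$prec, -t(X) %*% St_inv),
    cbind(-St_inv %*% X, Vinv + St_inv))
  Sn <- spd_inv(P, "joint posterior precision")
  rhs <- c(prior$prec_mean, drop(Vinv %*% network$y))
  m_joint <- drop(Sn %*% rhs)
  id <- seq_len(p)
  new_nma_fit(m_joint[id], Sn[id, id, drop = FALSE], "re",
              network = network, prior = prior, tau2 = tau2,
              X = X, Vinv = Vinv,
              B_star = Sn[id, p + seq_len(N), drop = FALSE],
              joint = list(mean = m_joint, cov = Sn),
              source = "fitted_re")
}

#' Posterior summary from an external analysis
#'
#' Wraps a reported joint posterior (e.g. from MCMC output of a complex
#' hierarchical NMA) in the same container produced by the fitting functions,
#' partitioning the covariance so downstream influence and threshold
#' computations can proceed. The layout names which coordinates are the basic
#' effects \eqn{d}, which are study effects \eqn{\delta} (yielding
#' \code{B_star}), and which are additional parameters \eqn{\mu} (yielding
#' \code{D_star}).
#'
#' @param mean posterior mean vector, or \code{NULL} when \code{draws} given.
#' @param cov posterior covariance matrix, or \code{NULL} when \code{draws}
#'   given.
#' @param layout list with integer index vectors \code{d} (required),
#'   \code{delta}, \code{mu} (optional) into the coordinates of \code{mean}.
#' @param draws optional matrix of posterior samples (one row per draw);
#'   empirical mean and covariance are used.
#' @return An \code{"nma_fit"} object with \code{model = "external"}.
#' @export
partition_external_posterior <- function(mean = NULL, cov = NULL,
                                         layout = NULL, draws = NULL) {
  if (!is.null(draws)) {
    draws <- as.matrix(draws)
    mean <- colMeans(draws)
    cov <- stats::cov(draws)
  }
  stopifnot(!is.null(mean), !is.null(cov))
  cov <- as.matrix(cov)
  q <- length(mean)
  if (!all(dim(cov) == q)) stop("mean and cov do not conform", call. = FALSE)
  layout <- layout %||% list(d = seq_len(q))
  idx_all <- unlist(layout, use.names = FALSE)
  if (length(idx_all) && (max(idx_all) > q || min(idx_all) < 1L))
    stop("layout indices outside posterior dimension", call. = FALSE)
  d_id <- layout$d
  if (is.null(d_id)) stop("layout must name the d coordinates", call. = FALSE)
  B_star <- if (!is.null(layout$delta))
    cov[d_id, layout$delta, drop = FALSE]
  D_star <- if (!is.null(layout$mu)) cov[d_id, layout$mu, drop = FALSE]
  new_nma_fit(mean[d_id], cov[d_id, d_id, drop = FALSE], "external",
              B_star = B_star, D_star = D_star, source = "external")
}

#' Read an externally reported posterior summary from CSV
#'
#' Expects a header row and one row per basic parameter: a \code{label}
#' column (treatment codes \code{2..K}), a \code{mean} column, and a square
#' block of covariance columns. Alternatively \code{draws} names a CSV of
#' posterior samples (one column per parameter).
#'
#' @param path CSV of the posterior summary.
#' @param draws optional CSV of posterior draws used instead of \code{path}.
#' @param layout passed to [partition_external_posterior()].
#' @return An \code{"nma_fit"} with \code{model = "external"}.
#' @export
read_posterior <- function(path = NULL, draws = NULL, layout = NULL) {
  if (!is.null(draws)) {
    return(partition_external_posterior(
      draws = as.matrix(utils::read.csv(draws)), layout = layout))
  }
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("label", "mean") %in% names(df)))
    stop("posterior CSV needs 'label' and 'mean' columns plus the covariance block",
         call. = FALSE)
  covcols <- setdiff(names(df), c("label", "mean"))
  if (length(covcols) != nrow(df))
    stop("covariance block is not square", call. = FALSE)
  partition_external_posterior(df$mean, as.matrix(df[covcols]),
                               layout = layout)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Accepts a file naming any of \code{outcome_direction}, \code{mcid},
#' \code{tau2}, and a \code{prior} block (\code{d0}, \code{sd} or
#' \code{Sigma_d} diagonal, \code{improper}).
#'
#' @param path file ending in \code{.yaml}/\code{.yml} (requires the yaml
#'   package) or \code{.json} (requires jsonlite).
#' @param K number of treatments, needed to materialise the prior.
#' @return List with a [decision_rule] \code{rule}, an [nma_prior]
#'   \code{prior}, and \code{tau2} (possibly \code{NULL}).
#' @export
read_config <- function(path, K) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  pr <- cfg$prior %||% list()
  prior <- nma_prior(K,
                     d0 = pr$d0 %||% 0,
                     Sigma_d = if (!is.null(pr$sd)) diag(pr$sd^2, K - 1L)
                               else pr$Sigma_d,
                     improper = isTRUE(pr$improper))
  list(rule = decision_rule(cfg$outcome_direction %||% "higher_better",
                            mcid = cfg$mcid %||% 0),
       prior = prior,
       tau2 = cfg$tau2)
}

#' Posterior mean of an arbitrary treatment contrast
#'
#' By the consistency equations, \eqn{d_{ab} = d_b - d_a} with
#' \eqn{d_1 = 0}, so \eqn{E(d_{ab}) = E(d_b) - E(d_a)}.
#'
#' @param posterior an \code{"nma_fit"} object.
#' @param a,b treatment codes in \code{1..K}.
#' @return The scalar \eqn{E(d_{ab})}.
#' @export
contrast_mean <- function(posterior, a, b) {
  E <- unname(c(0, posterior$mean_d))
  K <- length(E)
  stopifnot(a >= 1, a <= K, b >= 1, b <= K)
  E[b] - E[a]
}

#' @export
coef.nma_fit <- function(object, ...) object$mean_d

#' @export
vcov.nma_fit <- function(object, ...) object$cov_d

#' @export
print.nma_fit <- function(x, digits = 3, ...) {
  cat(sprintf("NMA posterior (%s model%s)\n", x$model,
              if (!is.null(x$tau2) && x$tau2 > 0)
                sprintf(", tau2 = %g", x$tau2) else ""))
  print(round(x$mean_d, digits))
  invisible(x)
}

#' @export
summary.nma_fit <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$cov_d))
  out <- data.frame(mean = object$mean_d, sd = se,
                    lower = object$mean_d - z * se,
                    upper = object$mean_d + z * se)
  rownames(out) <- names(object$mean_d)
  structure(list(table = out, model = object$model, level = level),
            class = "summary.nma_fit")
}

#' @export
print.summary.nma_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (%s model), %g%% intervals\n",
              x$model, 100 * x$level))
  print(round(x$table, digits))
  invisible(x)
}

#' Run the random-effects threshold analysis over a grid of tau2 values
#'
#' The fixed-\eqn{\tau^2} approximation should be checked by sensitivity
#' analysis, substituting plausible values such as the limits of the credible
#' interval for \eqn{\tau} from the original analysis.
#'
#' @param network an [nma_data] object.
#' @param tau2_values numeric vector of between-study variances (0 allowed,
#'   giving the fixed-effect model).
#' @param prior an [nma_prior].
#' @param rule a [decision_rule]; defaults from the network.
#' @return A list of [nma_thresh] results, one per \code{tau2} value, named
#'   by the value.
#' @export
tau2_sensitivity <- function(network, tau2_values, prior = NULL, rule = NULL) {
  out <- lapply(tau2_values, function(t2)
    run_study_level(network, prior = prior,
                    model = if (t2 > 0) "re" else "fe",
                    rule = rule, tau2 = t2))
  names(out) <- paste0("tau2=", tau2_values)
  out
}
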