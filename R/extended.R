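# Extended conjugate models: additional parameters (e.g. study baselines for
# arm-level data) and class-effect random-effects models. These exist so the
# corresponding influence-matrix variants have fittable models to act on and
# to be verified against.

#' Specification of an extended model
#'
#' Describes additional normal parameters \eqn{\mu \sim N(\mu_0, \Sigma_\mu)}
#' entering the likelihood, and (for random-effects models) the design
#' matrices linking data to study effects and extra parameters:
#' \eqn{y | \delta, \mu \sim N(L\delta + M\mu, V)}.
#'
#' @param M \code{N x p} design of the extra parameters (may have 0 columns).
#' @param L \code{N x N} design for the study effects \eqn{\delta}
#'   (random-effects models only); defaults to the identity.
#' @param mu0,Sigma_mu prior mean and covariance of \eqn{\mu}.
#' @return An object of class \code{"extended_spec"}.
#' @export
extended_spec <- function(M, L = NULL, mu0 = 0, Sigma_mu = NULL) {
  M <- as.matrix(M)
  p <- ncol(M)
  mu0 <- rep_len(as.numeric(mu0), p)
  if (is.null(Sigma_mu)) Sigma_mu <- diag(1e6, p)
  if (length(Sigma_mu) == 1L && p == 1L) Sigma_mu <- matrix(Sigma_mu, 1, 1)
  Sigma_mu <- as.matrix(Sigma_mu)
  if (p > 0L && !all(dim(Sigma_mu) == p))
    stop("Sigma_mu must be p x p", call. = FALSE)
  structure(list(M = M, L = L, mu0 = mu0, Sigma_mu = Sigma_mu, p = p),
            class = "extended_spec")
}

#' Fixed-effect model with additional parameters
#'
#' The parameter vector is extended to \eqn{\gamma = (d, \mu)} with stacked
#' design \eqn{[X \; M]}; the conjugate posterior follows exactly as in the
#' basic fixed-effect case. The first \eqn{K - 1} coordinates of the
#' posterior are the basic effects.
#'
#' @param network an [nma_data] object; alternatively supply \code{y},
#'   \code{V} and \code{X} directly via \code{...} is not supported — build a
#'   network object first.
#' @param prior an [nma_prior] for \eqn{d}.
#' @param ext an [extended_spec] with \code{N}-row \code{M}.
#' @return An \code{"nma_fit"} with \code{model = "fe_extended"}, carrying
#'   the full stacked design \code{X_full} and joint covariance.
#' @export
fit_fe_extended <- function(network, prior = NULL, ext) {
  validate_nma_data(network)
  prior <- prior %||% nma_prior(network$K)
  stopifnot(inherits(ext, "extended_spec"), nrow(ext$M) == network$N)
  X <- build_design_matrix(network)
  Xf <- cbind(X, ext$M)
  p <- network$K - 1L
  Vinv <- spd_inv(network$V, "within-study covariance V")
  prec_prior <- block_diag(list(prior$prec,
                                spd_inv(ext$Sigma_mu, "Sigma_mu")))
  Sn <- spd_inv(prec_prior + t(Xf) %*% Vinv %*% Xf,
                "extended posterior precision")
  rhs <- c(prior$prec_mean,
           drop(spd_inv(ext$Sigma_mu, "Sigma_mu") %*% ext$mu0)) +
    drop(t(Xf) %*% Vinv %*% network$y)
  m <- drop(Sn %*% rhs)
  id <- seq_len(p)
  new_nma_fit(m[id], Sn[id, id, drop = FALSE], "fe_extended",
              network = network, prior = prior, tau2 = 0,
              X = X, X_full = Xf, Vinv = Vinv, ext = ext,
              joint = list(mean = m, cov = Sn), source = "fitted_fe")
}

#' Random-effects model with additional parameters
#'
#' Likelihood \eqn{y | \delta, \mu \sim N(L\delta + M\mu, V)} with
#' \eqn{\delta | d \sim N(Xd, \Sigma_{\tau^2})} and normal priors on \eqn{d}
#' and \eqn{\mu}. The joint posterior over \eqn{(d, \delta, \mu)} is obtained
#' by inverting the assembled precision; the partitions \eqn{B^*}
#' (cov of \eqn{d} with \eqn{\delta}) and \eqn{D^*} (cov of \eqn{d} with
#' \eqn{\mu}) feed the influence matrix \eqn{H = (B^* L^T + D^* M^T) V^{-1}}.
#'
#' @inheritParams fit_fe_extended
#' @param tau2 between-study variance (> 0).
#' @return An \code{"nma_fit"} with \code{model = "re_extended"}.
#' @export
fit_re_extended <- function(network, prior = NULL, ext, tau2) {
  validate_nma_data(network)
  prior <- prior %||% nma_prior(network$K)
  stopifnot(inherits(ext, "extended_spec"), nrow(ext$M) == network$N,
            tau2 > 0)
  X <- build_design_matrix(network)
  N <- network$N; p <- network$K - 1L; pm <- ext$p
  L <- ext$L %||% diag(N)
  M <- ext$M
  Vinv <- spd_inv(network$V, "within-study covariance V")
  St_inv <- spd_inv(build_re_covariance(network, tau2),
                    "between-study covariance")
  Smu_inv <- if (pm > 0L) spd_inv(ext$Sigma_mu, "Sigma_mu") else
    matrix(0, 0, 0)
  # parameter order (d, delta, mu)
  P <- rbind(
    cbind(t(X) %*% St_inv %*% X + prior$prec, -t(X) %*% St_inv,
          matrix(0, p, pm)),
    cbind(-St_inv %*% X, St_inv + t(L) %*% Vinv %*% L, t(L) %*% Vinv %*% M),
    cbind(matrix(0, pm, p), t(M) %*% Vinv %*% L,
          Smu_inv + t(M) %*% Vinv %*% M))
  Sn <- spd_inv(P, "joint posterior precision")
  rhs <- c(prior$prec_mean,
           drop(t(L) %*% Vinv %*% network$y),
           if (pm > 0L) drop(Smu_inv %*% ext$mu0 + t(M) %*% Vinv %*% network$y)
           else numeric(0))
  m <- drop(Sn %*% rhs)
  id <- seq_len(p)
  new_nma_fit(m[id], Sn[id, id, drop = FALSE], "re_extended",
              network = network, prior = prior, tau2 = tau2,
              X = X, Vinv = Vinv, ext = ext,
              B_star = Sn[id, p + seq_len(N), drop = FALSE],
              D_star = if (pm > 0L)
                Sn[id, p + N + seq_len(pm), drop = FALSE]
              else matrix(0, p, 0),
              joint = list(mean = m, cov = Sn), source = "fitted_re")
}

#' Class-effect structure for treatment effects
#'
#' Treatment effects exchangeable within classes: \eqn{d | z \sim N(Zz,
#' \Sigma_{class})} with class effects \eqn{z \sim N(z_0, \Sigma_z)}.
#' \code{Sigma_class} equal to the zero matrix gives fixed class effects
#' (\eqn{d = Zz} exactly).
#'
#' @param Z \code{(K-1) x c} class design assigning each non-reference
#'   treatment to a class.
#' @param Sigma_class \code{(K-1) x (K-1)} between-treatment (within-class)
#'   covariance; a scalar is expanded to \code{scalar * I}; 0 means fixed
#'   class effects.
#' @param z0,Sigma_z prior mean and covariance of the class effects.
#' @return An object of class \code{"class_spec"}.
#' @export
class_spec <- function(Z, Sigma_class = 0, z0 = 0, Sigma_z = NULL) {
  Z <- as.matrix(Z)
  nc <- ncol(Z)
  if (length(Sigma_class) == 1L)
    Sigma_class <- diag(as.numeric(Sigma_class), nrow(Z))
  Sigma_class <- as.matrix(Sigma_class)
  z0 <- rep_len(as.numeric(z0), nc)
  if (is.null(Sigma_z)) Sigma_z <- diag(1e6, nc)
  if (length(Sigma_z) == 1L) Sigma_z <- diag(as.numeric(Sigma_z), nc)
  structure(list(Z = Z, Sigma_class = as.matrix(Sigma_class), z0 = z0,
                 Sigma_z = as.matrix(Sigma_z),
                 fixed = all(Sigma_class == 0)),
            class = "class_spec")
}

#' Random-effects model with class effects
#'
#' For exchangeable class effects (\code{Sigma_class} positive definite) the
#' hierarchical prior on \eqn{d} marginalises to the normal prior
#' \eqn{d \sim N(Z z_0, \Sigma_{class} + Z \Sigma_z Z^T)} and the fit reduces
#' to [fit_re_fixed_tau()] with that prior. For fixed class effects
#' (\code{Sigma_class = 0}) the model is fitted in class space with design
#' \eqn{XZ} and mapped back via \eqn{d = Zz}. In both cases the influence
#' matrix has the same form as the extended random-effects model.
#'
#' @param network an [nma_data] object.
#' @param cls a [class_spec].
#' @param tau2 between-study variance (> 0).
#' @return An \code{"nma_fit"} with \code{model = "class_re"} carrying
#'   \code{B_star}.
#' @export
fit_class_re <- function(network, cls, tau2) {
  stopifnot(inherits(cls, "class_spec"))
  p <- network$K - 1L
  if (nrow(cls$Z) != p) stop("Z must have K-1 rows", call. = FALSE)
  if (!cls$fixed) {
    pr <- nma_prior(network$K, d0 = drop(cls$Z %*% cls$z0),
                    Sigma_d = cls$Sigma_class +
                      cls$Z %*% cls$Sigma_z %*% t(cls$Z))
    fit <- fit_re_fixed_tau(network, pr, tau2)
    fit$model <- "class_re"
    fit$cls <- cls
    return(fit)
  }
  # fixed class effects: work in z space with design X Z, then d = Z z
  validate_nma_data(network)
  X <- build_design_matrix(network)
  Xz <- X %*% cls$Z
  N <- network$N; nc <- ncol(cls$Z)
  Vinv <- spd_inv(network$V, "within-study covariance V")
  St_inv <- spd_inv(build_re_covariance(network, tau2),
                    "between-study covariance")
  prec_z <- spd_inv(cls$Sigma_z, "Sigma_z")
  P <- rbind(
    cbind(t(Xz) %*% St_inv %*% Xz + prec_z, -t(Xz) %*% St_inv),
    cbind(-St_inv %*% Xz, Vinv + St_inv))
  Sn <- spd_inv(P, "joint posterior precision")
  rhs <- c(drop(prec_z %*% cls$z0), drop(Vinv %*% network$y))
  m <- drop(Sn %*% rhs)
  idz <- seq_len(nc)
  mean_d <- drop(cls$Z %*% m[idz])
  cov_d <- cls$Z %*% Sn[idz, idz, drop = FALSE] %*% t(cls$Z)
  B_star <- cls$Z %*% Sn[idz, nc + seq_len(N), drop = FALSE]
  new_nma_fit(mean_d, cov_d, "class_re",
              network = network, tau2 = tau2, X = X, Vinv = Vinv,
              cls = cls, B_star = B_star,
              joint = list(mean = m, cov = Sn), source = "fitted_re")
}
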