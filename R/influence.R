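#' Influence matrix of an NMA model
#'
#' The influence matrix \eqn{H} is the \eqn{(K-1) \times N} linear map from
#' additive perturbations of the data to changes in the posterior means of
#' the basic treatment effects: adjusting the data to \eqn{y + \beta} moves
#' the posterior mean to \eqn{E(d) + H\beta}. Its form depends on the model:
#' \describe{
#'   \item{fixed effect}{\eqn{H = \Sigma_n X^T V^{-1}}}
#'   \item{random effects (fixed \eqn{\tau^2})}{\eqn{H = B^* V^{-1}}}
#'   \item{extended FE}{first \eqn{K-1} rows of \eqn{\Sigma_n X^T V^{-1}}
#'     for the stacked design}
#'   \item{extended / class RE}{\eqn{H = (B^* L^T + D^* M^T) V^{-1}}}
#'   \item{frequentist GLS}{\eqn{H = (X^T V^{-1} X)^{-1} X^T V^{-1}}}
#' }
#' \code{nma_influence()} dispatches on the fitted model; the
#' \code{influence_*} functions expose each variant directly.
#'
#' External posteriors carrying only the mean and covariance of \eqn{d} have
#' no study-level influence matrix; use the contrast-level analysis
#' ([reconstruct_likelihood()], [run_contrast_level()]) instead.
#'
#' @param posterior an \code{"nma_fit"} object.
#' @param network the [nma_data] the model was fitted to (defaults to the one
#'   stored in the fit).
#' @return An object of class \code{"nma_influence"}: list with the matrix
#'   \code{H} (rows labelled \code{d2..dK}) and the model \code{variant}.
#' @examples
#' net <- example_network()
#' H <- nma_influence(fit_fe(net))
#' dim(H$H)
#' @export
nma_influence <- function(posterior, network = NULL) {
  stopifnot(inherits(posterior, "nma_fit"))
  switch(posterior$model,
    fe = influence_fe(posterior, network),
    re = influence_re(posterior, network),
    fe_extended = influence_fe_extended(posterior, network),
    re_extended = influence_re_extended(posterior, network),
    class_re = influence_re_extended(posterior, network),
    external = stop(
      "study-level influence is unavailable for an external posterior of d alone; use the contrast-level analysis",
      call. = FALSE),
    stop("unknown model variant: ", posterior$model, call. = FALSE))
}

new_influence <- function(H, variant) {
  if (!all(is.finite(H))) stop("influence matrix has non-finite entries",
                               call. = FALSE)
  rownames(H) <- paste0("d", 1L + seq_len(nrow(H)))
  structure(list(H = H, variant = variant), class = "nma_influence")
}

get_H <- function(x) {
  if (inherits(x, "nma_influence")) x$H else as.matrix(x)
}

#' @rdname nma_influence
#' @export
influence_fe <- function(posterior, network = NULL) {
  net <- network %||% posterior$network
  if (!posterior$model %in% c("fe", "external"))
    stop("influence_fe requires a fixed-effect posterior", call. = FALSE)
  X <- posterior$X %||% build_design_matrix(net)
  Vinv <- posterior$Vinv %||% spd_inv(net$V, "V")
  new_influence(posterior$cov_d %*% t(X) %*% Vinv, "fe")
}

#' @rdname nma_influence
#' @export
influence_re <- function(posterior, network = NULL) {
  if (is.null(posterior$B_star))
    stop("posterior does not carry the B* partition (cov of d with delta)",
         call. = FALSE)
  net <- network %||% posterior$network
  Vinv <- posterior$Vinv %||% spd_inv(net$V, "V")
  new_influence(posterior$B_star %*% Vinv, "re")
}

#' @rdname nma_influence
#' @param n_basic number of basic parameters to keep (defaults to
#'   \code{K - 1}); the remaining rows belong to nuisance parameters and are
#'   discarded.
#' @export
influence_fe_extended <- function(posterior, network = NULL, n_basic = NULL) {
  if (posterior$model != "fe_extended")
    stop("influence_fe_extended requires a fit from fit_fe_extended",
         call. = FALSE)
  net <- network %||% posterior$network
  n_basic <- n_basic %||% (net$K - 1L)
  Xf <- posterior$X_full
  Vinv <- posterior$Vinv %||% spd_inv(net$V, "V")
  H_full <- posterior$joint$cov %*% t(Xf) %*% Vinv
  new_influence(H_full[seq_len(n_basic), , drop = FALSE], "fe_extended")
}

#' @rdname nma_influence
#' @export
influence_re_extended <- function(posterior, network = NULL) {
  if (is.null(posterior$B_star))
    stop("posterior does not carry the B* partition", call. = FALSE)
  net <- network %||% posterior$network
  Vinv <- posterior$Vinv %||% spd_inv(net$V, "V")
  N <- ncol(posterior$B_star)
  L <- posterior$ext$L %||% diag(N)
  M <- posterior$ext$M %||% matrix(0, N, 0)
  D_star <- posterior$D_star %||% matrix(0, nrow(posterior$B_star), 0)
  H <- (posterior$B_star %*% t(L) +
          if (ncol(M) > 0L) D_star %*% t(M) else 0) %*% Vinv
  new_influence(H, if (posterior$model == "class_re") "class_re"
                else "re_extended")
}

#' @rdname nma_influence
#' @export
influence_frequentist <- function(network) {
  X <- build_design_matrix(network)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  Vinv <- spd_inv(network$V, "V")
  new_influence(spd_inv(t(X) %*% Vinv %*% X, "X'V^-1X") %*% t(X) %*% Vinv,
                "frequentist")
}

#' @export
print.nma_influence <- function(x, ...) {
  cat(sprintf("Influence matrix (%s variant): %d parameters x %d data points\n",
              x$variant, nrow(x$H), ncol(x$H)))
  invisible(x)
}

#' Write an influence matrix to CSV with labelled rows and columns
#'
#' @param influence an \code{"nma_influence"} object.
#' @param path output file.
#' @export
write_influence <- function(influence, path) {
  H <- get_H(influence)
  utils::write.csv(data.frame(parameter = rownames(H), H,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Refit a model on bias-adjusted data
#'
#' Convenience used by the numerical oracle and the refit-identity tests:
#' refits the same model after adding the adjustment vector \eqn{\beta} to
#' the data.
#'
#' @param posterior an \code{"nma_fit"} from one of the fitting functions
#'   (not external).
#' @param beta adjustment vector of length \code{N}, or a single index-value
#'   pair via \code{m} and \code{value}.
#' @param m,value optional: adjust only datum \code{m} by \code{value}.
#' @return A new \code{"nma_fit"} on the adjusted data.
#' @export
fit_adjusted <- function(posterior, beta = NULL, m = NULL, value = NULL) {
  net <- posterior$network
  if (is.null(net)) stop("cannot refit an external posterior", call. = FALSE)
  if (is.null(beta)) {
    beta <- numeric(net$N)
    beta[m] <- value
  }
  net$y <- net$y + beta
  switch(posterior$model,
    fe = fit_fe(net, posterior$prior),
    re = fit_re_fixed_tau(net, posterior$prior, posterior$tau2),
    fe_extended = fit_fe_extended(net, posterior$prior, posterior$ext),
    re_extended = fit_re_extended(net, posterior$prior, posterior$ext,
                                  posterior$tau2),
    class_re = fit_class_re(net, posterior$cls, posterior$tau2),
    stop("cannot refit model variant ", posterior$model, call. = FALSE))
}
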