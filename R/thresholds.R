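#' Decision rule for treatment recommendation
#'
#' The recommended treatment is the one with the best posterior expected
#' effect: the argmax of \eqn{E(d_k)} over \eqn{k = 1..K} (with
#' \eqn{E(d_1) = 0}) when higher outcomes are better, the argmin when lower
#' outcomes are better. An optional minimal clinically important difference
#' \eqn{\rho \ge 0} asks instead for the adjustment at which another
#' treatment becomes better than the current optimum by at least \eqn{\rho}.
#'
#' @param direction \code{"higher_better"} or \code{"lower_better"}.
#' @param mcid minimal clinically important difference \eqn{\rho \ge 0}, in
#'   effect units (default 0, the plain maximal-efficacy rule).
#' @return An object of class \code{"decision_rule"}.
#' @export
decision_rule <- function(direction = c("higher_better", "lower_better"),
                          mcid = 0) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(mcid), length(mcid) == 1L, mcid >= 0)
  structure(list(direction = direction, mcid = mcid),
            class = "decision_rule")
}

#' Optimal treatment under the current posterior
#'
#' @param posterior an \code{"nma_fit"} object.
#' @param rule a [decision_rule]; defaults to higher-is-better.
#' @return The optimal treatment code \eqn{k^*} (integer). Ties are broken
#'   to the lowest code and flagged via \code{attr(, "tie")}.
#' @examples
#' optimal_treatment(fit_fe(example_network()))
#' @export
optimal_treatment <- function(posterior, rule = NULL) {
  rule <- rule %||% decision_rule()
  E <- c(0, posterior$mean_d)
  if (rule$direction == "lower_better") E <- -E
  kstar <- which.max(E)
  tie <- sum(abs(E - max(E)) < 1e-12) > 1L
  if (tie) kstar <- min(which(abs(E - max(E)) < 1e-12))
  structure(as.integer(kstar), tie = tie)
}

# Signed effects and influence on the "benefit" scale: for lower-is-better
# outcomes both are negated so that the higher-is-better threshold algebra
# applies unchanged. The resulting u values are adjustments to the data on
# the original scale, so no back-transformation is needed.
benefit_scale <- function(mean_d, H, rule) {
  s <- if (rule$direction == "lower_better") -1 else 1
  list(E = s * c(0, mean_d), H = s * H)
}

#' Solution set of candidate bias adjustments for one datum
#'
#' For each non-optimal treatment \eqn{a}, the candidate adjustment
#' \eqn{u_{a k^*, m}} is the additive change to datum \eqn{y_m} at which the
#' posterior expectation of the contrast between \eqn{a} and the current
#' optimum \eqn{k^*} crosses zero (or the MCID \eqn{\rho}), making \eqn{a}
#' at least as good in expectation:
#' \deqn{u_{a k^*, m} = \frac{-E(d_{a k^*}) - \rho}{[H]_{k^*-1,m} - [H]_{a-1,m}}}
#' for \eqn{k^* \ne 1} (with the \eqn{a = 1} row of \eqn{H} read as zero),
#' and \eqn{u_{1a,m} = (-E(d_{1a}) + \rho) / [H]_{a-1,m}} when \eqn{k^* = 1}.
#' A zero influence difference gives an infinite solution: treatment \eqn{a}
#' can never become optimal through datum \eqn{m}.
#'
#' @param posterior an \code{"nma_fit"}.
#' @param H an [nma_influence] object or a bare \code{(K-1) x N} matrix.
#' @param kstar the current optimal treatment (from [optimal_treatment()]).
#' @param m datum index in \code{1..N}.
#' @param rule a [decision_rule].
#' @return An object of class \code{"solution_set"}: data frame with columns
#'   \code{a} (treatment) and \code{u} (signed adjustment, may be
#'   \code{Inf}/\code{-Inf}), plus attributes \code{kstar} and \code{m}.
#' @export
solution_set <- function(posterior, H, kstar = NULL, m, rule = NULL) {
  rule <- rule %||% decision_rule()
  H <- get_H(H)
  kstar <- as.integer(kstar %||% optimal_treatment(posterior, rule))
  if (length(m) != 1L || m < 1L || m > ncol(H))
    stop("datum index m out of range", call. = FALSE)
  bs <- benefit_scale(posterior$mean_d, H, rule)
  K <- length(bs$E)
  hcol <- c(0, bs$H[, m])  # influence on d_1 is identically zero
  a_set <- setdiff(seq_len(K), kstar)
  if (kstar != 1L) {
    num <- (bs$E[a_set] - bs$E[kstar]) - rule$mcid  # = -E(d_{a k*}) - rho
    den <- hcol[kstar] - hcol[a_set]
  } else {
    num <- -bs$E[a_set] + rule$mcid                 # = -E(d_{1a}) + rho
    den <- hcol[a_set]
  }
  u <- num / den
  u[is.nan(u)] <- Inf       # 0/0: contrast pinned, unreachable
  if (any(u == 0, na.rm = TRUE))
    warning("solution exactly 0: decision is tied at the unadjusted data",
            call. = FALSE)
  structure(data.frame(a = a_set, u = u),
            kstar = kstar, m = m, class = c("solution_set", "data.frame"))
}

#' Thresholds and invariant interval from a solution set
#'
#' The positive (negative) bias-adjustment threshold is the smallest
#' positive (largest negative) candidate solution; the treatment attaining
#' it is the new optimum at that threshold — no refit is needed, because the
#' contrast whose posterior expectation changes sign at the threshold is the
#' one that takes over the maximum. A side with no finite solution is open
#' (\code{Inf}/\code{-Inf}, reported as "NT", no threshold).
#'
#' @param solutions a \code{"solution_set"}.
#' @return An object of class \code{"threshold_result"}: list with
#'   \code{beta_neg}, \code{beta_pos}, \code{new_opt_neg},
#'   \code{new_opt_pos} (NA on an open side), \code{kstar}, \code{m}.
#' @export
thresholds_from_solutions <- function(solutions) {
  stopifnot(inherits(solutions, "solution_set"), nrow(solutions) > 0L)
  u <- solutions$u
  a <- solutions$a
  pos <- which(u >= 0 & is.finite(u))
  neg <- which(u < 0 & is.finite(u))
  if (length(pos)) {
    ip <- pos[which.min(u[pos])]
    beta_pos <- u[ip]; new_pos <- a[ip]
  } else {
    beta_pos <- Inf; new_pos <- NA_integer_
  }
  if (length(neg)) {
    im <- neg[which.max(u[neg])]
    beta_neg <- u[im]; new_neg <- a[im]
  } else {
    beta_neg <- -Inf; new_neg <- NA_integer_
  }
  structure(list(beta_neg = beta_neg, beta_pos = beta_pos,
                 new_opt_neg = new_neg, new_opt_pos = new_pos,
                 kstar = attr(solutions, "kstar"),
                 m = attr(solutions, "m")),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Datum %s: thresholds [%s, %s], new optimum %s / %s (k* = %d)\n",
              paste(x$m, collapse = ","),
              fmt_thresh(x$beta_neg), fmt_thresh(x$beta_pos),
              fmt_opt(x$new_opt_neg), fmt_opt(x$new_opt_pos), x$kstar))
  invisible(x)
}

fmt_thresh <- function(b) if (is.finite(b)) sprintf("%.2f", b) else "NT"
fmt_opt <- function(a) if (is.na(a)) "-" else as.character(a)

#' Solution set for a common bias across several data points
#'
#' When the same additive bias is applied to every datum in an index set
#' \eqn{M}, its influence is the sum of the individual influences, so the
#' candidate solutions combine harmonically:
#' \eqn{u_{a,M} = (\sum_{m \in M} u_{a,m}^{-1})^{-1}} with the convention
#' \eqn{\infty^{-1} = 0}.
#'
#' @inheritParams solution_set
#' @param M non-empty vector of datum indices.
#' @return A \code{"solution_set"} with attribute \code{m = M}.
#' @export
common_bias_solution_set <- function(posterior, H, kstar = NULL, M,
                                     rule = NULL) {
  rule <- rule %||% decision_rule()
  H <- get_H(H)
  if (length(M) == 0L) stop("index set M is empty", call. = FALSE)
  if (any(M < 1L | M > ncol(H))) stop("index in M out of range", call. = FALSE)
  kstar <- as.integer(kstar %||% optimal_treatment(posterior, rule))
  sets <- lapply(M, function(m)
    suppressWarnings(solution_set(posterior, H, kstar, m, rule)))
  inv_sum <- Reduce(`+`, lapply(sets, function(s) {
    r <- 1 / s$u
    r[!is.finite(s$u)] <- 0
    r
  }))
  u <- 1 / inv_sum
  u[inv_sum == 0] <- Inf
  structure(data.frame(a = sets[[1L]]$a, u = u),
            kstar = kstar, m = M, class = c("solution_set", "data.frame"))
}

#' Study-level threshold analysis
#'
#' Fits the chosen model, builds its influence matrix once, and derives
#' bias-adjustment thresholds and decision-invariant intervals for every
#' data point in turn. The invariant interval about \eqn{y_m} is
#' \eqn{(y_m + \beta^{-thresh}_m,\; y_m + \beta^{+thresh}_m)}; when the 95\%
#' confidence interval of a study estimate extends beyond its invariant
#' interval, the recommendation is sensitive to the level of imprecision in
#' that study and the row is flagged.
#'
#' @param network an [nma_data] object.
#' @param prior an [nma_prior] (default vague).
#' @param model \code{"fe"} or \code{"re"}.
#' @param rule a [decision_rule]; defaults to the network's outcome
#'   direction with \code{mcid = 0}.
#' @param tau2 between-study variance for the RE model.
#' @param sort if \code{TRUE}, order rows by smallest absolute threshold
#'   first (the forest-plot convention).
#' @return An object of class \code{"nma_thresh"}: a data frame with one row
#'   per datum (columns \code{datum, study, contrast, estimate, ci_lo,
#'   ci_hi, int_lo, int_hi, beta_neg, beta_pos, new_opt_neg, new_opt_pos,
#'   sensitive}) carrying the fit, influence matrix, rule and \eqn{k^*} as
#'   attributes. Has \code{print} and \code{plot} (forest) methods.
#' @examples
#' res <- run_study_level(example_network(), model = "fe")
#' res
#' @export
run_study_level <- function(network, prior = NULL, model = c("fe", "re"),
                            rule = NULL, tau2 = NULL, sort = FALSE) {
  model <- match.arg(model)
  rule <- rule %||% decision_rule(network$outcome_direction)
  fit <- nma_fit(network, model, prior = prior, tau2 = tau2)
  H <- nma_influence(fit)
  est <- network$y
  se <- sqrt(diag(network$V))
  lab <- sprintf("%s (%d vs %d)", network$contrasts$study,
                 network$contrasts$treatment, network$contrasts$comparator)
  nma_thresh_table(fit, H, rule, estimates = est,
                   ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                   labels = lab, level = "study", sort = sort)
}

# Shared threshold-table builder for study- and contrast-level analyses.
# `estimates` anchors the invariant intervals.
nma_thresh_table <- function(fit, H, rule, estimates, ci_lo, ci_hi, labels,
                             level, sort = FALSE) {
  Hm <- get_H(H)
  N <- ncol(Hm)
  kstar <- optimal_treatment(fit, rule)
  rows <- lapply(seq_len(N), function(m) {
    th <- thresholds_from_solutions(
      suppressWarnings(solution_set(fit, Hm, kstar, m, rule)))
    data.frame(datum = m, label = labels[m], estimate = estimates[m],
               ci_lo = ci_lo[m], ci_hi = ci_hi[m],
               beta_neg = th$beta_neg, beta_pos = th$beta_pos,
               int_lo = estimates[m] + th$beta_neg,
               int_hi = estimates[m] + th$beta_pos,
               new_opt_neg = th$new_opt_neg, new_opt_pos = th$new_opt_pos)
  })
  out <- do.call(rbind, rows)
  out$sensitive <- out$ci_lo < out$int_lo | out$ci_hi > out$int_hi
  if (sort)
    out <- out[order(pmin(abs(out$beta_neg), abs(out$beta_pos))), ]
  structure(out, kstar = as.integer(kstar), tie = attr(kstar, "tie"),
            rule = rule, fit = fit, influence = H, level = level,
            class = c("nma_thresh", "data.frame"))
}

#' @export
print.nma_thresh <- function(x, digits = 2, ...) {
  cat(sprintf("%s-level threshold analysis: k* = %d (%s%s)\n",
              tools::toTitleCase(attr(x, "level")), attr(x, "kstar"),
              attr(x, "rule")$direction,
              if (attr(x, "rule")$mcid > 0)
                sprintf(", mcid = %g", attr(x, "rule")$mcid) else ""))
  df <- as.data.frame(x)
  df$invariant <- sprintf("(%s, %s)",
                          fmt_signed(df$int_lo), fmt_signed(df$int_hi))
  df$new_opt <- sprintf("%s / %s", vapply(df$new_opt_neg, fmt_opt, ""),
                        vapply(df$new_opt_pos, fmt_opt, ""))
  show <- df[c("datum", "label", "estimate", "invariant", "new_opt",
               "sensitive")]
  show$estimate <- round(show$estimate, digits)
  print(show, row.names = FALSE)
  invisible(x)
}

# Two-decimal formatting preserving the sign of signed zero, and "NT" for
# open interval ends.
fmt_signed <- function(v) {
  vapply(v, function(b) {
    if (!is.finite(b)) return("NT")
    s <- sprintf("%.2f", abs(b))
    if (b < 0 || (b == 0 && sign(1 / b) < 0)) paste0("-", s) else s
  }, "")
}
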