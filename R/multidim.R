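# Simultaneous bias adjustment in r >= 2 data points. Allowing r components
# of beta to be non-zero turns the threshold points into hyperplanes
# beta' w_a = 1 with [w_a]_i = 1 / u_{a,i} on the adjusted indices; their
# intersection about the origin is the decision-invariant region.

#' Threshold lines for simultaneous adjustment of two data points
#'
#' For each non-optimal treatment \eqn{a}, the set of simultaneous
#' adjustments \eqn{(\beta_{m_1}, \beta_{m_2})} at which \eqn{a} ties the
#' current optimum is the line \eqn{\beta_{m_1}/u_{a,m_1} +
#' \beta_{m_2}/u_{a,m_2} = 1}; its axis intercepts are the one-dimensional
#' thresholds. An infinite \eqn{u} on one axis gives a line parallel to that
#' axis; treatments with both solutions infinite are unreachable through the
#' chosen data and are dropped (recorded in attribute \code{dropped}).
#'
#' @param solutions_m1,solutions_m2 \code{"solution_set"} objects for the
#'   two data points (or index sets, via [common_bias_solution_set()]);
#'   must share the same \eqn{k^*}.
#' @return An object of class \code{"threshold_lines"}: data frame with
#'   columns \code{a}, \code{u1}, \code{u2}, \code{w1}, \code{w2}
#'   (coefficients of \eqn{\beta^T w = 1}).
#' @export
threshold_lines_2d <- function(solutions_m1, solutions_m2) {
  stopifnot(inherits(solutions_m1, "solution_set"),
            inherits(solutions_m2, "solution_set"))
  if (attr(solutions_m1, "kstar") != attr(solutions_m2, "kstar"))
    stop("solution sets have inconsistent optimal treatments", call. = FALSE)
  s <- merge(as.data.frame(solutions_m1), as.data.frame(solutions_m2),
             by = "a", suffixes = c("1", "2"))
  w1 <- ifelse(is.finite(s$u1), 1 / s$u1, 0)
  w2 <- ifelse(is.finite(s$u2), 1 / s$u2, 0)
  keep <- !(w1 == 0 & w2 == 0)
  if (any(s$u1 == 0, na.rm = TRUE) || any(s$u2 == 0, na.rm = TRUE))
    warning("a threshold line passes through the origin (tie at the unadjusted data)",
            call. = FALSE)
  structure(data.frame(a = s$a, u1 = s$u1, u2 = s$u2,
                       w1 = w1, w2 = w2)[keep, , drop = FALSE],
            kstar = attr(solutions_m1, "kstar"),
            m = c(attr(solutions_m1, "m")[1], attr(solutions_m2, "m")[1]),
            dropped = s$a[!keep],
            class = c("threshold_lines", "data.frame"))
}

#' Two-dimensional decision-invariant region
#'
#' Intersects the half-planes \eqn{\beta^T w_a \le 1} (each containing the
#' origin, since no adjustment changes the decision) by polygon clipping.
#' The region is convex; it is closed when threshold lines bound it in every
#' direction, otherwise open (the clipping box edges remain and the open
#' directions extend to infinity).
#'
#' @param lines a \code{"threshold_lines"} object.
#' @param bound half-width of the clipping box used to represent open
#'   regions; defaults to 10 times the largest finite threshold (at least
#'   1).
#' @return An object of class \code{"invariant_region"}: list with
#'   \code{vertices} (counter-clockwise polygon), \code{edges} (data frame
#'   with the new optimum \code{a} labelling each boundary segment, \code{NA}
#'   for box edges of an open region), \code{closed} flag, and the
#'   generating \code{lines}. Has \code{print} and \code{plot} methods.
#' @export
invariant_region_2d <- function(lines, bound = NULL) {
  stopifnot(inherits(lines, "threshold_lines"))
  ufin <- abs(c(lines$u1, lines$u2))
  bound <- bound %||% max(10 * max(ufin[is.finite(ufin)], 0), 1)
  poly <- matrix(c(-bound, -bound, bound, -bound, bound, bound, -bound,
                   bound), ncol = 2, byrow = TRUE)
  for (i in seq_len(nrow(lines)))
    poly <- clip_halfplane(poly, c(lines$w1[i], lines$w2[i]), 1)
  if (nrow(poly) < 3L)
    stop("invariant region is degenerate (origin on a threshold line)",
         call. = FALSE)
  poly <- ccw(poly)
  # label each polygon edge with the active constraint
  nb <- nrow(poly)
  mids <- (poly + poly[c(2:nb, 1L), , drop = FALSE]) / 2
  lab <- apply(mids, 1L, function(mid) {
    act <- which(abs(lines$w1 * mid[1] + lines$w2 * mid[2] - 1) < 1e-8)
    if (length(act)) lines$a[act[1L]] else NA_integer_
  })
  closed <- !any(is.na(lab)) &&
    all(abs(poly) < bound * (1 - 1e-9))
  structure(list(vertices = poly,
                 edges = data.frame(from = seq_len(nb),
                                    to = c(2:nb, 1L), a = lab),
                 closed = closed, bound = bound, lines = lines,
                 m = attr(lines, "m"), kstar = attr(lines, "kstar")),
            class = "invariant_region")
}

# Sutherland-Hodgman clip of a convex polygon to the half-plane w.x <= c.
clip_halfplane <- function(poly, w, cval) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), 0, 2)
  d <- poly %*% w - cval
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (d[i] <= 1e-12) out <- rbind(out, poly[i, ])
    if (d[i] * d[j] < -1e-24) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

ccw <- function(poly) {
  n <- nrow(poly)
  a2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  if (a2 < 0) poly[n:1, , drop = FALSE] else poly
}

# point-in-region test used by tests and plotting
in_region <- function(region, pt) {
  ln <- region$lines
  all(ln$w1 * pt[1] + ln$w2 * pt[2] <= 1 + 1e-12)
}

#' @export
print.invariant_region <- function(x, ...) {
  cat(sprintf("2-D invariant region for data (%s): %s, bounded by new optima {%s} (k* = %d)\n",
              paste(x$m, collapse = ", "),
              if (x$closed) "closed" else "open",
              paste(sort(unique(stats::na.omit(x$edges$a))), collapse = ", "),
              x$kstar))
  invisible(x)
}

#' @export
plot.invariant_region <- function(x, xlab = NULL, ylab = NULL, ...) {
  v <- x$vertices
  lim <- max(abs(v)) * 1.1
  xlab <- xlab %||% sprintf("adjustment to datum %s", x$m[1])
  ylab <- ylab %||% sprintf("adjustment to datum %s", x$m[2])
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), xlab = xlab,
                 ylab = ylab, asp = 1, ...)
  graphics::polygon(v[, 1], v[, 2], col = grDevices::adjustcolor("steelblue", 0.3),
                    border = "steelblue")
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  graphics::points(0, 0, pch = 3)
  for (i in seq_len(nrow(x$edges))) {
    a <- x$edges$a[i]
    if (is.na(a)) next
    mid <- (v[x$edges$from[i], ] + v[x$edges$to[i], ]) / 2
    graphics::text(mid[1], mid[2], bquote(tilde(k) * "*" == .(a)), cex = 0.8)
  }
  invisible(x)
}

#' Minimal simultaneous adjustments changing the decision
#'
#' For each reachable non-optimal treatment \eqn{a}, the point on its
#' threshold hyperplane closest to the origin is \eqn{\beta^{min}_a =
#' w_a / \|w_a\|^2}, the smallest overall simultaneous adjustment (in
#' Euclidean norm over the chosen data points) that makes \eqn{a} optimal.
#'
#' @param solutions list of \code{"solution_set"} objects, one per adjusted
#'   data point, all sharing \eqn{k^*}.
#' @return Data frame with one row per reachable \eqn{a}: the adjustment
#'   vector (columns \code{beta_1..beta_r}, aligned with \code{solutions})
#'   and its \code{norm}, sorted by norm ascending.
#' @export
beta_min <- function(solutions) {
  stopifnot(length(solutions) >= 1L,
            all(vapply(solutions, inherits, TRUE, "solution_set")))
  ks <- vapply(solutions, attr, 1L, "kstar")
  if (length(unique(ks)) != 1L)
    stop("solution sets have inconsistent optimal treatments", call. = FALSE)
  a_all <- solutions[[1L]]$a
  W <- vapply(solutions, function(s) {
    ifelse(is.finite(s$u), 1 / s$u, 0)
  }, numeric(length(a_all)))
  W <- matrix(W, nrow = length(a_all))
  keep <- rowSums(W != 0) > 0L
  out <- do.call(rbind, lapply(which(keep), function(i) {
    w <- W[i, ]
    bm <- w / sum(w^2)
    d <- as.data.frame(t(bm))
    names(d) <- paste0("beta_", seq_along(bm))
    d$a <- a_all[i]
    d$norm <- sqrt(sum(bm^2))
    d
  }))
  out <- out[order(out$norm), c("a", grep("^beta_", names(out), value = TRUE),
                                "norm")]
  rownames(out) <- NULL
  out
}

#' Invariant region for two simultaneous common-bias adjustments
#'
#' Combines two disjoint index sets with [common_bias_solution_set()] (one
#' shared bias per set) and intersects the resulting threshold lines.
#'
#' @inheritParams common_bias_solution_set
#' @param M1,M2 disjoint index sets.
#' @return An \code{"invariant_region"}.
#' @export
common_bias_region_2d <- function(posterior, H, kstar = NULL, M1, M2,
                                  rule = NULL) {
  if (length(intersect(M1, M2)))
    stop("index sets M1 and M2 overlap", call. = FALSE)
  s1 <- common_bias_solution_set(posterior, H, kstar, M1, rule)
  s2 <- common_bias_solution_set(posterior, H, kstar, M2, rule)
  invariant_region_2d(threshold_lines_2d(s1, s2))
}

#' Study-level invariant region front end
#'
#' Fits the model, derives the two solution sets and intersects the
#' threshold lines for simultaneous adjustment of data points \code{m1} and
#' \code{m2} (e.g. the two correlated relative effects of a three-arm
#' study).
#'
#' @inheritParams run_study_level
#' @param m1,m2 indices of the two data points to adjust.
#' @return An \code{"invariant_region"}.
#' @export
invariant_region <- function(network, m1, m2, prior = NULL,
                             model = c("fe", "re"), rule = NULL,
                             tau2 = NULL) {
  model <- match.arg(model)
  rule <- rule %||% decision_rule(network$outcome_direction)
  fit <- nma_fit(network, model, prior = prior, tau2 = tau2)
  H <- nma_influence(fit)
  ks <- optimal_treatment(fit, rule)
  s1 <- suppressWarnings(solution_set(fit, H, ks, m1, rule))
  s2 <- suppressWarnings(solution_set(fit, H, ks, m2, rule))
  invariant_region_2d(threshold_lines_2d(s1, s2))
}
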