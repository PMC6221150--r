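#' Assemble network meta-analysis data
#'
#' Builds the evidence object used by every model in the package: the stacked
#' vector of relative treatment effects \code{y}, its block-diagonal
#' within-study covariance \code{V}, and the contrast labels (treatment,
#' comparator) for each data point. Treatments are coded by the positive
#' integers \code{1..K}, with treatment 1 the network reference.
#'
#' Two input layouts are supported. In \code{format = "relative"} each row is
#' one non-baseline arm of a study, giving the estimated relative effect of
#' \code{treatment} versus \code{comparator} (the study baseline) together
#' with its \code{variance}; a study with \eqn{A} arms contributes
#' \eqn{A - 1} rows. Within-study sampling covariances for multi-arm studies
#' are supplied in columns \code{cov_with_prev1}, \code{cov_with_prev2}, ...,
#' where \code{cov_with_prevj} on a row is the covariance of that row's
#' estimate with the row \eqn{j} positions earlier in the same study; missing
#' cells default to 0 with a warning. In \code{format = "arm"} each row is one
#' arm (columns \code{study}, \code{treatment}, \code{estimate},
#' \code{variance}); relative effects are formed by differencing against the
#' study's first listed arm, the shared baseline variance inducing the
#' off-diagonal covariance terms.
#'
#' @param data a data frame in one of the two layouts above.
#' @param format \code{"relative"} (default) or \code{"arm"}.
#' @param K number of treatments; defaults to the largest code present.
#' @param outcome_direction \code{"higher_better"} or \code{"lower_better"};
#'   the default decision direction carried through to threshold analyses.
#' @return An object of class \code{"nma_data"}: a list with elements
#'   \code{K}, \code{N}, \code{y}, \code{V}, \code{contrasts} (data frame
#'   \code{study}, \code{treatment}, \code{comparator}), \code{studies}, and
#'   \code{outcome_direction}.
#' @examples
#' d <- data.frame(study = c(1, 1, 2), treatment = c(2, 3, 3),
#'                 comparator = 1, estimate = c(0.5, 0.2, 0.1),
#'                 variance = c(0.1, 0.1, 0.2),
#'                 cov_with_prev1 = c(NA, 0.05, NA))
#' net <- suppressWarnings(nma_data(d))
#' net$N
#' @seealso [build_design_matrix()], [build_re_covariance()], [nma_fit()]
#' @export
nma_data <- function(data, format = c("relative", "arm"), K = NULL,
                     outcome_direction = c("higher_better", "lower_better")) {
  format <- match.arg(format)
  outcome_direction <- match.arg(outcome_direction)
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty data table", call. = FALSE)
  if (format == "arm") {
    need <- c("study", "treatment", "estimate", "variance")
  } else {
    need <- c("study", "treatment", "comparator", "estimate", "variance")
  }
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("estimate", "variance"))
    if (!is.numeric(data[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  bad_var <- which(is.na(data$variance) | data$variance <= 0)
  if (length(bad_var))
    stop("missing or non-positive variance in rows: ",
         paste(bad_var, collapse = ", "), call. = FALSE)
  bad_est <- which(is.na(data$estimate))
  if (length(bad_est))
    stop("missing estimate in rows: ", paste(bad_est, collapse = ", "),
         call. = FALSE)
  dup <- duplicated(data[c("study", "treatment")])
  if (any(dup))
    stop("duplicate (study, treatment) rows: ",
         paste(which(dup), collapse = ", "), call. = FALSE)

  if (format == "arm") {
    data <- arm_to_relative(data)
  }

  trt <- as.integer(data$treatment)
  cmp <- as.integer(data$comparator)
  if (any(trt < 1L) || any(cmp < 1L))
    stop("treatment codes must be positive integers", call. = FALSE)
  if (any(trt == cmp))
    stop("treatment equal to comparator in rows: ",
         paste(which(trt == cmp), collapse = ", "), call. = FALSE)
  K <- as.integer(K %||% max(trt, cmp))

  study_ids <- unique(data$study)
  blocks <- vector("list", length(study_ids))
  studies <- vector("list", length(study_ids))
  ord <- order(match(data$study, study_ids))
  data <- data[ord, , drop = FALSE]
  trt <- trt[ord]; cmp <- cmp[ord]
  covcols <- grep("^cov_with_prev[0-9]+$", names(data), value = TRUE)
  row_at <- 0L
  warned_cov <- FALSE
  for (s in seq_along(study_ids)) {
    idx <- which(data$study == study_ids[s])
    nr <- length(idx)
    base <- unique(cmp[idx])
    if (length(base) != 1L)
      stop(sprintf("study %s: all rows must share one comparator (the study baseline)",
                   study_ids[s]), call. = FALSE)
    B <- diag(data$variance[idx], nr, nr)
    if (nr > 1L) {
      for (r in 2:nr) for (j in seq_len(r - 1L)) {
        col <- paste0("cov_with_prev", j)
        v <- if (col %in% covcols) data[[col]][idx[r]] else NA_real_
        if (is.na(v)) {
          v <- 0
          warned_cov <- TRUE
        }
        B[r, r - j] <- B[r - j, r] <- v
      }
    }
    blocks[[s]] <- B
    studies[[s]] <- list(id = study_ids[s],
                         treatments = c(base, trt[idx]),
                         rows = row_at + seq_len(nr))
    row_at <- row_at + nr
  }
  if (warned_cov)
    warning("missing within-study covariance cells set to 0", call. = FALSE)

  net <- structure(list(
    K = K, N = nrow(data),
    y = data$estimate,
    V = block_diag(blocks),
    contrasts = data.frame(study = data$study, treatment = trt,
                           comparator = cmp),
    studies = studies,
    outcome_direction = outcome_direction
  ), class = "nma_data")
  validate_nma_data(net)
  net
}

# Difference arm-level rows against each study's first arm. The baseline
# arm's variance appears in every element of the block (shared baseline).
arm_to_relative <- function(data) {
  out <- NULL
  for (sid in unique(data$study)) {
    rows <- data[data$study == sid, , drop = FALSE]
    if (nrow(rows) < 2L)
      stop(sprintf("study %s has fewer than 2 arms", sid), call. = FALSE)
    rel <- data.frame(
      study = sid,
      treatment = rows$treatment[-1L],
      comparator = rows$treatment[1L],
      estimate = rows$estimate[-1L] - rows$estimate[1L],
      variance = rows$variance[-1L] + rows$variance[1L]
    )
    nr <- nrow(rel)
    if (nr > 1L) for (j in seq_len(nr - 1L))
      rel[[paste0("cov_with_prev", j)]] <-
        c(rep(NA_real_, j), rep(rows$variance[1L], nr - j))
    out <- rbind_fill(out, rel)
  }
  out
}

rbind_fill <- function(a, b) {
  if (is.null(a)) return(b)
  for (col in setdiff(names(b), names(a))) a[[col]] <- NA_real_
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA_real_
  rbind(a, b[names(a)])
}

validate_nma_data <- function(net) {
  stopifnot(inherits(net, "nma_data"))
  if (net$N != sum(vapply(net$studies, function(s) length(s$treatments) - 1L,
                          integer(1))))
    stop("data point count does not match study arm counts", call. = FALSE)
  if (!is_spd(net$V))
    stop("within-study covariance V is not symmetric positive definite",
         call. = FALSE)
  unreachable <- unreachable_treatments(net)
  if (length(unreachable))
    stop("network is disconnected; treatments unreachable from 1: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  invisible(net)
}

# Treatments not linked to the reference by any chain of direct comparisons
# (includes codes <= K that appear in no study).
unreachable_treatments <- function(net) {
  g <- igraph::graph_from_edgelist(
    cbind(net$contrasts$treatment, net$contrasts$comparator),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, net$K - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(net$K)]
  which(memb != memb[1L])
}

#' Signed incidence design matrix of an NMA
#'
#' Row \eqn{i} of the design has +1 in the column of treatment \eqn{t_i} and
#' -1 in the column of comparator \eqn{c_i}; columns index treatments
#' \code{2..K} (the basic parameters \eqn{d_2, \dots, d_K}); entries for the
#' reference treatment 1 are omitted since \eqn{d_1 = 0}.
#'
#' @param network an [nma_data] object.
#' @return An \code{N x (K-1)} numeric matrix with column names \code{d2..dK}.
#' @examples
#' net <- example_network()
#' build_design_matrix(net)
#' @export
build_design_matrix <- function(network) {
  validate_nma_data(network)
  X <- matrix(0, network$N, network$K - 1L)
  colnames(X) <- paste0("d", 2:network$K)
  for (i in seq_len(network$N)) {
    t_i <- network$contrasts$treatment[i]
    c_i <- network$contrasts$comparator[i]
    if (t_i > 1L) X[i, t_i - 1L] <- 1
    if (c_i > 1L) X[i, c_i - 1L] <- -1
  }
  X
}

#' Between-study heterogeneity covariance
#'
#' The random-effects covariance \eqn{\Sigma_{\tau^2}} is block diagonal by
#' study: the block of an \eqn{(A_j - 1)}-effect study has \eqn{\tau^2} on the
#' diagonal and \eqn{0.5\tau^2} off it (the homogeneous-variance assumption
#' for multi-arm trials sharing a baseline arm); two-arm blocks are the scalar
#' \eqn{\tau^2}.
#'
#' @param network an [nma_data] object.
#' @param tau2 between-study variance, \eqn{\tau^2 \ge 0}.
#' @return An \code{N x N} positive semi-definite matrix.
#' @export
build_re_covariance <- function(network, tau2) {
  stopifnot(inherits(network, "nma_data"))
  if (!is.numeric(tau2) || length(tau2) != 1L || is.na(tau2) || tau2 < 0)
    stop("tau2 must be a single non-negative number", call. = FALSE)
  blocks <- lapply(network$studies, function(s) {
    nr <- length(s$treatments) - 1L
    tau2 * (diag(0.5, nr, nr) + matrix(0.5, nr, nr))
  })
  block_diag(blocks)
}

#' @export
print.nma_data <- function(x, ...) {
  n_multi <- sum(vapply(x$studies, function(s) length(s$treatments) > 2L,
                        logical(1)))
  cat(sprintf("Network meta-analysis data: %d treatments, %d studies (%d multi-arm), %d data points\n",
              x$K, length(x$studies), n_multi, x$N))
  cat(sprintf("Outcome direction: %s\n", x$outcome_direction))
  invisible(x)
}

#' Read or write NMA data as CSV
#'
#' @param path file path of a UTF-8 CSV with header. Relative mode columns:
#'   \code{study,treatment,comparator,estimate,variance} plus optional
#'   \code{cov_with_prev...}; arm mode: \code{study,treatment,estimate,variance}.
#' @param format passed to [nma_data()].
#' @param ... passed to [nma_data()].
#' @return \code{read_network} returns an [nma_data] object;
#'   \code{write_network} invisibly returns \code{path}. Writing always uses
#'   the relative layout, so \code{read_network(write_network(net))}
#'   reproduces \code{y} and \code{V} exactly.
#' @export
read_network <- function(path, format = c("relative", "arm"), ...) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  nma_data(df, format = match.arg(format), ...)
}

#' @rdname read_network
#' @param network an [nma_data] object to serialise.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "nma_data"))
  df <- network$contrasts
  df$estimate <- network$y
  df$variance <- diag(network$V)
  max_block <- max(vapply(network$studies,
                          function(s) length(s$treatments) - 1L, integer(1)))
  if (max_block > 1L) {
    for (j in seq_len(max_block - 1L))
      df[[paste0("cov_with_prev", j)]] <- NA_real_
    for (s in network$studies) {
      rows <- s$rows
      if (length(rows) > 1L)
        for (r in 2:length(rows)) for (j in seq_len(r - 1L))
          df[rows[r], paste0("cov_with_prev", j)] <-
            network$V[rows[r], rows[r - j]]
    }
  }
  # serialise floats at full precision so a round trip is bit identical
  for (col in grep("^(estimate|variance|cov_with_prev)", names(df)))
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        sprintf("%.17g", df[[col]]))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Small worked example network
#'
#' A four-treatment network with one three-arm study, used in documentation
#' examples and as a quick smoke test.
#' @return An [nma_data] object with \code{K = 4}, \code{N = 5}.
#' @export
example_network <- function() {
  nma_data(data.frame(
    study = c(1, 1, 2, 3, 4),
    treatment = c(2, 3, 3, 4, 4),
    comparator = c(1, 1, 1, 2, 3),
    estimate = c(0.42, 0.61, 0.35, -0.12, 0.08),
    variance = c(0.06, 0.05, 0.09, 0.11, 0.07),
    cov_with_prev1 = c(NA, 0.03, NA, NA, NA)
  ))
}
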