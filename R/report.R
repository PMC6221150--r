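#' Forest-style table of invariant intervals
#'
#' Condenses a threshold analysis into forest-plot rows: the estimate with
#' its 95\% interval (confidence interval at study level, credible interval
#' at contrast level), the decision-invariant interval with the new optimum
#' at each end, and a sensitivity flag. The flag is recomputed here from the
#' raw numbers — a row is sensitive exactly when its 95\% interval extends
#' beyond the invariant interval.
#'
#' @param results an [nma_thresh] object (or a data frame with the same
#'   columns).
#' @param sort order rows with smallest absolute thresholds first (the
#'   forest-plot convention).
#' @param filter_threshold keep only rows whose smallest absolute threshold
#'   is below this value (default \code{Inf}, keep all).
#' @return A data frame of class \code{"forest_table"} with columns
#'   \code{label}, \code{estimate}, \code{ci_lo}, \code{ci_hi},
#'   \code{int_lo}, \code{int_hi}, \code{new_opt_lo}, \code{new_opt_hi},
#'   \code{sensitive}.
#' @export
make_forest <- function(results, sort = TRUE, filter_threshold = Inf) {
  df <- as.data.frame(results)
  need <- c("label", "estimate", "ci_lo", "ci_hi", "int_lo", "int_hi",
            "beta_neg", "beta_pos", "new_opt_neg", "new_opt_pos")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("results lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (length(df$estimate) != length(df$int_lo))
    stop("misaligned inputs", call. = FALSE)
  smallest <- pmin(abs(df$beta_neg), abs(df$beta_pos))
  df <- df[smallest < filter_threshold, , drop = FALSE]
  smallest <- smallest[smallest < filter_threshold]
  if (sort && nrow(df)) df <- df[order(smallest), , drop = FALSE]
  out <- data.frame(label = df$label, estimate = df$estimate,
                    ci_lo = df$ci_lo, ci_hi = df$ci_hi,
                    int_lo = df$int_lo, int_hi = df$int_hi,
                    new_opt_lo = df$new_opt_neg, new_opt_hi = df$new_opt_pos,
                    sensitive = df$ci_lo < df$int_lo | df$ci_hi > df$int_hi,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("forest_table", "data.frame")
  out
}

#' Render a forest table to file
#'
#' @param rows a \code{"forest_table"} from [make_forest()].
#' @param path output file path.
#' @param format \code{"csv"} (default), \code{"md"} (markdown table), or a
#'   plot in \code{"png"}/\code{"svg"}.
#' @return \code{path}, invisibly.
#' @export
render_forest <- function(rows, path, format = c("csv", "md", "png", "svg")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- rows
    out$int_lo <- fmt_signed(out$int_lo)
    out$int_hi <- fmt_signed(out$int_hi)
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else if (format == "md") {
    lines <- c("| label | estimate (95% CI) | invariant interval | new optima | sensitive |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.2f (%.2f, %.2f) | (%s, %s) | %s / %s | %s |",
                       rows$label, rows$estimate, rows$ci_lo, rows$ci_hi,
                       fmt_signed(rows$int_lo), fmt_signed(rows$int_hi),
                       vapply(rows$new_opt_lo, fmt_opt, ""),
                       vapply(rows$new_opt_hi, fmt_opt, ""),
                       ifelse(rows$sensitive, "yes", "no")))
    writeLines(lines, path, useBytes = FALSE)
  } else {
    dev <- if (format == "png") function(p) grDevices::png(p, 900, 200 + 40 * nrow(rows))
           else function(p) grDevices::svg(p, 9, 2 + 0.4 * nrow(rows))
    dev(path)
    on.exit(grDevices::dev.off())
    plot_forest(rows)
  }
  invisible(path)
}

# Base-graphics forest: point + CI line + shaded invariant band per row.
plot_forest <- function(rows, main = "Decision-invariant intervals", ...) {
  n <- nrow(rows)
  if (n == 0L) {
    graphics::plot.new(); graphics::title(main); return(invisible(rows))
  }
  fin <- c(rows$ci_lo, rows$ci_hi,
           rows$int_lo[is.finite(rows$int_lo)],
           rows$int_hi[is.finite(rows$int_hi)], rows$estimate)
  xlim <- range(fin)
  pad <- 0.08 * diff(xlim)
  xlim <- xlim + c(-pad, pad)
  yy <- rev(seq_len(n))
  op <- graphics::par(mar = c(4, 10, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "effect scale", ylab = "", main = main, ...)
  graphics::axis(2, at = yy, labels = rows$label, las = 1, cex.axis = 0.8,
                 font = ifelse(rows$sensitive, 2, 1))
  for (i in seq_len(n)) {
    lo <- max(rows$int_lo[i], xlim[1] - pad)
    hi <- min(rows$int_hi[i], xlim[2] + pad)
    graphics::rect(lo, yy[i] - 0.3, hi, yy[i] + 0.3,
                   col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    if (!is.finite(rows$int_lo[i]))
      graphics::text(xlim[1], yy[i], "NT", cex = 0.7, adj = 0)
    if (!is.finite(rows$int_hi[i]))
      graphics::text(xlim[2], yy[i], "NT", cex = 0.7, adj = 1)
  }
  graphics::segments(rows$ci_lo, yy, rows$ci_hi, yy)
  graphics::points(rows$estimate, yy, pch = 21, bg = "white")
  invisible(rows)
}

#' @export
plot.nma_thresh <- function(x, sort = TRUE, filter_threshold = Inf, ...) {
  plot_forest(make_forest(x, sort = sort, filter_threshold = filter_threshold),
              ...)
}

#' @export
print.forest_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$invariant <- sprintf("(%s, %s)", fmt_signed(df$int_lo),
                          fmt_signed(df$int_hi))
  print(df[c("label", "estimate", "invariant", "sensitive")],
        row.names = FALSE)
  invisible(x)
}
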