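#' Per-item standardized mean differences between label groups
#'
#' For each item, z-scores the column (mean 0, SD 1) and computes the
#' standardized mean difference (Cohen's d with pooled SD) between the
#' cancer (label 1) and non-cancer (label 0) groups, with the usual
#' normal-approximation standard error
#' `sqrt(1/n1 + 1/n0 + d^2 / (2 (n1 + n0)))`, 95% CI, and
#' inverse-variance weight. The sign convention is fixed: positive SMD
#' means the cancer group scores higher. (The SMD is affine-invariant,
#' so the pre-standardization step does not change it; it is kept to
#' match the published display pipeline.)
#'
#' @param cohort an `sc_cohort` with both label groups non-empty.
#' @return data frame with one row per item: `item_id`, `smd`,
#'   `se_smd`, `ci_low`, `ci_high`, `weight`.
#' @export
smd_per_item <- function(cohort) {
  labels <- cohort$labels
  if (length(unique(labels)) < 2L) {
    stop("both label groups must be non-empty", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  records <- lapply(seq_len(ncol(cohort$responses)), function(j) {
    x <- as.numeric(scale(cohort$responses[, j]))
    x1 <- x[labels == 1L]
    x0 <- x[labels == 0L]
    pooled_sd <- sqrt(((n1 - 1) * stats::var(x1) +
                       (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2))
    d <- (mean(x1) - mean(x0)) / pooled_sd
    se <- sqrt(1 / n1 + 1 / n0 + d^2 / (2 * (n1 + n0)))
    data.frame(item_id = j, smd = d, se_smd = se,
               ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
               weight = 1 / se^2)
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Cochran's Q heterogeneity test
#'
#' Tests whether the per-item effects share a common value:
#' `Q = sum(w_i (d_i - d_pooled)^2)` with `d_pooled` the
#' inverse-variance-weighted mean, `df = N - 1`, and p-value from the
#' chi-square distribution.
#'
#' @param records data frame from [smd_per_item()] (needs `smd` and
#'   `weight` columns), at least 2 rows.
#' @return list with `q`, `df`, `p_value`, `pooled`.
#' @export
heterogeneity <- function(records) {
  stopifnot(nrow(records) >= 2L)
  w <- records$weight
  d <- records$smd
  pooled <- sum(w * d) / sum(w)
  q <- sum(w * (d - pooled)^2)
  df <- nrow(records) - 1L
  list(q = q, df = df,
       p_value = stats::pchisq(q, df, lower.tail = FALSE),
       pooled = pooled)
}

#' Forest summary of a cohort
#'
#' Convenience wrapper combining [smd_per_item()] and
#' [heterogeneity()].
#'
#' @param cohort an `sc_cohort`.
#' @return list of class `forest_summary` with `records` and the
#'   heterogeneity fields.
#' @export
forest_summary <- function(cohort) {
  records <- smd_per_item(cohort)
  het <- heterogeneity(records)
  structure(list(records = records, heterogeneity = het),
            class = "forest_summary")
}

#' @export
print.forest_summary <- function(x, ...) {
  r <- x$records
  cat("Per-item standardized mean differences (cancer - non-cancer):\n")
  cat("  range ", sprintf("%.2f", min(r$smd)), " to ",
      sprintf("%.2f", max(r$smd)), "; ",
      sum(r$ci_low > 0), " of ", nrow(r), " CIs exclude 0\n", sep = "")
  cat("Heterogeneity: Q = ", sprintf("%.1f", x$heterogeneity$q),
      " on ", x$heterogeneity$df, " df, p ",
      format.pval(x$heterogeneity$p_value, digits = 2), "\n", sep = "")
  invisible(x)
}

#' Export forest-plot data
#'
#' Writes the per-item records as CSV (ordered by item id) and the
#' heterogeneity summary as a JSON sidecar (`<path>.json` with `q`,
#' `df`, `p_value`). Re-exporting is idempotent.
#'
#' @param summary a `forest_summary` (or the records data frame).
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
export_forest <- function(summary, path) {
  if (inherits(summary, "forest_summary")) {
    records <- summary$records
    het <- summary$heterogeneity
  } else {
    records <- summary
    het <- NULL
  }
  records <- records[order(records$item_id), , drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE)
  if (!is.null(het)) {
    jsonlite::write_json(het[c("q", "df", "p_value", "pooled")],
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Draw a forest plot
#'
#' Base-graphics forest plot of the per-item SMDs with 95% CIs and a
#' reference line at 0.
#'
#' @param x a `forest_summary`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.forest_summary <- function(x, ...) {
  r <- x$records[order(x$records$item_id, decreasing = TRUE), ]
  ypos <- seq_len(nrow(r))
  graphics::plot(r$smd, ypos, xlim = range(c(0, r$ci_low, r$ci_high)),
                 pch = 15, yaxt = "n", xlab = "Standardized mean difference",
                 ylab = "", ...)
  graphics::axis(2, at = ypos, labels = r$item_id, las = 1, cex.axis = 0.6)
  graphics::segments(r$ci_low, ypos, r$ci_high, ypos)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
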