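#' Normality-routed clinical correlation per region
#'
#' For each differential region, tests the region values (not the clinical
#' scores) for normality with Shapiro-Wilk; when the normality p is at or
#' above `alpha_normality` the Pearson correlation with the score is
#' reported, otherwise the Spearman rank correlation — exactly one method
#' per region, the other left absent. A Bonferroni-adjusted p over regions
#' is emitted additionally.
#'
#' @param region_values data.frame or named list: per region, one value per
#'   subject (e.g. mean dALFF CV inside the cluster).
#' @param scores clinical scores, one per subject (finite).
#' @param alpha_normality Shapiro-Wilk routing threshold (default 0.05).
#' @return data.frame of class `correlation_report`: region, normality_p,
#'   method (pearson/spearman/none), coefficient, p, p_bonferroni, flagged.
#' @export
correlate_with_clinical <- function(region_values, scores,
                                    alpha_normality = 0.05) {
  region_values <- as.data.frame(region_values)
  if (!all(is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (nrow(region_values) != n)
    stop("region values (", nrow(region_values),
         " rows) must match scores (", n, ")")
  if (n < 4) stop("need at least 4 paired observations")
  rows <- lapply(names(region_values), function(rg) {
    v <- region_values[[rg]]
    if (stats::sd(v) == 0 || stats::sd(scores) == 0) {
      return(data.frame(region = rg, normality_p = NA_real_, method = "none",
                        coefficient = NA_real_, p = NA_real_, flagged = TRUE))
    }
    np <- stats::shapiro.test(v)$p.value
    if (np < alpha_normality) {
      ct <- stats::cor.test(v, scores, method = "spearman", exact = FALSE)
      data.frame(region = rg, normality_p = np, method = "spearman",
                 coefficient = unname(ct$estimate), p = ct$p.value,
                 flagged = FALSE)
    } else {
      ct <- stats::cor.test(v, scores, method = "pearson")
      data.frame(region = rg, normality_p = np, method = "pearson",
                 coefficient = unname(ct$estimate), p = ct$p.value,
                 flagged = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  class(out) <- c("correlation_report", class(out))
  out
}

#' Write a correlation report in the two-branch table layout
#'
#' CSV with one column per method and an en-dash style `-` marker in the
#' branch that was not taken for a region.
#'
#' @param report a `correlation_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(report, path) {
  fmt <- function(x, take) ifelse(take & !is.na(x), sprintf("%.4f", x), "-")
  df <- data.frame(
    region = report$region,
    normality_p = fmt(report$normality_p, TRUE),
    pearson_p = fmt(report$p, report$method == "pearson"),
    spearman_p = fmt(report$p, report$method == "spearman"),
    coefficient = fmt(report$coefficient, TRUE),
    p_bonferroni = fmt(report$p_bonferroni, TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
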