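#' Condition-level summaries of permeability reports
#'
#' Aggregates per-image reports into a per-condition mean and SEM for each
#' metric. Images are averaged within replicate (donor) first; the grand
#' mean and SEM (sample SD of replicate means / sqrt(n_replicates)) are
#' then taken across replicates, so the replicate — not the image — is the
#' unit of replication.
#'
#' @param reports Data frame with columns `condition`, `replicate` and one
#'   column per metric (e.g. from [simulate_condition_study()]).
#' @param metrics Character vector of metric column names; defaults to the
#'   four report metrics present.
#' @return Data frame: `condition`, `metric`, `mean`, `sem`,
#'   `n_replicates`, plus the replicate means in
#'   `attr(, "replicate_means")`.
#' @export
summarize_conditions <- function(reports, metrics = NULL) {
  stopifnot(all(c("condition", "replicate") %in% names(reports)))
  if (is.null(metrics))
    metrics <- intersect(c("fraction_permeable", "total_accumulation",
                           "tj_fraction", "mean_per_permeable"),
                         names(reports))
  if (nrow(reports) == 0) stop("empty report table")
  rep_means <- aggregate(reports[metrics],
                         by = list(condition = reports$condition,
                                   replicate = reports$replicate),
                         FUN = mean, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(rep_means, rep_means$condition),
    function(g) {
      data.frame(condition = g$condition[1], metric = metrics,
                 mean = vapply(metrics, function(m) mean(g[[m]]), 0),
                 sem = vapply(metrics, function(m)
                   sd(g[[m]]) / sqrt(nrow(g)), 0),
                 n_replicates = nrow(g), row.names = NULL)
    }))
  rownames(out) <- NULL
  attr(out, "replicate_means") <- rep_means
  out
}

#' Unpaired two-sample Student's t test on replicate means
#'
#' Classical pooled-variance (Student) unpaired t test, two-sided, with
#' significance stars at the conventional thresholds: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `ns` otherwise (strict inequalities).
#'
#' @param a,b Numeric vectors of replicate means (each length >= 2).
#' @param metric Optional metric name carried through to the result.
#' @return List of class `comparison_result`: `metric`, `t`, `df`, `p`,
#'   `stars`, `degenerate` (both samples constant but with different
#'   means, where the t statistic is unbounded).
#' @export
unpaired_t_test <- function(a, b, metric = NA_character_) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var < .Machine$double.eps) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      res <- list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = FALSE)
    else
      res <- list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0, degenerate = TRUE)
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, degenerate = FALSE)
  }
  res$metric <- metric
  res$stars <- significance_stars(res$p)
  class(res) <- "comparison_result"
  res
}

#' @rdname unpaired_t_test
#' @param p A p value.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %st = %.3f, df = %g, p = %.4g %s%s\n",
              if (is.na(x$metric)) "" else paste0(x$metric, ": "),
              x$t, x$df, x$p, x$stars,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' Percent change of a treated value relative to a reference
#'
#' `100 * (treated - reference) / reference`, the convention in which a
#' drop from 100 to 54 reads as -46%.
#'
#' @param reference Reference (untreated) value, > 0.
#' @param treated Treated value.
#' @return Signed percent change.
#' @export
percent_change <- function(reference, treated) {
  if (reference <= 0) stop("reference must be positive")
  100 * (treated - reference) / reference
}
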