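#' Nonparametric comparison of two methods' metric records
#'
#' For every (metric, structure) pair: when both methods yield finite values
#' on the identical set of cases, a paired two-tailed Wilcoxon signed-rank
#' test is used (exact for small samples without ties, as in
#' \code{stats::wilcox.test}; all-zero differences give p = 1). When the
#' infinite-metric discard rule has broken the pairing — a failed record on
#' either side — the comparison falls back to a two-tailed Mann-Whitney U
#' test on the finite values.
#'
#' @param records_a,records_b Record frames from \code{\link{evaluate_case}}
#'   over the same case universe.
#' @param alpha Significance threshold.
#' @return Data frame: metric, structure, n_a, n_b, test, statistic,
#'   p_value, significant.
#' @export
compare_methods <- function(records_a, records_b, alpha = 0.05) {
  key <- unique(rbind(records_a[c("metric", "structure")],
                      records_b[c("metric", "structure")]))
  out <- list()
  for (i in seq_len(nrow(key))) {
    met <- key$metric[i]; st <- key$structure[i]
    a <- records_a[records_a$metric == met & records_a$structure == st, ]
    b <- records_b[records_b$metric == met & records_b$structure == st, ]
    fa <- a[!a$failed & is.finite(a$value), ]
    fb <- b[!b$failed & is.finite(b$value), ]
    paired <- !any(a$failed) && !any(b$failed) &&
      setequal(fa$case, fb$case) && nrow(fa) == nrow(fb)
    if (paired) {
      x <- fa$value[order(fa$case)]
      y <- fb$value[order(fb$case)]
      if (length(x) < 2) next
      if (all(x == y)) {
        stat <- NA_real_; p <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                           alternative = "two.sided"))
        stat <- unname(wt$statistic); p <- wt$p.value
      }
      test <- "wilcoxon_signed_rank"
    } else {
      if (nrow(fa) < 2 || nrow(fb) < 2) next
      wt <- suppressWarnings(wilcox.test(fa$value, fb$value, paired = FALSE,
                                         alternative = "two.sided"))
      stat <- unname(wt$statistic); p <- wt$p.value
      test <- "mann_whitney_u"
    }
    out[[length(out) + 1L]] <- data.frame(
      metric = met, structure = st, n_a = nrow(fa), n_b = nrow(fb),
      test = test, statistic = stat, p_value = p,
      significant = is.finite(p) && p < alpha, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write the evaluation report
#'
#' Tidy CSV of all metric records, optional CSV of method comparisons, and
#' a summary CSV grouped by substructure class (Heart / Chambers / GVs /
#' CAs / Valves / Nodes) with mean and SD per metric over finite records.
#' The composite row aggregates two ways, both emitted: mean over all
#' per-structure means, and mean of the class means.
#'
#' @param records Record frame from \code{\link{evaluate_case}} (rbind over
#'   cases).
#' @param comparisons Optional frame from \code{\link{compare_methods}}.
#' @param out_dir Output directory.
#' @return Invisibly, the summary data frame.
#' @export
write_report <- function(records, comparisons = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
  if (!is.null(comparisons))
    write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
  fin <- records[!records$failed, ]
  fin$class <- vapply(fin$structure, structure_class, character(1))
  per_struct <- stats::aggregate(value ~ metric + structure + class,
                                 data = fin, FUN = mean)
  rows <- list()
  for (met in sort(unique(fin$metric))) {
    sub <- fin[fin$metric == met, ]
    ps <- per_struct[per_struct$metric == met, ]
    for (cl in sort(unique(sub$class)))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, class = cl,
        mean = mean(sub$value[sub$class == cl]),
        sd = sd(sub$value[sub$class == cl]), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = met, class = "Composite(structures)",
      mean = mean(ps$value), sd = sd(ps$value), stringsAsFactors = FALSE)
    clm <- stats::aggregate(value ~ class, data = ps, FUN = mean)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = met, class = "Composite(classes)",
      mean = mean(clm$value), sd = sd(clm$value), stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(summary)
}
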