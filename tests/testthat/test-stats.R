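mk_records <- function(values, metric = "dsc", structure = "WH",
                       failed = FALSE) {
  data.frame(case = sprintf("c%02d", seq_along(values)), structure = structure,
             metric = metric, value = values,
             failed = rep_len(failed, length(values)),
             stringsAsFactors = FALSE)
}

test_that("identical samples are never significantly different", {
  a <- mk_records(c(0.8, 0.85, 0.9, 0.7, 0.95, 0.88))
  cmp <- compare_methods(a, a)
  expect_identical(cmp$test, "wilcoxon_signed_rank")
  expect_false(any(cmp$significant))
  expect_equal(cmp$p_value, 1)
})

test_that("paired Wilcoxon p-values match exact sign-flip enumeration at n = 6", {
  x <- c(0.80, 0.85, 0.90, 0.70, 0.95, 0.88)
  y <- c(0.72, 0.81, 0.84, 0.73, 0.90, 0.795)  # distinct |differences|
  cmp <- compare_methods(mk_records(x), mk_records(y))
  expect_identical(cmp$test, "wilcoxon_signed_rank")
  # exact two-sided null: enumerate all 2^6 sign assignments of |d| ranks
  d <- x - y
  rk <- rank(abs(d))
  Vobs <- sum(rk[d > 0])
  n <- length(d)
  Vall <- vapply(0:(2^n - 1), function(code) {
    signs <- as.integer(intToBits(code)[1:n])
    sum(rk[signs == 1])
  }, numeric(1))
  p_exact <- min(1, 2 * min(mean(Vall <= Vobs), mean(Vall >= Vobs)))
  expect_equal(cmp$p_value, p_exact, tolerance = 1e-12)
})

test_that("a failed record on one side switches to Mann-Whitney on finite values", {
  a <- mk_records(c(5, 6, 7, 8, 9, 10), metric = "hd95")
  b <- mk_records(c(5.5, 6.5, 7.5, 8.5, 9.5, 10.5), metric = "hd95")
  a$value[3] <- NA; a$failed[3] <- TRUE  # infinite-metric discard
  cmp <- compare_methods(a, b)
  expect_identical(cmp$test, "mann_whitney_u")
  expect_identical(cmp$n_a, 5L)
  expect_identical(cmp$n_b, 6L)
  # and the p-value equals a direct unpaired two-sided test
  w <- wilcox.test(a$value[!a$failed], b$value, paired = FALSE)
  expect_equal(cmp$p_value, w$p.value, tolerance = 1e-12)
})

test_that("reports aggregate by substructure class and regenerate identically", {
  anat <- fixture_anatomy(4)
  recs <- evaluate_case(anat, anat, case = "a")
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  s1 <- write_report(recs, out_dir = d1)
  s2 <- write_report(recs, out_dir = d2)
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  # the Heart class holds WH alone, so its mean equals the WH value
  wh <- recs$value[recs$structure == "WH" & recs$metric == "dsc"]
  expect_equal(s1$mean[s1$metric == "dsc" & s1$class == "Heart"], wh)
  # composite-over-structures equals the mean of per-structure means
  ps <- aggregate(value ~ structure,
                  recs[recs$metric == "dsc" & !recs$failed, ], mean)
  expect_equal(s1$mean[s1$metric == "dsc" &
                         s1$class == "Composite(structures)"],
               mean(ps$value))
})
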