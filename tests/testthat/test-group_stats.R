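content_tab <- function(contents, case = NULL, symbols = NULL) {
  n <- length(contents)
  tab <- data.frame(
    accession = sprintf("NM_%04d", seq_len(n)),
    gene_symbol = symbols %||% sprintf("G%04d", seq_len(n)),
    chrom = rep("1", n), strand = rep("+", n),
    window_start = rep(0L, n), window_end = rep(500L, n),
    effective_length = rep(500L, n),
    snp_content = as.integer(contents), stringsAsFactors = FALSE
  )
  if (!is.null(case)) attr(tab, "case") <- case
  tab
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("content_histogram counts and cumulative transform", {
  h <- content_histogram(content_tab(c(0, 0, 1, 3)))
  expect_equal(h$counts, c(`0` = 2L, `1` = 1L, `3` = 1L))
  expect_equal(h$at_least, c(`1` = 2L, `2` = 1L, `3` = 1L))
  expect_equal(sum(h$counts), 4L)  # conservation
  e <- content_histogram(content_tab(integer(0)))
  expect_length(e$counts, 0L)
})

test_that("angular_transform hits closed-form values and rejects bad input", {
  expect_equal(angular_transform(0), 0, tolerance = 1e-12)
  expect_equal(angular_transform(1), pi, tolerance = 1e-12)
  expect_equal(angular_transform(0.25), pi / 3, tolerance = 1e-12)
  expect_error(angular_transform(1.2), "\\[0, 1\\]")
  expect_error(angular_transform(-0.1), "\\[0, 1\\]")
})

test_that("compare_proportions matches the frozen closed-form oracle", {
  # x1=10/100 vs x2=500/10000, frozen from 30-digit evaluation of
  # y_i = 2*asin(sqrt(p_i)), z = (y1-y2)/sqrt(1/n1+1/n2)
  r <- compare_proportions(10, 100, 500, 10000)
  expect_equal(r$y1, 0.6435011087932844, tolerance = 1e-12)
  expect_equal(r$y2, 0.4510268117962624, tolerance = 1e-12)
  expect_equal(r$z_stat, 1.9151908367155967, tolerance = 1e-12)
  expect_equal(r$p_value, 0.0277340853279717, tolerance = 1e-10)

  # equal proportions -> z = 0, one-sided p = 0.5
  for (xn in list(c(30, 100, 3000, 10000), c(0, 50, 0, 5000))) {
    r0 <- compare_proportions(xn[1], xn[2], xn[3], xn[4])
    expect_equal(r0$z_stat, 0)
    expect_equal(r0$p_value, 0.5)
  }

  # two-sided doubles the tail; finite-df mode is heavier-tailed
  r2 <- compare_proportions(10, 100, 500, 10000, sidedness = "two-sided")
  expect_equal(r2$p_value, 2 * r$p_value, tolerance = 1e-12)
  rt <- compare_proportions(10, 100, 500, 10000, df = NULL)
  expect_gt(rt$p_value, r$p_value)

  expect_error(compare_proportions(1, 0, 1, 10), "positive")
  expect_error(compare_proportions(11, 10, 1, 10), "0 <= x <= n")
})

test_that("threshold_sweep: identity, boundary, monotonicity, symmetry", {
  cs <- case_spec("TSS", 500)
  bg <- content_tab(rep(c(0, 1, 2, 5, 9), 20), cs)

  # group == background -> all z = 0
  sw <- threshold_sweep(bg, bg, n_range = 1:10)
  expect_true(all(sw$z_stat == 0))
  expect_true(all(sw$p_value == 0.5))

  # boundary: group all >= 10, background all 0, N = 1
  grp <- content_tab(rep(10, 40), cs)
  bg0 <- content_tab(rep(0, 400), cs)
  sw2 <- threshold_sweep(grp, bg0, n_range = 1)
  expect_equal(sw2$p1, 1)
  expect_equal(sw2$p2, 0)
  expect_equal(sw2$z_stat, pi / sqrt(1 / 40 + 1 / 400), tolerance = 1e-12)

  # p1, p2 non-increasing in N; N strictly increasing
  set.seed(3)
  g <- content_tab(rpois(150, 3), cs)
  b <- content_tab(rpois(3000, 2), cs)
  sw3 <- threshold_sweep(g, b)
  expect_true(all(diff(sw3$p1) <= 0))
  expect_true(all(diff(sw3$p2) <= 0))
  expect_true(all(diff(sw3$N) > 0))

  # swapping group and background negates z
  swap <- threshold_sweep(b, g)
  expect_equal(swap$z_stat, -sw3$z_stat, tolerance = 1e-12)

  # case mismatch is fatal
  other <- content_tab(rpois(100, 2), case_spec("CRS", 1000))
  expect_error(threshold_sweep(g, other), "different")
})

test_that("run_case_matrix covers the default matrix and counts unmatched", {
  set.seed(5)
  inst <- random_instance(n_transcripts = 40, n_snps = 1500)
  groups <- list(
    grp = c(inst$transcripts$gene_symbol[1:8], "NOSUCHGENE1", "NOSUCHGENE2")
  )
  expect_warning(
    res <- run_case_matrix(inst$transcripts, inst$snps, groups,
                           n_range = 1:5),
    "2 symbol"
  )
  expect_equal(attr(res, "unmatched")[["grp"]], 2L)
  expect_length(res$grp, 6L)
  expect_s3_class(res$grp$utrge0_TSS_500, "sweep_table")
  expect_equal(nrow(res$grp$utrgt0_CRS_1000), 5L)
})

test_that("one-sided test is calibrated under the binomial null", {
  # independent Binomial(200, .3) vs Binomial(20000, .3); rejection
  # frequency at alpha = .05 must sit near the nominal level
  set.seed(20260910)
  reps <- 2000
  x1 <- rbinom(reps, 200, 0.3)
  x2 <- rbinom(reps, 20000, 0.3)
  p <- vapply(seq_len(reps), function(i) {
    compare_proportions(x1[i], 200, x2[i], 20000)$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("test is consistent: large n with a true gap always rejects", {
  set.seed(99)
  rej <- vapply(1:50, function(i) {
    x1 <- rbinom(1, 5000, 0.33)
    x2 <- rbinom(1, 50000, 0.30)
    compare_proportions(x1, 5000, x2, 50000)$p_value < 0.05
  }, logical(1))
  expect_true(all(rej))
})
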