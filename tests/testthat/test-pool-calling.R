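test_that("the published thresholds classify the reference cases", {
  cases <- data.frame(r = c(0.15, 0.30, 0.30, 0.20, 0.30, 0.199),
                      th = c(0.50, 0.02, 0.97, 0.05, 0.50, 0.01),
                      want = c("negative", "allele1", "allele2",
                               "allele1", "both", "negative"))
  for (i in seq_len(nrow(cases)))
    expect_equal(classify_pool(cases$r[i], cases$th[i]), cases$want[i],
                 info = sprintf("R=%.3f theta=%.2f", cases$r[i],
                                cases$th[i]))
  # inclusive upper boundary too
  expect_equal(classify_pool(0.2, 0.95), "allele2")
})

test_that("classification is a total function partitioning the (R, theta) plane", {
  grid <- expand.grid(r = seq(0, 1.2, by = 0.04),
                      th = seq(0, 1, by = 0.02))
  calls <- classify_pools(data.frame(pool_id = "p", assay_id = "a",
                                     norm_r = grid$r,
                                     norm_theta = grid$th))$call
  expect_false(any(is.na(calls)))
  expect_setequal(unique(calls), c("negative", "allele1", "allele2",
                                   "both"))
  # each point lands in exactly the region its coordinates dictate
  p <- calling_params()
  expect_identical(calls == "negative", grid$r < p$r_min)
  expect_identical(calls == "allele1",
                   grid$r >= p$r_min & grid$th <= p$theta_low)
})

test_that("invalid signals are rejected naming the pool", {
  expect_error(classify_pools(data.frame(pool_id = "bad1", assay_id = "a",
                                         norm_r = NaN, norm_theta = 0.5)),
               "bad1")
  expect_error(classify_pools(data.frame(pool_id = "bad2", assay_id = "a",
                                         norm_r = 0.5, norm_theta = 1.2)),
               "bad2")
  # theta may be undefined when the signal is absent
  out <- classify_pools(data.frame(pool_id = "p", assay_id = "a",
                                   norm_r = 0.1, norm_theta = NA))
  expect_equal(out$call, "negative")
})

test_that("plate summaries conserve pool counts and match a direct tally", {
  set.seed(8)
  calls <- data.frame(pool_id = sprintf("p%03d", 1:300),
                      assay_id = sample(c("a1", "a2", "a3"), 300,
                                        replace = TRUE),
                      call = sample(c("negative", "allele1", "allele2",
                                      "both"), 300, replace = TRUE))
  ps <- plate_summary(calls)
  expect_equal(sum(ps$total), 300)
  for (i in seq_len(nrow(ps)))
    for (cl in c("negative", "allele1", "allele2", "both"))
      expect_equal(ps[[cl]][i],
                   sum(calls$assay_id == ps$assay_id[i] &
                         calls$call == cl))
  all_neg <- plate_summary(data.frame(pool_id = "p", assay_id = "a",
                                      call = "negative"))
  expect_equal(all_neg$allele1 + all_neg$allele2 + all_neg$both, 0)
})

test_that("signal tables round-trip losslessly through TSV", {
  df <- data.frame(pool_id = c("d1.p00", "d2.p05"),
                   assay_id = c("SNP001", "SNP001"),
                   norm_r = c(0.123456789012345, 1 / 3),
                   norm_theta = c(0.05, 2 / 7))
  path <- tempfile(fileext = ".tsv")
  write_tsv(df, path, seed = 42)
  back <- read_pool_signals(path)
  expect_identical(back$norm_r, df$norm_r)
  expect_identical(back$norm_theta, df$norm_theta)
  expect_identical(back$pool_id, df$pool_id)
  expect_true(any(grepl("seed: 42", readLines(path))))
})
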