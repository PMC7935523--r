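test_that("hauc accumulates accuracy above chance", {
  expect_equal(hauc(c(60, 70, 80), 3), 60)       # 10 + 20 + 30
  expect_equal(hauc(rep(50, 7)), 0)              # chance level
  expect_equal(hauc(rep(40, 5), 5), -50)         # below-chance is negative
  expect_equal(hauc(c(80, 90), 1), 30)
  expect_error(hauc(c(60, 70), 3))
  expect_error(hauc(c(60, 70), 0))
  expect_error(hauc(c(60, 105)))                 # accuracies out of range
  # trapezoidal alternative counts interval midpoints
  expect_equal(hauc(c(60, 70, 80), 3, rule = "trapezoid"), 40)
  expect_equal(hauc(c(60, 70, 80), 1, rule = "trapezoid"), 10)
})

test_that("tfi matches its defining ratio and boundary behavior", {
  expect_identical(tfi(rep(100, 20), rep(100, 20), 20), 100)
  expect_equal(tfi(c(80, 90, 95), rep(50, 3)), 0)
  expect_equal(tfi(80, 65, 1), 50)
  # identity property on random curves
  set.seed(1)
  for (i in 1:50) {
    curve <- runif(20, 51, 100)
    k <- sample(20, 1)
    expect_equal(tfi(curve, curve, k), 100)
  }
  expect_error(tfi(rep(50, 5), rep(80, 5)), class = "shapenet_undefined_tfi")
  expect_true(is.na(tfi(rep(50, 5), rep(80, 5), on_undefined = "na")))
  expect_error(tfi(rep(60, 4), rep(60, 5)))
})

test_that("tfi is monotone in transfer accuracy and bounded when dominated", {
  set.seed(2)
  for (i in 1:50) {
    k <- sample(3:20, 1)
    learning <- runif(k, 55, 100)
    transfer <- runif(k, 50, 100)
    base <- tfi(learning, transfer, k)
    e <- sample(k, 1)
    bumped <- transfer
    bumped[e] <- min(100, bumped[e] + runif(1, 0.5, 5))
    if (bumped[e] > transfer[e]) {
      expect_gt(tfi(learning, bumped, k), base)
    }
    # dominated transfer: 50 <= transfer <= learning, epochwise
    dominated <- 50 + (learning - 50) * runif(k)
    val <- tfi(learning, dominated, k)
    expect_gte(val, 0)
    expect_lte(val, 100)
  }
})

test_that("hauc and the regression match independent oracles", {
  set.seed(3)
  hauc_err <- vapply(1:1000, function(i) {
    k <- sample(1:25, 1)
    curve <- runif(k, 0, 100)
    abs(hauc(curve, k) - oracle_hauc(curve, k))
  }, 0)
  expect_lt(max(hauc_err), 1e-10)

  worst <- 0
  any_degenerate <- FALSE
  for (i in 1:1000) {
    k <- sample(3:25, 1)
    learning <- runif(k, 40, 100)
    transfer <- pmin(100, pmax(0, 0.6 * learning + rnorm(k, 0, 5)))
    got <- transfer_regression(learning, transfer)
    want <- oracle_ols(learning, transfer)
    any_degenerate <- any_degenerate || got$degenerate
    worst <- max(worst, abs(got$slope - want$slope), abs(got$r - want$r))
  }
  expect_false(any_degenerate)
  expect_lt(worst, 1e-10)
})

test_that("tfi at k = 1 reduces to the single-epoch ratio", {
  set.seed(4)
  for (i in 1:100) {
    l1 <- runif(1, 51, 100)
    t1 <- runif(1, 0, 100)
    curves <- cbind(c(l1, runif(4, 0, 100)), c(t1, runif(4, 0, 100)))
    expect_equal(tfi(curves[, 1], curves[, 2], 1),
                 (t1 - 50) / (l1 - 50) * 100, tolerance = 1e-12)
  }
})

test_that("the regression flags degenerate (constant) learning curves", {
  out <- transfer_regression(rep(100, 20), runif(20, 60, 90))
  expect_true(out$degenerate)
  expect_true(is.na(out$slope))
  expect_true(is.na(out$r))

  lin <- transfer_regression(c(60, 70, 80, 90), c(60, 70, 80, 90))
  expect_equal(lin$slope, 1)
  expect_equal(lin$r, 1)

  set.seed(5)
  learning <- runif(20, 55, 100)
  half <- transfer_regression(learning, 0.5 * learning + 1e-9 * rnorm(20))
  expect_equal(half$slope, 0.5, tolerance = 1e-6)
  expect_equal(half$r, 1, tolerance = 1e-6)

  expect_error(transfer_regression(c(60, 70), c(60, 70)))
  abs_r <- transfer_regression(learning, 100 - 0.5 * learning,
                               absolute_r = TRUE)
  expect_equal(abs_r$r, 1, tolerance = 1e-9)
  expect_equal(abs_r$slope, -0.5, tolerance = 1e-9)
})

test_that("reports assemble run summaries and round-trip through CSV", {
  mk_run <- function(id, learning, transfer) {
    structure(list(id = id, model = "oracle", epochs = length(learning),
                   split_seed = 1, train_seed = 1,
                   learning = learning, transfer = transfer),
              class = "shapenet_run")
  }
  set.seed(6)
  perfect <- mk_run("C.1", runif(20, 90, 100), NA)
  perfect$transfer <- perfect$learning
  flat <- mk_run("C.2", runif(20, 70, 100), rep(50, 20))
  ceiling_run <- mk_run("D.1", rep(100, 20), runif(20, 80, 100))
  rep_df <- build_report(list(perfect, flat, ceiling_run))
  expect_s3_class(rep_df, "transfer_report")
  expect_identical(nrow(rep_df), 3L)
  expect_equal(rep_df$tfi_k[1], 100)
  expect_equal(rep_df$tfi_k[2], 0)
  expect_identical(rep_df$experiment, c("C.1", "C.2", "D.1"))
  expect_false(any(is.na(rep_df$learning_1)))
  expect_true(rep_df$degenerate[3])
  expect_true(is.na(rep_df$slope[3]))

  path <- tempfile(fileext = ".csv")
  write_report(rep_df, path)
  back <- read_report(path)
  expect_equal(back$tfi_k, rep_df$tfi_k)
  expect_equal(back$slope, rep_df$slope)
  expect_output(print(rep_df), "N/A")  # degenerate regression prints as N/A
})
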