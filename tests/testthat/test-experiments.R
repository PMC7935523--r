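test_that("the task registry encodes the 12 tasks in 6 groups", {
  defs <- experiment_registry()
  expect_identical(length(defs), 12L)
  groups <- table(vapply(defs, `[[`, "", "group"))
  expect_identical(as.integer(groups[c("A", "B", "C", "D", "E", "F")]),
                   c(3L, 3L, 2L, 2L, 1L, 1L))
  expect_true(all(vapply(defs, `[[`, 0L, "epochs") == 20L))

  a1 <- experiment_registry("A.1")
  expect_identical(a1$learning_pair, c("square", "trapezoid"))
  expect_identical(a1$transfer_pair, c("rectangle", "trapezoid"))
  f <- experiment_registry("F")
  expect_identical(f$learning_pair, c("dot-inside-circle", "dot-outside-circle"))
  expect_identical(f$transfer_pair, c("dot-inside-square", "dot-outside-square"))
  e <- experiment_registry("E")
  expect_identical(e$learning_pair,
                   c("isosceles-triangle-outline", "disassembled-isosceles-triangle"))
  # all categories named in tasks exist in the shape registry
  cats <- unique(unlist(lapply(defs, function(d) c(d$learning_pair, d$transfer_pair))))
  expect_true(all(cats %in% category_names()))
  expect_error(experiment_registry("Z.9"))
})

test_that("the protocol yields the expected curves for oracle classifiers", {
  ds <- tiny_dataset(c("disk", "ring", "triangle-solid", "triangle-ring"),
                     n = 10)
  run <- run_experiment("C.1", function(seed) oracle_classifier(), ds,
                        epochs = 4)
  expect_s3_class(run, "shapenet_run")
  expect_identical(length(run$learning), 4L)
  expect_identical(length(run$transfer), 4L)
  expect_true(all(run$learning == 100))
  expect_true(all(run$transfer == 100))

  run0 <- run_experiment("C.1", function(seed) constant_classifier(0L), ds,
                         epochs = 4)
  expect_true(all(run0$learning == 50))  # balanced classes
  expect_true(all(run0$transfer == 50))

  s <- summary(run)
  expect_equal(s$tfi_k, 100)
  expect_true(s$degenerate)

  expect_error(run_experiment("C.1", function(seed) oracle_classifier(),
                              tiny_dataset(c("disk", "ring"), n = 4)),
               "lacks categories")
})

test_that("protocol bookkeeping isolates transfer images and balances classes", {
  def <- experiment_registry("C.1")
  ds <- tiny_dataset(c(def$learning_pair, def$transfer_pair), n = 10)
  man <- make_splits(ds$manifest, def$learning_pair, 0.85, seed = 3)
  man$split[man$category %in% setdiff(def$transfer_pair, def$learning_pair)] <-
    "transfer"
  expect_false(any(man$split == "transfer" & man$category %in% def$learning_pair))
  expect_false(any(man$split %in% c("train", "validation") &
                     man$category %in% def$transfer_pair))
  tr <- table(man$category[man$split == "train"])
  expect_true(length(unique(tr)) == 1)  # equal counts per class
  te <- table(man$category[man$split == "transfer"])
  expect_identical(as.integer(te), c(10L, 10L))
})

test_that("the protocol is deterministic given a deterministic classifier", {
  ds <- tiny_dataset(c("disk", "ring", "square-solid", "square-ring"), n = 8)
  fac <- function(seed) reference_classifier(input_size = 64, widths = c(2, 3, 4),
                                             hidden = 8, seed = seed)
  r1 <- run_experiment("C.2", fac, ds, epochs = 2, split_seed = 4, train_seed = 5)
  r2 <- run_experiment("C.2", fac, ds, epochs = 2, split_seed = 4, train_seed = 5)
  expect_identical(r1$learning, r2$learning)
  expect_identical(r1$transfer, r2$transfer)
})

test_that("run logs round-trip through CSV and reject malformed input", {
  ds <- tiny_dataset(c("disk", "ring", "triangle-solid", "triangle-ring"), n = 6)
  run <- run_experiment("C.1", function(seed) oracle_classifier(), ds, epochs = 20)
  path <- tempfile(fileext = ".csv")
  write_log(run, path)
  back <- read_log(path)
  expect_identical(back$learning, run$learning)
  expect_identical(back$transfer, run$transfer)
  expect_identical(back$id, "C.1")
  expect_identical(back$epochs, 20L)

  # externally produced minimal CSV is a valid metric-only entry point
  ext <- tempfile(fileext = ".csv")
  write.csv(data.frame(epoch = 1:3, learning_acc = c(60, 70, 80),
                       transfer_acc = c(55, 60, 65)), ext, row.names = FALSE)
  lg <- read_log(ext)
  expect_identical(lg$learning, c(60, 70, 80))

  gap <- tempfile(fileext = ".csv")
  write.csv(data.frame(epoch = c(1, 3, 4), learning_acc = 1:3 * 10 + 40,
                       transfer_acc = 1:3 * 10 + 40), gap, row.names = FALSE)
  expect_error(read_log(gap), "consecutive")

  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(epoch = 1:2, learning_acc = c(60, 120),
                       transfer_acc = c(50, 50)), bad, row.names = FALSE)
  expect_error(read_log(bad))
})
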