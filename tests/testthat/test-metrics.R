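test_that("perfect predictions give 100% everywhere", {
  r <- compute_metrics(c("a", "b", "c", "a"), c("a", "b", "c", "a"))
  expect_equal(r$accuracy, 100)
  expect_true(all(r$per_class$precision == 100))
  expect_true(all(r$per_class$recall == 100))
  expect_true(all(r$per_class$f1 == 100))
  expect_equal(sum(r$confusion), r$n_test)
})

test_that("degenerate constant predictions follow the metric definitions", {
  truth <- rep(c("c0", "c1", "c2", "c3"), each = 10L)
  pred <- rep("c0", 40L)
  r <- compute_metrics(truth, pred)
  expect_equal(r$accuracy, 25)
  pc <- r$per_class
  expect_equal(pc$recall[pc$label == "c0"], 100)
  expect_equal(pc$precision[pc$label == "c0"], 25)
  # classes never predicted: precision 0 by convention, not NaN
  expect_true(all(pc$precision[pc$label != "c0"] == 0))
  expect_true(all(pc$f1[pc$label != "c0"] == 0))
})

test_that("a worked 2x2 example matches hand arithmetic", {
  r <- compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(r$accuracy, 75)
  pc <- r$per_class
  expect_equal(pc$precision, c(100, 66.67))
  expect_equal(pc$recall, c(50, 100))
  expect_equal(pc$f1, c(66.67, 80))
  expect_equal(unname(r$confusion), rbind(c(1L, 1L), c(0L, 2L)))
})

test_that("report invariants hold: row sums, trace accuracy, F1 harmonic", {
  set.seed(42)
  for (rep in 1:20) {
    K <- sample(2:6, 1L)
    n <- sample(20:200, 1L)
    labels <- paste0("k", seq_len(K))
    truth <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    r <- compute_metrics(truth, pred, labels = labels)
    expect_equal(as.vector(rowSums(r$confusion)),
                 as.vector(table(factor(truth, labels))))
    expect_equal(r$accuracy, round(100 * sum(diag(r$confusion)) / n, 2))
    expect_equal(r$n_test, n)
  }
})

test_that("metrics agree with the brute-force oracle on random vectors", {
  set.seed(7)
  for (rep in 1:200) {
    K <- sample(2:8, 1L)
    n <- sample(5:80, 1L)
    labels <- paste0("c", seq_len(K))
    truth <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    r <- compute_metrics(truth, pred, labels = labels)
    o <- brute_force_metrics(truth, pred, labels)
    expect_identical(unname(r$confusion), unname(o$confusion + 0L))
    expect_equal(r$accuracy, o$accuracy)
    expect_equal(r$per_class$precision, o$precision)
    expect_equal(r$per_class$recall, o$recall)
    expect_equal(r$per_class$f1, o$f1)
  }
})

test_that("length mismatches and empty inputs are rejected", {
  expect_error(compute_metrics(c("a", "b"), "a"), "length")
  expect_error(compute_metrics(character(0), character(0)), "empty")
})
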