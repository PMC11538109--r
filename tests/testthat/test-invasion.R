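test_that("fixture-trained classifier separates sharp from blurred planes", {
  ts <- make_invasion_training_set(20)
  expect_gte(length(ts$images), 200)
  m <- train_invasion_classifier(ts$images, ts$labels, seed = 1)
  expect_gte(m$holdout_accuracy, 0.95)
  expect_error(
    train_invasion_classifier(ts$images[1:10], rep(TRUE, 10)),
    "label error")
})

test_that("classify_stack applies the inclusive 0.5 threshold rule", {
  zs <- zstack(replicate(4, matrix(runif(64), 8, 8), simplify = FALSE), 10, 1)
  stub <- function(img) 0.7
  call <- classify_stack(stub, zs)
  expect_equal(call$invaded, rep(TRUE, 4))

  probs <- c(0.9, 0.3, 0.6, 0.2)
  i <- 0
  stub2 <- function(img) { i <<- i + 1; probs[i] }
  call2 <- classify_stack(stub2, zs, threshold = 0.5)
  expect_equal(call2$invaded, c(TRUE, FALSE, TRUE, FALSE))

  # probability exactly at the threshold counts as invaded
  call3 <- classify_stack(function(img) 0.5, zs)
  expect_true(all(call3$invaded))

  # a threshold above 1 classifies nothing for [0,1]-valued models
  call4 <- classify_stack(function(img) 1, zs, threshold = 1.01)
  expect_equal(compute_invasion_depth(call4, 10)$depth_um, 0)
})

test_that("invasion depth is deepest invaded index times z step", {
  mk <- function(y) {
    out <- tibble::tibble(plane = seq_along(y) - 1L, probability = y,
                          invaded = y >= 0.5)
    attr(out, "z_step_um") <- 10
    out
  }
  expect_equal(compute_invasion_depth(mk(c(1, 1, 1, 0, 0)))$depth_um, 20)
  expect_equal(compute_invasion_depth(mk(rep(0, 5)))$depth_um, 0)
  expect_true(is.na(compute_invasion_depth(mk(rep(0, 5)))$deepest_invaded_index))
  # the deepest invaded plane governs, even for non-monotone calls
  expect_equal(compute_invasion_depth(mk(c(1, 0, 1, 0)))$depth_um, 20)
  # adding a deeper invaded plane strictly increases depth
  expect_gt(compute_invasion_depth(mk(c(1, 0, 1, 0, 1)))$depth_um,
            compute_invasion_depth(mk(c(1, 0, 1, 0)))$depth_um)
})

test_that("classification metrics match their formulas and flag undefined", {
  m <- classification_metrics(confusion_counts(tp = 6, tn = 42, fp = 2,
                                               fn = 0))
  expect_equal(m$value[m$metric == "accuracy"], 0.96)
  expect_equal(m$value[m$metric == "sensitivity"], 1.00)
  expect_equal(m$value[m$metric == "specificity"], 42 / 44)

  perfect <- classification_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(perfect$value, c(1, 1, 1))

  nosens <- classification_metrics(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(nosens$value[nosens$metric == "sensitivity"]))
  expect_false(nosens$defined[nosens$metric == "sensitivity"])
  expect_error(confusion_counts(0, 0, 0, 0))
})

test_that("trained classifier recovers the deepest invaded plane", {
  ts <- make_invasion_training_set(20)
  m <- train_invasion_classifier(ts$images, ts$labels, seed = 1)
  hits <- 0
  n <- 50
  for (i in seq_len(n)) {
    di <- (i %% 10)
    fx <- make_invasion_fixture(di, seed = 9000 + i)
    d <- compute_invasion_depth(classify_stack(m, fx$stack))
    got <- ifelse(is.na(d$deepest_invaded_index), -1,
                  d$deepest_invaded_index)
    hits <- hits + (abs(got - di) <= 1)
  }
  expect_gte(hits / n, 0.9)
})
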