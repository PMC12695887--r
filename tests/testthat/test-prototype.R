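test_that("classify returns the nearest prototype with a low-index tie rule", {
  m <- matrix(c(0, 0, 3, 0, 0, 4), nrow = 3, byrow = TRUE,
              dimnames = NULL)
  ps <- prototype_set(m, c("a", "b", "c"))
  got <- classify(c(3, 0), ps)
  expect_identical(got$class, "b")
  expect_equal(got$distance, 0)

  # equidistant from classes 1 and 2 -> class 1
  tie <- prototype_set(matrix(c(-1, 0, 1, 0), 2, byrow = TRUE),
                       c("first", "second"))
  expect_identical(classify(c(0, 5), tie)$class, "first")

  expect_error(classify(c(1, 2, 3), ps), "dimension|length")
})

test_that("classify agrees with exhaustive nearest-prototype search", {
  set.seed(31)
  for (r in 1:100) {
    C <- sample(2:6, 1)
    D <- sample(2:8, 1)
    m <- matrix(rnorm(C * D), C, D)
    ps <- prototype_set(m, paste0("k", seq_len(C)))
    f <- rnorm(D)
    d_all <- apply(m, 1, function(row) sqrt(sum((f - row)^2)))
    got <- classify(f, ps)
    expect_identical(got$class, paste0("k", which.min(d_all)))
    expect_equal(got$distance, min(d_all))
    # argmax of probabilities must match the nearest-prototype rule
    p <- class_probabilities(f, ps)$probabilities
    expect_identical(names(which.max(p)), got$class)
  }
})

test_that("distance-softmax probabilities are normalized and shift-invariant", {
  D <- 4
  proto_at <- function(dists) {
    # prototypes placed so the feature at the origin has given distances
    m <- matrix(0, length(dists), D)
    m[, 1] <- dists
    prototype_set(m, paste0("c", seq_along(dists)))
  }
  # all distances equal, C = 5 -> uniform
  p_eq <- class_probabilities(numeric(D), proto_at(rep(2, 5)))
  expect_equal(unname(p_eq$probabilities), rep(0.2, 5), tolerance = 1e-12)

  # closed form: C = 2, d1 = 0, d2 = ln 3 -> p1 = 0.75
  p_cf <- class_probabilities(numeric(D), proto_at(c(0, log(3))))
  expect_equal(unname(p_cf$probabilities[1]), 0.75, tolerance = 1e-12)

  # common additive shift of all distances leaves probabilities unchanged
  base <- c(0.5, 1.2, 2.0)
  p1 <- class_probabilities(numeric(D), proto_at(base))$probabilities
  p2 <- class_probabilities(numeric(D), proto_at(base + 10))$probabilities
  expect_equal(unname(p1), unname(p2), tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-12)

  expect_error(class_probabilities(c(NA, 1, 1, 1), proto_at(c(1, 2))),
               "finite")
})

test_that("cross-entropy is -log p with clamping and composition", {
  ps <- prototype_set(matrix(c(0, 0, 5, 0), 2, byrow = TRUE), c("a", "b"))
  sure <- class_probabilities(c(0, 0), ps)
  # p_a here is not 1; construct exact cases via direct pa_probs
  mk_probs <- function(p) structure(
    list(probabilities = stats::setNames(p, paste0("c", seq_along(p))),
         class_names = paste0("c", seq_along(p))), class = "pa_probs")
  expect_equal(cross_entropy(mk_probs(c(1, 0)), "c1"), 0)
  expect_equal(cross_entropy(mk_probs(rep(0.2, 5)), "c3"), log(5),
               tolerance = 1e-12)
  expect_equal(cross_entropy(mk_probs(c(0, 1)), "c1"), -log(1e-12))
  expect_error(cross_entropy(mk_probs(c(0.5, 0.5)), "zebra"), "unknown")

  # consistency with class_probabilities over random cases
  set.seed(7)
  for (r in 1:50) {
    m <- matrix(rnorm(6), 3, 2)
    psr <- prototype_set(m, c("x", "y", "z"))
    f <- rnorm(2)
    pr <- class_probabilities(f, psr)
    y <- sample(c("x", "y", "z"), 1)
    expect_equal(cross_entropy(pr, y),
                 -log(pr$probabilities[[y]]), tolerance = 1e-12)
  }
})

test_that("prototype loss is the squared distance to the true prototype", {
  ps <- prototype_set(matrix(0, 2, 3), c("a", "b"))
  expect_equal(prototype_loss(c(0, 0, 0), ps, "a"), 0)
  expect_equal(prototype_loss(c(1, 2, 2), ps, "b"), 9)

  set.seed(12)
  for (r in 1:20) {
    m <- matrix(rnorm(8), 2, 4)
    psr <- prototype_set(m, c("a", "b"))
    f <- rnorm(4)
    y <- sample(c("a", "b"), 1)
    acc <- 0
    for (j in 1:4) acc <- acc + (f[j] - m[match(y, c("a", "b")), j])^2
    expect_equal(prototype_loss(f, psr, y), acc, tolerance = 1e-12)
    expect_gte(prototype_loss(f, psr, y), 0)
  }
})

test_that("the total loss is CE + lambda * PL exactly", {
  lb <- total_loss(2.0, 5.0, 0.1)
  expect_identical(lb$total, 2.0 + 0.1 * 5.0)
  expect_identical(total_loss(1.3, 0, 0.1)$total, 1.3)
  expect_identical(total_loss(1.3, 99, 0)$total, 1.3)
  expect_error(total_loss(-1, 2, 0.1), ">= 0")
  expect_error(total_loss(1, 2, -0.5), ">= 0")
})

test_that("splitting is stratified, exhaustive and reproducible", {
  ds <- generate_dataset(default_templates("rbc_species"), 20,
                         small_config(seed = 2))
  sp <- split_dataset(ds, 0.8, stratified = TRUE, seed = 9)
  expect_length(sp$train$signals, 80)
  expect_length(sp$test$signals, 20)
  expect_identical(as.vector(sp$train$counts), rep(16L, 5))
  expect_identical(as.vector(sp$test$counts), rep(4L, 5))
  expect_setequal(sp$assignment$index, 1:100)

  sp2 <- split_dataset(ds, 0.8, stratified = TRUE, seed = 9)
  expect_identical(sp$assignment, sp2$assignment)
  sp3 <- split_dataset(ds, 0.8, stratified = TRUE, seed = 10)
  expect_false(identical(sp$assignment, sp3$assignment))

  # extreme fraction: rounding applies, union always equals the input
  two <- generate_dataset(default_templates("rbc_species")[1:2], 2,
                          small_config(seed = 1))
  hi <- split_dataset(two, 0.95, seed = 1)
  expect_identical(length(hi$train$signals) + length(hi$test$signals), 4L)

  single <- pa_dataset(list(generate_signal(tone_template("only"),
                                            small_config())),
                       class_names = c("only", "other"),
                       allow_empty = TRUE)
  expect_error(split_dataset(single, 0.8), "stratified")
  expect_error(split_dataset(ds, 1.2), "train_fraction")
})

test_that("zero-epoch training returns the untouched initialization", {
  ds <- separated_dataset(4, seed = 2)
  cfg <- tiny_model_config(seed = 7)
  clf <- train_classifier(ds, config = cfg,
                          train = train_config(epochs = 0, seed = 1))
  expect_identical(clf$model$params, init_model(cfg)$params)
  expect_identical(nrow(clf$history), 0L)
})

test_that("training separates two linearly separated classes completely", {
  ds <- separated_dataset(10, seed = 3)
  clf <- train_classifier(
    ds, config = tiny_model_config(seed = 1),
    train = train_config(epochs = 40, seed = 1))
  expect_identical(tail(clf$history$train_accuracy, 1), 1)
  # features end up strictly closer to their prototypes than at epoch 1
  expect_lt(tail(clf$history$pl, 1), clf$history$pl[1])

  # converged classifier reproduces its own training labels
  tr_idx <- clf$split$index[clf$split$set == "train"]
  pred <- predict(clf, pa_dataset(ds$signals[tr_idx],
                                  class_names = ds$class_names))
  expect_identical(pred$class,
                   vapply(ds$signals[tr_idx], `[[`, character(1), "label"))
})

test_that("predictions equal the nearest-prototype oracle on held-out data", {
  ds <- separated_dataset(8, seed = 5)
  clf <- train_classifier(
    ds, config = tiny_model_config(seed = 2),
    train = train_config(epochs = 30, seed = 2))
  te_idx <- clf$split$index[clf$split$set == "test"]
  test_ds <- pa_dataset(ds$signals[te_idx], class_names = ds$class_names)
  pred <- predict(clf, test_ds)
  # oracle: recompute features and scan all prototype distances
  X <- pafingerprint:::classifier_inputs(clf, test_ds$signals)
  feats <- pafingerprint:::cnn_forward(clf$model$params, clf$model_config, X)
  for (i in seq_len(nrow(feats))) {
    d <- apply(clf$prototypes$m, 1, function(row)
      sqrt(sum((feats[i, ] - row)^2)))
    expect_identical(pred$class[i], clf$class_names[which.min(d)])
  }
  expect_equal(unname(rowSums(pred$probabilities)), rep(1, nrow(feats)),
               tolerance = 1e-9)

  # batch predict equals per-sample predict
  for (i in seq_along(test_ds$signals)) {
    one <- predict(clf, test_ds$signals[[i]])
    expect_identical(one$class, pred$class[i])
  }
})

test_that("stronger prototype weighting tightens the learned clusters", {
  # mean final feature-to-true-prototype distance is non-increasing in
  # lambda, averaged over seeds
  mean_pl <- function(lambda, seed) {
    ds <- separated_dataset(6, seed = seed)
    clf <- train_classifier(
      ds, config = tiny_model_config(seed = seed),
      train = train_config(lambda = lambda, epochs = 25, seed = seed))
    tail(clf$history$pl, 1)
  }
  seeds <- 1:5
  avg <- vapply(c(0, 0.1, 1), function(l)
    mean(vapply(seeds, function(s) mean_pl(l, s), numeric(1))), numeric(1))
  expect_true(all(diff(avg) <= 0))
})

test_that("training a second model never mutates an existing classifier", {
  rbc <- generate_dataset(default_templates("rbc_species"), 4,
                          acquisition_config(seed = 1))
  clf_rbc <- train_classifier(rbc, config = tiny_model_config(seed = 1),
                              train = train_config(epochs = 5, seed = 1))
  digest_before <- clf_rbc$model$digest
  proto_before <- clf_rbc$prototypes$m
  wb <- generate_dataset(default_templates("whole_blood"), 4,
                         acquisition_config(seed = 2))
  clf_wb <- train_classifier(wb, config = tiny_model_config(seed = 1),
                             train = train_config(epochs = 5, seed = 2))
  expect_identical(clf_rbc$model$digest, digest_before)
  expect_identical(clf_rbc$prototypes$m, proto_before)
  expect_false(identical(clf_wb$model$digest, digest_before))
  expect_setequal(clf_wb$class_names,
                  c("pig", "sheep", "turkey", "goat", "horse"))
})

test_that("classifier archives round-trip with verified digests", {
  ds <- separated_dataset(4, seed = 8)
  clf <- train_classifier(ds, config = tiny_model_config(seed = 4),
                          train = train_config(epochs = 5, seed = 4))
  path <- tempfile(fileext = ".rds")
  save_classifier(clf, path)
  back <- load_classifier(path)
  expect_identical(back$model$digest, clf$model$digest)
  sig <- ds$signals[[1]]
  expect_identical(predict(back, sig)$class, predict(clf, sig)$class)
})
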