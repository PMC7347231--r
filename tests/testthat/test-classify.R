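test_that("degenerate augmentation is the identity and noise obeys its variance", {
  set.seed(40)
  img <- matrix(runif(10000), 100, 100)
  ident <- augment_config(clip_frac = 0, amp_range = c(1, 1),
                          noise_var = c(0, 0))
  expect_equal(augment_image(img, ident), img)

  # forced variance 0.01 -> noise sd 0.1 on the normalized scale
  half <- matrix(0.5, 100, 100)
  noisy <- augment_image(half, augment_config(clip_frac = 0,
                                              amp_range = c(1, 1),
                                              noise_var = c(0.01, 0.01)))
  expect_equal(sd(noisy - 0.5), 0.1, tolerance = 0.01)
  expect_true(all(noisy >= 0 & noisy <= 1))

  # determinism under fixed seed; input untouched
  img2 <- img
  set.seed(41); a1 <- augment_image(img, augment_config())
  set.seed(41); a2 <- augment_image(img, augment_config())
  expect_identical(a1, a2)
  expect_identical(img, img2)
})

test_that("clipping removes at most the configured fraction of occupied columns", {
  set.seed(42)
  img <- matrix(0, 50, 50)
  img[, 1:40] <- 1
  for (i in 1:20) {
    out <- augment_image(img, augment_config(amp_range = c(1, 1),
                                             noise_var = c(0, 0)))
    occ <- sum(colSums(out) > 0)
    expect_gte(occ, 36)   # at most 10% of 40 columns clipped
    expect_lte(occ, 40)
    # content is left-aligned
    expect_true(all(which(colSums(out) > 0) == seq_len(occ)))
  }
})

test_that("class weights are inverse-frequency with equal expected contribution", {
  w <- class_weights(rep(c("a", "b"), c(100, 100)))
  expect_equal(unname(w), c(1, 1))

  w2 <- class_weights(rep(c("f", "m"), c(132, 100)))
  expect_equal(unname(w2["m"] / w2["f"]), 1.32)
  counts <- c(132, 100)
  expect_equal(unname(w2["f"] * counts[1]), unname(w2["m"] * counts[2]))

  w3 <- class_weights(rep(c("x", "y"), c(1, 999)))
  expect_equal(unname(w3["x"] / w3["y"]), 999)
  expect_error(class_weights(rep("a", 5)), "2 classes")
})

test_that("leave-one-subject folds are subject-disjoint and complete", {
  subjects <- rep(paste0("m", 1:17), times = sample(5:12, 17, replace = TRUE))
  folds <- split_leave_one_subject(subjects)
  expect_equal(nrow(folds), 17)
  for (i in seq_len(nrow(folds))) {
    te <- folds$test[[i]]
    tr <- folds$train[[i]]
    expect_equal(length(te), sum(subjects == folds$subject[i]))
    expect_length(intersect(subjects[te], subjects[tr]), 0)
    expect_setequal(c(te, tr), seq_along(subjects))
  }
})

test_that("random folds partition the data exactly", {
  set.seed(43)
  folds <- split_random_folds(100, 10)
  expect_equal(nrow(folds), 10)
  sizes <- lengths(folds$test)
  expect_true(all(sizes == 10))
  all_test <- sort(unlist(folds$test))
  expect_equal(all_test, 1:100)          # coverage and disjointness
  for (i in 1:10) {
    expect_length(intersect(folds$test[[i]], folds$train[[i]]), 0)
  }
  set.seed(44); f1 <- split_random_folds(57, 10)
  set.seed(44); f2 <- split_random_folds(57, 10)
  expect_identical(f1, f2)
  expect_equal(sort(unlist(f1$test)), 1:57)
  expect_error(split_random_folds(5, 10), "n >= k")
})

test_that("label shuffling preserves the label multiset", {
  set.seed(45)
  y <- rep(c("f", "m"), c(60, 40))
  s <- shuffle_labels(y)
  expect_equal(as.vector(table(s)), as.vector(table(y)))
  expect_false(all(s == y))
  set.seed(46); s1 <- shuffle_labels(y)
  set.seed(46); s2 <- shuffle_labels(y)
  expect_identical(s1, s2)
})

test_that("ridge solves the normal equations", {
  # lambda = 0 with an invertible augmented system: exact interpolation
  x <- matrix(c(1, 3), 2, 1)
  y <- c("a", "b")
  m0 <- ridge_classify(x, y, lambda = 0, balance = FALSE)
  expect_equal(predict(m0, x), y)
  expect_equal(predict(m0, x, type = "score"), c(0, 1), tolerance = 1e-8)

  # huge lambda: weights -> 0, predictions constant
  set.seed(47)
  xb <- matrix(rnorm(40), 20, 2)
  yb <- rep(c("a", "b"), 10)
  mbig <- ridge_classify(xb, yb, lambda = 1e6, balance = FALSE)
  expect_lt(sqrt(sum(mbig$coef[-1]^2)), 1e-3)
  expect_equal(length(unique(predict(mbig, xb))), 1)

  # 3 x 2 system, lambda = 1: matches an element-wise normal-equation solve
  x3 <- matrix(c(1, 2, 3, 0, 1, 1), 3, 2)
  y3 <- c(0, 1, 1)
  m1 <- ridge_classify(x3, factor(c("a", "b", "b")), lambda = 1,
                       balance = FALSE)
  X <- cbind(1, x3)
  A <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) A[i, j] <- sum(X[, i] * X[, j])
  diag(A) <- diag(A) + 1
  b <- c(sum(X[, 1] * y3), sum(X[, 2] * y3), sum(X[, 3] * y3))
  expect_equal(unname(m1$coef), drop(solve(A, b)), tolerance = 1e-10)

  expect_error(ridge_classify(matrix(1, 4, 3), rep(c("a", "b"), 2),
                              lambda = 0), "singular")
})

test_that("SVM kernels behave as expected on canonical constructions", {
  set.seed(48)
  # linearly separable set, linear kernel: perfect training accuracy
  x <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  m <- svm_classify(x, y, kernel = "linear")
  expect_equal(mean(predict(m, x) == y), 1)

  # XOR: quadratic separates, linear cannot
  xx <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
  xx <- xx[rep(1:4, 10), ] + matrix(rnorm(80, sd = 0.05), 40, 2)
  yy <- rep(c("a", "a", "b", "b"), 10)
  mq <- svm_classify(xx, yy, kernel = "quadratic", cost = 10)
  expect_equal(mean(predict(mq, xx) == yy), 1)
  ml <- svm_classify(xx, yy, kernel = "linear", cost = 10)
  expect_lte(mean(predict(ml, xx) == yy), 0.75)

  # predictions invariant to duplicating a training point
  x2 <- rbind(x, x[1, , drop = FALSE])
  y2 <- c(y, y[1])
  m2 <- svm_classify(x2, y2, kernel = "linear", balance = FALSE)
  m1 <- svm_classify(x, y, kernel = "linear", balance = FALSE)
  grid <- matrix(rnorm(20), 10, 2)
  expect_equal(predict(m1, grid), predict(m2, grid))

  expect_error(svm_classify(x, rep("a", 40)), "2 classes")
})

test_that("evaluation reports percent correct overall and per class", {
  ev <- evaluate_predictions(rep(c("f", "m"), c(30, 30)),
                             rep(c("f", "m"), c(30, 30)))
  expect_equal(ev$overall, 100)

  truth <- rep(c("f", "m"), c(40, 20))
  pred <- truth
  pred[c(1:10, 41:45)] <- c(rep("m", 10), rep("f", 5))  # 45 of 60 correct
  ev2 <- evaluate_predictions(truth, pred)
  expect_equal(ev2$overall, 75)
  expect_equal(ev2$per_class$percent_correct,
               c(100 * 30 / 40, 100 * 15 / 20))
  expect_equal(sum(ev2$per_class$n), ev2$n_test)
  expect_error(evaluate_predictions(character(0), character(0)), "empty")

  # uniform random predictor over 17 classes: expected near 100/17
  set.seed(49)
  cls <- paste0("m", 1:17)
  tr <- sample(cls, 6000, replace = TRUE)
  pr <- sample(cls, 6000, replace = TRUE)
  expect_equal(evaluate_predictions(tr, pr)$overall, 100 / 17,
               tolerance = 1.2)

  # tidy/glance surfaces
  td <- generics::tidy(ev2)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(generics::glance(ev2)$percent_correct, 75)
})

test_that("augmented training does not hurt a simple classifier", {
  set.seed(50)
  profs <- surrogate_profiles()
  ds <- make_labeled_dataset(profs, n_per_individual = 60,
                             n_individuals_per_class = 1, snr_db = 20)
  inp <- network_input(images = ds$image)
  test <- seq(1, nrow(ds), by = 4)
  train <- setdiff(seq_len(nrow(ds)), test)
  proto <- tibble::tibble(stage = 1, epochs = 4, lr = 1e-3, dropout = 0,
                          lr_end = NA_real_)
  fit <- function(aug) {
    set.seed(51)
    net <- build_network(conv_net_spec(units = 8, fc_units = c(8, 8, 8)))
    net <- train_network(
      net, list(streams = list(inp$streams[[1]][, train]), scalars = NULL),
      ds$class[train], protocol = proto, augment = aug)
    p <- predict(net, list(streams = list(inp$streams[[1]][, test]),
                           scalars = NULL), type = "class")
    mean(p == ds$class[test])
  }
  plain <- fit(NULL)
  aug <- fit(augment_config())
  expect_gte(aug, plain - 0.15)
})

test_that("subject-disjoint validation scores below random folds when individuals carry signatures", {
  set.seed(52)
  # weak class signal plus strong individual signatures: random folds can
  # exploit the individual identity present in their training sets, a
  # subject-disjoint scheme cannot
  n_ind <- 8
  calls_per <- 50
  ind <- rep(seq_len(n_ind), each = calls_per)
  cls <- ifelse(ind <= n_ind / 2, "a", "b")
  offsets <- matrix(rnorm(n_ind * 9, sd = 1.5), n_ind, 9)
  x <- offsets[ind, ] + matrix(rnorm(length(ind) * 9), ncol = 9)
  x[, 1] <- x[, 1] + ifelse(cls == "a", 0.3, -0.3)

  proto <- tibble::tibble(stage = 1, epochs = 15, lr = 1e-3, dropout = 0,
                          lr_end = NA_real_)
  fit_acc <- function(train, test) {
    net <- build_network(dense_net_spec(units = 16))
    inp <- network_input(features = x)
    tr <- list(streams = list(), scalars = inp$scalars[, train, drop = FALSE])
    te <- list(streams = list(), scalars = inp$scalars[, test, drop = FALSE])
    net <- train_network(net, tr, cls[train], protocol = proto)
    mean(predict(net, te, type = "class") == cls[test])
  }
  loso <- split_leave_one_subject(ind)
  acc_loso <- mean(vapply(seq_len(nrow(loso)), function(i) {
    fit_acc(loso$train[[i]], loso$test[[i]])
  }, numeric(1)))
  rf <- split_random_folds(length(ind), 5)
  acc_rand <- mean(vapply(seq_len(nrow(rf)), function(i) {
    fit_acc(rf$train[[i]], rf$test[[i]])
  }, numeric(1)))
  expect_lte(acc_loso, acc_rand + 0.02)
  expect_gt(acc_rand, 0.8)
})
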