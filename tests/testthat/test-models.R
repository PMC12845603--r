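test_that("the network fits separable data and produces valid heads", {
  tbl <- random_feature_table(2, 10, seed = 1)
  tbl$rms_alpha <- NULL
  # make the two classes linearly separable along one feature
  tbl$rms_overall <- ifelse(tbl$label == "high", 3, -3) + rnorm(20, sd = 0.1)
  model <- train_model(tbl, ann_architecture(), training_config(epochs = 100, seed = 2))
  expect_identical(as.character(predict(model, tbl, type = "class")),
                   as.character(tbl$label))
  p <- predict(model, tbl, type = "prob")
  expect_true(all(p > 0 & p < 1))
  # softmax head sums to one
  tbl3 <- tbl
  tbl3$label <- factor(sample(c("a", "b", "c"), 20, TRUE))
  m3 <- train_model(tbl3, ann_architecture(output = "softmax"),
                    training_config(epochs = 10, seed = 3))
  P <- predict(m3, tbl3, type = "prob")
  expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-6)
  # head/label mismatches error
  expect_error(train_model(tbl3, ann_architecture(output = "sigmoid"),
                           training_config(seed = 1)), "two classes")
  expect_error(train_model(tbl, ann_architecture(output = "linear"),
                           training_config(seed = 1), target = "label"),
               "factor label")
})

test_that("training with permuted labels stays at chance on held-out subjects", {
  tbl <- random_feature_table(9, 60, seed = 4) # labels random: a null by design
  cv <- cross_validate(tbl, ann_architecture(),
                       training_config(epochs = 50, seed = 5), cv_plan(seed = 5))
  acc <- sum(cv$folds$accuracy * cv$folds$n_val) / sum(cv$folds$n_val)
  n <- sum(cv$folds$n_val)
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / n))
})

test_that("grouped folds keep subjects disjoint and reproducible", {
  tbl <- random_feature_table(7, 20, seed = 6)
  plan <- cv_plan("group_shuffle_by_subject", seed = 7)
  folds <- eareeg:::make_folds(tbl, plan)
  expect_length(folds, 3)
  for (k in seq_along(folds)) {
    val_sub <- unique(tbl$subject_id[folds[[k]]])
    train_sub <- unique(tbl$subject_id[-folds[[k]]])
    expect_length(intersect(val_sub, train_sub), 0)
  }
  expect_identical(folds, eareeg:::make_folds(tbl, plan))
  expect_error(eareeg:::make_folds(random_feature_table(2, 5), plan),
               "at least 3 subjects")
  cv1 <- cross_validate(tbl, "logistic", training_config(seed = 8), plan)
  cv2 <- cross_validate(tbl, "logistic", training_config(seed = 8), plan)
  expect_identical(cv1$folds, cv2$folds)
})

test_that("R-squared has its defining fixed points", {
  y <- c(1, 3, 5, 7, 9)
  expect_equal(eareeg:::r_squared(y, y), 1)
  expect_equal(eareeg:::r_squared(y, rep(mean(y), 5)), 0)
  expect_warning(r0 <- eareeg:::r_squared(rep(4, 5), y), "zero-variance")
  expect_true(is.na(r0))
})

test_that("the exact binomial tail matches closed forms", {
  expect_equal(binomial_vs_chance(10, 10, 0.5), 2^-10)
  expect_gte(binomial_vs_chance(5, 10, 0.5), 0.5)
  expect_equal(binomial_vs_chance(0, 10, 0.5), 1)
  expect_error(binomial_vs_chance(11, 10), "exceed")
  expect_error(binomial_vs_chance(5, 10, chance = 0), "chance")
})

test_that("median sigmoid outputs summarize per session cell", {
  tbl <- random_feature_table(3, 30, seed = 9)
  tbl$session <- rep(1:3, 30)
  tbl$level <- rep(c("low", "high"), 45)
  model <- train_model(tbl, ann_architecture(), training_config(epochs = 20, seed = 10))
  med <- median_sigmoid_by_session(model, tbl)
  expect_true(all(c("subject_id", "session", "level", "median_prob") %in% names(med)))
  # agrees with a direct median over the same cell
  cell <- tbl[tbl$subject_id == "s01" & tbl$session == 1 & tbl$level == "low", ]
  expect_equal(
    med$median_prob[med$subject_id == "s01" & med$session == 1 & med$level == "low"],
    median(predict(model, cell, type = "prob")))
  expect_error(median_sigmoid_by_session(
    structure(list(target = "rating", levels = NULL), class = "eeg_model"), tbl),
    "binary")
})

test_that("tidy and glance expose fold metrics and their summary", {
  tbl <- random_feature_table(4, 20, seed = 11)
  cv <- cross_validate(tbl, "logistic", training_config(seed = 12), cv_plan(seed = 12))
  td <- generics::tidy(cv)
  expect_equal(nrow(td), 3)
  gl <- generics::glance(cv)
  expect_equal(gl$accuracy_mean, mean(td$accuracy))
  expect_equal(gl$accuracy_sd, sd(td$accuracy))
})

test_that("ANN checkpoints round-trip through JSON", {
  tbl <- random_feature_table(2, 15, seed = 13)
  model <- train_model(tbl, ann_architecture(), training_config(epochs = 5, seed = 14))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  restored <- read_model(path)
  expect_equal(predict(restored, tbl, type = "prob"),
               predict(model, tbl, type = "prob"), tolerance = 1e-12)
})
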