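# Training, subject-grouped cross-validation, and evaluation metrics.

#' Cross-validation plan
#'
#' `"group_shuffle_by_subject"` shuffles subjects (seeded) and partitions them
#' into `n_folds` disjoint groups, so no subject contributes to both training
#' and validation in any fold (K-subject-out). `"kfold_within_subject"`
#' shuffles rows of a single-subject table into `n_folds` parts.
#'
#' @param scheme Splitting scheme.
#' @param n_folds Number of folds (default 3).
#' @param seed Integer seed for the shuffle.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("group_shuffle_by_subject", "kfold_within_subject"),
                    n_folds = 3, seed = 1) {
  scheme <- match.arg(scheme)
  check_count(n_folds, "n_folds", lower = 2L)
  structure(list(scheme = scheme, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)), class = "cv_plan")
}

feature_matrix <- function(table) {
  keys <- intersect(feature_roster()$key, names(table))
  extra <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                   c(keys, "block", "segment", "session", "trial", "fs",
                     "seed", "n_samples", "rating"))
  keys <- c(keys, extra[startsWith(extra, "canary")])
  if (!length(keys)) abort("no feature columns found in `table`.")
  list(X = as.matrix(table[, keys, drop = FALSE]), keys = keys)
}

target_vector <- function(table, target) {
  if (target == "label") {
    if (!"label" %in% names(table)) abort("`table` has no `label` column.")
    factor(table$label)
  } else {
    if (!"rating" %in% names(table)) abort("`table` has no `rating` column.")
    as.numeric(table$rating)
  }
}

#' Train a predictor on a labelled feature table
#'
#' Features are z-scored with statistics computed from the training table
#' only; the standardization constants travel with the model. The network is
#' trained natively ([ann_architecture()], [training_config()]); the
#' baselines wrap standard implementations (logistic regression via
#' `stats::glm`, RBF support-vector machine via `e1071::svm`, random forest
#' via `randomForest::randomForest`, linear regression via `stats::lm`).
#'
#' @param table Labelled feature table (a `label` factor for classification,
#'   or `rating` for regression).
#' @param arch An [ann_architecture()], or one of `"logistic"`, `"svm"`,
#'   `"random_forest"`, `"linear"`.
#' @param cfg A [training_config()].
#' @param target `"label"` or `"rating"` (inferred from `arch` head when an
#'   architecture object is given).
#' @return An object of class `eeg_model`.
#' @export
train_model <- function(table, arch = ann_architecture(), cfg = training_config(),
                        target = NULL) {
  if (inherits(arch, "ann_architecture")) {
    target <- target %||% if (arch$output == "linear") "rating" else "label"
  } else {
    arch <- match.arg(arch, c("logistic", "svm", "random_forest", "linear"))
    target <- target %||% if (arch == "linear") "rating" else "label"
  }
  fm <- feature_matrix(table)
  y <- target_vector(table, target)
  if (is.factor(y)) {
    y <- droplevels(y)
    if (inherits(arch, "ann_architecture")) {
      if (arch$output == "sigmoid" && nlevels(y) != 2L) {
        abort("sigmoid head requires exactly two classes.")
      }
      if (arch$output == "softmax" && nlevels(y) != arch$out_units) {
        abort("softmax head size must equal the number of classes.")
      }
      if (arch$output == "linear") abort("linear head cannot fit a factor label.")
    }
  } else if (inherits(arch, "ann_architecture") && arch$output != "linear") {
    abort("classification heads require a factor label.")
  }
  center <- colMeans(fm$X)
  scl <- apply(fm$X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(fm$X, 2, center), 2, scl, "/")

  fit <- if (inherits(arch, "ann_architecture")) {
    if (arch$input_units != ncol(Xs)) {
      arch <- ann_architecture(ncol(Xs), arch$hidden, arch$output,
                               n_classes = arch$out_units)
    }
    Y <- switch(arch$output,
      sigmoid = matrix(as.numeric(y == levels(y)[2L]), ncol = 1),
      softmax = {
        M <- matrix(0, length(y), nlevels(y))
        M[cbind(seq_along(y), as.integer(y))] <- 1
        M
      },
      linear = matrix(y, ncol = 1)
    )
    mlp_train(Xs, Y, arch, cfg)
  } else {
    with_seed(cfg$seed, switch(arch,
      logistic = suppressWarnings(
        stats::glm.fit(cbind(1, Xs), as.numeric(y == levels(y)[2L]),
                       family = stats::binomial())$coefficients),
      svm = e1071::svm(Xs, y, kernel = "radial", probability = TRUE),
      random_forest = randomForest::randomForest(Xs, y),
      linear = stats::lm.fit(cbind(1, Xs), y)$coefficients
    ))
  }
  structure(
    list(kind = if (inherits(arch, "ann_architecture")) "ann" else arch,
         arch = if (inherits(arch, "ann_architecture")) arch else NULL,
         fit = fit, center = center, scale = scl, feature_keys = fm$keys,
         levels = if (is.factor(y)) levels(y) else NULL, target = target),
    class = "eeg_model"
  )
}

#' Predict from a fitted model
#'
#' @param object An `eeg_model`.
#' @param newdata A feature table containing the model's feature columns.
#' @param type `"prob"` (positive-class probability or class-probability
#'   matrix), `"class"`, or `"response"` (numeric prediction for regression).
#' @param ... Unused.
#' @return Numeric vector, factor, or probability matrix as per `type`.
#' @export
predict.eeg_model <- function(object, newdata,
                              type = c("prob", "class", "response"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$feature_keys, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  drop_aliased <- function(co) ifelse(is.na(co), 0, co) # aliased columns
  out <- switch(object$kind,
    ann = mlp_forward(object$fit, Xs, object$arch$output)$out,
    logistic = matrix(1 / (1 + exp(-(cbind(1, Xs) %*% drop_aliased(object$fit)))),
                      ncol = 1),
    svm = {
      pr <- predict(object$fit, Xs, probability = TRUE)
      matrix(attr(pr, "probabilities")[, object$levels[2L]], ncol = 1)
    },
    random_forest = matrix(predict(object$fit, Xs, type = "prob")[, object$levels[2L]],
                           ncol = 1),
    linear = matrix(cbind(1, Xs) %*% drop_aliased(object$fit), ncol = 1)
  )
  is_reg <- object$target == "rating"
  if (type == "response" || (type == "prob" && is_reg)) return(as.numeric(out))
  if (type == "prob") {
    if (ncol(out) == 1L) return(as.numeric(out))
    colnames(out) <- object$levels
    return(out)
  }
  if (is_reg) abort("`type = \"class\"` is undefined for regression models.")
  if (ncol(out) == 1L) {
    factor(object$levels[(as.numeric(out) > 0.5) + 1L], levels = object$levels)
  } else {
    factor(object$levels[max.col(out)], levels = object$levels)
  }
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1. For binary labels the positive class
#' is the second factor level; for more classes the three rate metrics are
#' macro-averaged. Undefined ratios (empty denominator) propagate as `NA`.
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predicted labels (same levels).
#' @return A one-row tibble `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(truth, pred) {
  truth <- factor(truth); pred <- factor(pred, levels = levels(truth))
  acc <- mean(pred == truth)
  per_class <- function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    c(prec, rec, f1)
  }
  if (nlevels(truth) == 2L) {
    m <- per_class(levels(truth)[2L])
  } else {
    m <- rowMeans(vapply(levels(truth), per_class, numeric(3)), na.rm = TRUE)
  }
  tibble(accuracy = acc, precision = m[1], recall = m[2], f1 = m[3])
}

r_squared <- function(truth, pred) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    warn("zero-variance targets: R^2 undefined.")
    return(NA_real_)
  }
  1 - sum((truth - pred)^2) / ss_tot
}

make_folds <- function(table, plan) {
  if (plan$scheme == "group_shuffle_by_subject") {
    if (!"subject_id" %in% names(table)) abort("grouped CV needs `subject_id`.")
    subjects <- unique(table$subject_id)
    if (length(subjects) < plan$n_folds) {
      abort(sprintf("grouped %d-fold CV needs at least %d subjects, got %d.",
                    plan$n_folds, plan$n_folds, length(subjects)))
    }
    with_seed(plan$seed, {
      shuffled <- sample(subjects)
      groups <- split(shuffled, rep(seq_len(plan$n_folds),
                                    length.out = length(shuffled)))
      map(groups, function(g) which(table$subject_id %in% g))
    })
  } else {
    n <- nrow(table)
    if (n < plan$n_folds) abort("fewer rows than folds.")
    with_seed(plan$seed, {
      ord <- sample.int(n)
      split(ord, rep(seq_len(plan$n_folds), length.out = n))
    })
  }
}

#' Cross-validate a predictor
#'
#' Runs the plan's folds; inside each training split (and only there) class
#' balancing by downsampling is applied for classification, and feature
#' standardization/model fitting use training rows only. Returns per-fold
#' metrics, their mean and standard deviation, and the pooled out-of-fold
#' predictions.
#'
#' @inheritParams train_model
#' @param plan A [cv_plan()].
#' @param balance Balance training classes by downsampling (classification
#'   only; default `TRUE`).
#' @return An object of class `eeg_cv_result`: list with `folds` (per-fold
#'   metric tibble), `summary`, `predictions`, and `models`.
#' @export
cross_validate <- function(table, arch = ann_architecture(),
                           cfg = training_config(),
                           plan = cv_plan(), balance = TRUE) {
  stopifnot(inherits(plan, "cv_plan"))
  target <- if (inherits(arch, "ann_architecture") && arch$output == "linear")
    "rating" else if (identical(arch, "linear")) "rating" else "label"
  folds <- make_folds(table, plan)
  fold_rows <- list(); preds <- list(); models <- list()
  for (k in seq_along(folds)) {
    val_idx <- folds[[k]]
    train <- table[-val_idx, , drop = FALSE]
    val <- table[val_idx, , drop = FALSE]
    if (target == "label" && balance) {
      train <- balance_classes(train, seed = derive_seed(plan$seed, k))
    }
    model <- train_model(train, arch, cfg, target = target)
    models[[k]] <- model
    if (target == "label") {
      pred <- predict(model, val, type = "class")
      truth <- factor(val$label, levels = model$levels)
      fold_rows[[k]] <- classification_metrics(truth, pred) |>
        mutate(fold = k, n_train = nrow(train), n_val = nrow(val),
               .before = 1)
      prob <- predict(model, val, type = "prob")
      preds[[k]] <- val |>
        select(any_of(c("subject_id", "condition", "task", "level",
                        "session", "trial", "block", "segment", "rating"))) |>
        mutate(fold = k, truth = truth, pred = pred,
               prob = if (is.matrix(prob)) prob[, model$levels[length(model$levels)]]
                      else as.numeric(prob))
    } else {
      pred <- predict(model, val, type = "response")
      truth <- as.numeric(val$rating)
      fold_rows[[k]] <- tibble(fold = k, n_train = nrow(train),
                               n_val = nrow(val),
                               r2 = suppressWarnings(r_squared(truth, pred)))
      preds[[k]] <- val |>
        select(any_of(c("subject_id", "condition", "task", "level",
                        "session", "trial", "block", "segment"))) |>
        mutate(fold = k, truth = truth, pred = pred)
    }
  }
  folds_tbl <- list_rbind(fold_rows)
  metric_cols <- setdiff(names(folds_tbl), c("fold", "n_train", "n_val"))
  summary <- folds_tbl |>
    summarise(across(all_of(metric_cols),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))))
  structure(list(folds = folds_tbl, summary = summary,
                 predictions = list_rbind(preds), models = models,
                 plan = plan, target = target),
            class = "eeg_cv_result")
}

#' @export
print.eeg_cv_result <- function(x, ...) {
  cat(sprintf("<eeg_cv_result: %s, %d folds (%s)>\n",
              if (x$target == "label") "classification" else "regression",
              nrow(x$folds), x$plan$scheme))
  print(x$folds)
  invisible(x)
}

#' @rdname tidy
#' @param x An `eeg_cv_result`.
#' @param ... Unused.
#' @export
tidy.eeg_cv_result <- function(x, ...) x$folds

#' Tidy and summarize cross-validation results
#'
#' `tidy()` returns the per-fold metric table; `glance()` a one-row
#' mean +/- sd summary.
#'
#' @name tidy
NULL

#' @rdname tidy
#' @export
glance.eeg_cv_result <- function(x, ...) x$summary

#' Evaluate a regression model on a labelled table
#'
#' @param model A regression `eeg_model`.
#' @param table Feature table with a `rating` column.
#' @return A list with `r2` and a `pairs` tibble (`truth`, `pred`).
#'   Zero-variance targets yield `r2 = NA` with a warning.
#' @export
evaluate_regression <- function(model, table) {
  pred <- predict(model, table, type = "response")
  truth <- as.numeric(table$rating)
  list(r2 = r_squared(truth, pred), pairs = tibble(truth = truth, pred = pred))
}

#' Within-subject regression across all subjects
#'
#' Fits the plan's within-subject K-fold regression separately per subject
#' and reports per-fold R^2 and the best fold per subject (the study's
#' reporting convention, alongside the mean).
#'
#' @inheritParams cross_validate
#' @return A tibble with one row per (subject, fold) plus a `best` flag.
#' @export
subject_regressions <- function(table,
                                arch = ann_architecture(output = "linear"),
                                cfg = training_config(),
                                plan = cv_plan("kfold_within_subject")) {
  subjects <- unique(table$subject_id)
  rows <- map(subjects, function(s) {
    sub <- table[table$subject_id == s, , drop = FALSE]
    cv <- cross_validate(sub, arch, cfg,
                         cv_plan("kfold_within_subject", plan$n_folds,
                                 derive_seed(plan$seed, match(s, subjects))),
                         balance = FALSE)
    cv$folds |> mutate(subject_id = s, .before = 1)
  })
  list_rbind(rows) |>
    group_by(.data$subject_id) |>
    mutate(best = !is.na(.data$r2) & .data$r2 == max(.data$r2, na.rm = TRUE)) |>
    ungroup()
}

#' One-sided exact binomial test against chance
#'
#' Probability of observing `n_correct` or more successes in `n_total`
#' Bernoulli trials at success probability `chance`.
#'
#' @param n_correct Number of correct predictions.
#' @param n_total Total number of predictions.
#' @param chance Chance accuracy, in (0, 1).
#' @return The one-sided tail p-value.
#' @export
#' @examples
#' binomial_vs_chance(10, 10, 0.5) # 2^-10
binomial_vs_chance <- function(n_correct, n_total, chance = 0.5) {
  n_correct <- check_count(n_correct, "n_correct", lower = 0L)
  n_total <- check_count(n_total, "n_total", lower = 1L)
  if (n_correct > n_total) abort("`n_correct` cannot exceed `n_total`.")
  if (chance <= 0 || chance >= 1) abort("`chance` must be in (0, 1).")
  pbinom(n_correct - 1, n_total, chance, lower.tail = FALSE)
}

#' Median predicted probability per session
#'
#' For a binary classifier, the median sigmoid output over the trials of each
#' (subject, session, level) cell; the per-subject level trend underlies the
#' session-level Mann-Whitney comparisons.
#'
#' @param model A binary-classification `eeg_model`.
#' @param table Feature table with `subject_id`, `session`, `level` columns.
#' @return A tibble `subject_id`, `session`, `level`, `median_prob`, `n`.
#' @export
median_sigmoid_by_session <- function(model, table) {
  if (model$target != "label" || length(model$levels) != 2L) {
    abort("`median_sigmoid_by_session()` requires a binary classifier.")
  }
  need <- c("subject_id", "session", "level")
  if (!all(need %in% names(table))) {
    abort("`table` must have subject_id, session and level columns.")
  }
  table$..prob <- predict(model, table, type = "prob")
  out <- table |>
    group_by(.data$subject_id, .data$session, .data$level) |>
    summarise(median_prob = median(.data$..prob), n = n(), .groups = "drop")
  empty <- out$n == 0
  if (any(empty)) warn("skipping empty session cells.")
  out[!empty, , drop = FALSE]
}
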