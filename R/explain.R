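# Shapley-value feature attribution: exact enumeration, permutation
# sampling, ranking and critical-feature selection.

#' Value function for a fitted model and one instance
#'
#' Returns `val(S)`: the model output with the features in `S` fixed to the
#' instance's values and the remaining features marginalized over a
#' background sample (each background row supplies the out-of-coalition
#' values; `val(S)` is the mean output). For classifiers the pre-threshold
#' positive-class probability is explained.
#'
#' @param model An `eeg_model`.
#' @param instance A one-row feature table (or named vector) with the model's
#'   feature columns.
#' @param background A feature table of background rows used for
#'   marginalization (e.g. 100 training rows drawn with a fixed seed).
#' @return A function `val(S)` taking an integer vector of feature indices
#'   (possibly empty) and returning a scalar.
#' @export
model_value_function <- function(model, instance, background) {
  keys <- model$feature_keys
  x <- as.numeric(as.data.frame(instance)[1, keys])
  B <- as.matrix(as.data.frame(background)[, keys, drop = FALSE])
  out_col <- function(M) {
    tbl <- as_tibble(as.data.frame(M))
    names(tbl) <- keys
    p <- predict(model, tbl, type = "prob")
    if (is.matrix(p)) p[, ncol(p)] else as.numeric(p)
  }
  function(S) {
    M <- B
    if (length(S)) M[, S] <- matrix(x[S], nrow(B), length(S), byrow = TRUE)
    mean(out_col(M))
  }
}

shapley_weights <- function(p) {
  # weight for a coalition of size s (excluding j): s! (p - s - 1)! / p!
  s <- 0:(p - 1)
  exp(lgamma(s + 1) + lgamma(p - s) - lgamma(p + 1))
}

#' Exact Shapley values by subset enumeration
#'
#' Computes `phi_j = sum_S |S|! (p-|S|-1)! / p! (val(S U j) - val(S))` over
#' all `2^(p-1)` coalitions per feature. Satisfies efficiency
#' (`sum(phi) = val(full) - val(empty)`), symmetry and the dummy axiom to
#' numerical precision. Enumeration is limited to `max_features`.
#'
#' @param vf A value function `val(S)` over integer index sets (see
#'   [model_value_function()]), or anything coercible via `match.fun`.
#' @param p Number of features.
#' @param max_features Refusal threshold for the `2^p` enumeration
#'   (default 12); use [sampled_shapley()] beyond it.
#' @return A tibble with columns `feature` (index) and `phi`.
#' @export
#' @examples
#' vf <- function(S) sum(c(1, 2)[S]) # additive game
#' exact_shapley(vf, p = 2)$phi      # 1, 2
exact_shapley <- function(vf, p, max_features = 12) {
  vf <- match.fun(vf)
  p <- check_count(p, "p")
  if (p > max_features) {
    abort(sprintf("p = %d exceeds max_features = %d; use sampled_shapley().",
                  p, max_features))
  }
  n_sets <- bitwShiftL(1L, p)
  vals <- numeric(n_sets)
  for (m in 0:(n_sets - 1L)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    vals[m + 1L] <- vf(S)
  }
  w <- shapley_weights(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (m in 0:(n_sets - 1L)) {
      if (bitwAnd(m, bit) != 0L) next
      s <- sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
      phi[j] <- phi[j] + w[s + 1L] * (vals[m + bit + 1L] - vals[m + 1L])
    }
  }
  tibble(feature = seq_len(p), phi = phi)
}

#' Permutation-sampled Shapley values
#'
#' Unbiased Monte-Carlo estimator: for each sampled permutation the features
#' are inserted in order and each feature is credited with the value change
#' its insertion causes. Reports a per-feature standard error.
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of sampled permutations (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `feature`, `phi`, `se`.
#' @export
sampled_shapley <- function(vf, p, n_permutations = 200, seed = 1) {
  vf <- match.fun(vf)
  p <- check_count(p, "p")
  n_permutations <- check_count(n_permutations, "n_permutations")
  contrib <- matrix(0, n_permutations, p)
  with_seed(as.integer(seed) %% 2147483647L, {
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(p)
      prev <- vf(integer(0))
      S <- integer(0)
      for (j in perm) {
        S <- c(S, j)
        cur <- vf(S)
        contrib[r, j] <- cur - prev
        prev <- cur
      }
    }
  })
  tibble(
    feature = seq_len(p),
    phi = colMeans(contrib),
    se = apply(contrib, 2, sd) / sqrt(n_permutations)
  )
}

#' Shapley attributions for a set of instances of a fitted model
#'
#' Runs [sampled_shapley()] (or [exact_shapley()] when feasible and
#' requested) for each instance against a fixed background sample, returning
#' one row per (instance, feature) with the feature's display name attached.
#'
#' @param model An `eeg_model`.
#' @param instances Feature table of instances to explain.
#' @param background Background feature table for marginalization.
#' @param n_permutations Permutations per instance for the sampled estimator.
#' @param seed Integer seed.
#' @param exact Use exact enumeration (only for <= 12 features).
#' @return A tibble `instance`, `feature` (display name), `key`, `phi`
#'   (and `se` for the sampled estimator), plus the instance's feature value.
#' @export
explain_model <- function(model, instances, background, n_permutations = 50,
                          seed = 1, exact = FALSE) {
  keys <- model$feature_keys
  roster <- feature_roster()
  disp <- roster$name[match(keys, roster$key)]
  disp[is.na(disp)] <- keys[is.na(disp)]
  rows <- map(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, , drop = FALSE]
    vf <- model_value_function(model, inst, background)
    att <- if (exact) exact_shapley(vf, length(keys)) else
      sampled_shapley(vf, length(keys), n_permutations, derive_seed(seed, i))
    att |>
      mutate(instance = i, key = keys[.data$feature],
             value = as.numeric(as.data.frame(inst)[1, keys])[.data$feature],
             feature = disp[.data$feature])
  })
  list_rbind(rows) |>
    select(any_of(c("instance", "feature", "key", "phi", "se", "value")))
}

#' Rank features by mean absolute attribution
#'
#' Importance is the mean of `|phi|` over instances; ties are broken by the
#' stable feature order of the input.
#'
#' @param attributions Output of [explain_model()] (needs `feature`, `phi`).
#' @param top_n Optionally keep only the `top_n` most important features.
#' @return A tibble `feature`, `mean_abs_phi`, `rank`, in descending
#'   importance.
#' @export
rank_features <- function(attributions, top_n = NULL) {
  if (!nrow(attributions)) abort("no attributions to rank.")
  first_seen <- match(unique(attributions$feature), attributions$feature)
  order_key <- setNames(rank(first_seen), unique(attributions$feature))
  out <- attributions |>
    group_by(.data$feature) |>
    summarise(mean_abs_phi = mean(abs(.data$phi)), .groups = "drop") |>
    arrange(desc(.data$mean_abs_phi), order_key[.data$feature]) |>
    mutate(rank = row_number())
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Critical-feature selection across models
#'
#' Features appearing in at least `min_count` of the supplied top-10 lists
#' (one list per task/fold model) are flagged critical.
#'
#' @param top10_lists A list of character vectors of feature names.
#' @param min_count Appearance-count threshold (default 7).
#' @return A tibble `feature`, `count`, `critical`; only critical rows when
#'   any qualify.
#' @export
critical_features <- function(top10_lists, min_count = 7) {
  min_count <- check_count(min_count, "min_count")
  if (length(top10_lists) < min_count) {
    warn(sprintf("only %d lists supplied but min_count = %d; nothing can qualify.",
                 length(top10_lists), min_count))
    return(tibble(feature = character(), count = integer(), critical = logical()))
  }
  counts <- table(unlist(lapply(top10_lists, unique)))
  tibble(feature = names(counts), count = as.integer(counts)) |>
    mutate(critical = .data$count >= min_count) |>
    filter(.data$critical) |>
    arrange(desc(.data$count), .data$feature)
}

#' Beeswarm summary data
#'
#' Per-instance attribution values with the feature magnitude min-max
#' normalized to \[-1, 1\] (the usual beeswarm color scale), restricted to
#' the top-ranked features. This is a data export; plotting is done by
#' [autoplot_beeswarm()] or external tools.
#'
#' @param attributions Output of [explain_model()].
#' @param top_n Number of top features to keep (default 10).
#' @return A tibble `feature`, `instance`, `phi`, `value_norm`.
#' @export
shap_beeswarm_data <- function(attributions, top_n = 10) {
  top <- rank_features(attributions, top_n = top_n)
  attributions |>
    filter(.data$feature %in% top$feature) |>
    group_by(.data$feature) |>
    mutate(value_norm = {
      r <- range(.data$value)
      if (diff(r) == 0) rep(0, n()) else 2 * (.data$value - r[1]) / diff(r) - 1
    }) |>
    ungroup() |>
    mutate(feature = factor(.data$feature, levels = rev(top$feature))) |>
    select("feature", "instance", "phi", "value_norm")
}
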