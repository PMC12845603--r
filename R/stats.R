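# Protocol-level statistics: rank tests, Bonferroni tiers, and the
# repeated-measures ANOVA on subjective ratings.

test_result <- function(method, statistic, p_value, n, tier) {
  tibble(method = method, statistic = statistic, p_value = p_value,
         n = list(n), tier = tier)
}

#' Bonferroni-corrected per-comparison threshold
#'
#' @param alpha_family Family-wise error level.
#' @param m Number of comparisons (>= 1).
#' @return `alpha_family / m`.
#' @export
#' @examples
#' bonferroni_thresholds(0.05, 3) # 0.0167
bonferroni_thresholds <- function(alpha_family, m) {
  check_number(alpha_family, "alpha_family", lower = 1e-12, upper = 1)
  m <- check_count(m, "m")
  alpha_family / m
}

#' Significance tier under Bonferroni-corrected thresholds
#'
#' `"*"` for p below the corrected 0.05-family threshold, `"**"` below the
#' corrected 0.01-family threshold, `"ns"` otherwise (with `m = 3`
#' comparisons these are p < 0.017 and p < 0.0033).
#'
#' @param p P-value(s).
#' @param m Number of comparisons in the family.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p, m = 1) {
  t1 <- bonferroni_thresholds(0.05, m)
  t2 <- bonferroni_thresholds(0.01, m)
  ifelse(p < t2, "**", ifelse(p < t1, "*", "ns"))
}

all_tied <- function(x) length(unique(x)) == 1L

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with tie correction: the exact distribution is
#' used for small samples (combined n below 40 and no ties), the
#' continuity-corrected normal approximation otherwise. The reported
#' statistic is the U count for `sample_a` over `sample_b`.
#'
#' @param sample_a,sample_b Numeric samples (non-empty).
#' @param m Family size used for the significance tier (default 1).
#' @return A one-row result tibble (`method`, `statistic`, `p_value`, `n`,
#'   `tier`).
#' @export
mann_whitney <- function(sample_a, sample_b, m = 1) {
  if (!length(sample_a) || !length(sample_b)) abort("samples must be non-empty.")
  if (all_tied(c(sample_a, sample_b))) {
    return(test_result("mann_whitney",
                       length(sample_a) * length(sample_b) / 2, 1,
                       c(length(sample_a), length(sample_b)),
                       significance_tier(1, m)))
  }
  use_exact <- (length(sample_a) + length(sample_b) < 40) &&
    !anyDuplicated(c(sample_a, sample_b))
  ht <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = use_exact, correct = TRUE)
  )
  test_result("mann_whitney", unname(ht$statistic), ht$p.value,
              c(length(sample_a), length(sample_b)),
              significance_tier(ht$p.value, m))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided; zero differences are removed (all-zero differences give the
#' degenerate p = 1). Used per feature and task on subjects' mean feature
#' values across difficulty levels (intra-subject variation analysis).
#'
#' @param paired_a,paired_b Equal-length paired numeric samples.
#' @param m Family size for the significance tier.
#' @return A one-row result tibble.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, m = 1) {
  if (length(paired_a) != length(paired_b)) abort("paired samples must match in length.")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (!length(d)) {
    return(test_result("wilcoxon_signed_rank", 0, 1, length(paired_a),
                       significance_tier(1, m)))
  }
  use_exact <- length(d) < 50 && !anyDuplicated(abs(d))
  ht <- suppressWarnings(wilcox.test(d, exact = use_exact, correct = TRUE))
  test_result("wilcoxon_signed_rank", unname(ht$statistic), ht$p.value,
              length(d), significance_tier(ht$p.value, m))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test on a complete subject x condition table, with the
#' subject as blocking factor. No sphericity correction is applied by
#' default; `correction = "greenhouse-geisser"` rescales the degrees of
#' freedom by the Greenhouse-Geisser epsilon.
#'
#' @param data A data frame with columns `subject_id`, `condition`, and the
#'   response named by `response`.
#' @param response Response column name (default `"rating"`).
#' @param correction `"none"` or `"greenhouse-geisser"`.
#' @return A one-row tibble `statistic` (F), `df1`, `df2`, `p_value`,
#'   `epsilon`, `n_subjects`.
#' @export
repeated_measures_anova <- function(data, response = "rating",
                                    correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  need <- c("subject_id", "condition", response)
  if (!all(need %in% names(data))) {
    abort("`data` needs subject_id, condition and the response column.")
  }
  d <- data |>
    transmute(subject = factor(.data$subject_id),
              condition = factor(as.character(.data$condition)),
              y = as.numeric(.data[[response]]))
  if (nlevels(d$condition) < 2L) abort("need at least two conditions.")
  wide <- d |>
    pivot_wider(names_from = "condition", values_from = "y",
                values_fn = mean) # one value per cell; mean collapses replicates
  wide <- wide[complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 2L) abort("need at least two complete subjects.")
  long <- wide |>
    pivot_longer(-"subject", names_to = "condition", values_to = "y") |>
    mutate(condition = factor(.data$condition))
  fit <- aov(y ~ condition + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  eps <- 1
  if (correction == "greenhouse-geisser") {
    Y <- as.matrix(wide[, -1, drop = FALSE])
    k <- ncol(Y)
    Sm <- stats::cov(Y)
    Sc <- Sm - outer(rowMeans(Sm), colMeans(Sm), "+") + mean(Sm)
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
  }
  p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  tibble(statistic = Fv, df1 = df1 * eps, df2 = df2 * eps, p_value = p,
         epsilon = eps, n_subjects = nrow(wide))
}

#' Rank-biserial effect size for the Mann-Whitney comparison
#'
#' @param sample_a,sample_b Numeric samples.
#' @return `1 - 2U / (n_a n_b)`, in \[-1, 1\].
#' @export
rank_biserial <- function(sample_a, sample_b) {
  r <- rank(c(sample_a, sample_b))
  n_a <- length(sample_a); n_b <- length(sample_b)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  1 - 2 * u / (n_a * n_b)
}

#' Pairwise rating comparisons across the stress conditions
#'
#' Runs the Bonferroni-tiered Mann-Whitney test on every pair of conditions'
#' pooled block ratings, plus the repeated-measures ANOVA across all
#' conditions.
#'
#' @param study A stress-study tibble with `subject_id`, `condition`,
#'   `rating` columns (see [generate_stress_study()]).
#' @return A list with `pairwise` (tibble of tiered tests) and `anova`.
#' @export
rating_statistics <- function(study) {
  conds <- levels(factor(as.character(study$condition)))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  m <- length(pairs)
  pw <- map(pairs, function(pr) {
    a <- study$rating[as.character(study$condition) == pr[1]]
    b <- study$rating[as.character(study$condition) == pr[2]]
    mann_whitney(a, b, m = m) |>
      mutate(condition_a = pr[1], condition_b = pr[2], .before = 1)
  })
  list(pairwise = list_rbind(pw), anova = repeated_measures_anova(study))
}
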