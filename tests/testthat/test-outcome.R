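test_that("median dichotomization splits at the cohort median with ties long", {
  lab <- dichotomize(c(10, 20, 30, 40))
  expect_equal(lab$labels, c(0L, 0L, 1L, 1L))
  expect_equal(lab$threshold, 25)

  # value at the median goes to the long class
  lab2 <- dichotomize(c(10, 20, 20, 30, 40))
  expect_equal(lab2$labels[c(2, 3)], c(1L, 1L))

  set.seed(4)
  months <- sample(seq(2, 70, length.out = 32))
  lab32 <- dichotomize(months)
  expect_equal(sum(lab32$labels), 16)
  expect_equal(sum(lab32$labels == 0), 16)

  expect_error(dichotomize(rep(5, 4)), "identical")
})

test_that("logistic scorer reproduces the closed-form logistic function", {
  set.seed(21)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- as.integer(runif(40) < plogis(0.4 + 1.2 * x[, 1] - 0.8 * x[, 2]))
  scorer <- fit_logistic(x, y)
  beta <- attr(scorer, "coefficients")
  ctr <- attr(scorer, "center"); scl <- attr(scorer, "scale")
  new <- matrix(rnorm(10 * 2), 10, 2)
  z <- sweep(sweep(new, 2, ctr, "-"), 2, scl, "/")
  expect_equal(scorer(new), as.numeric(1 / (1 + exp(-(cbind(1, z) %*% beta)))))
})

test_that("logistic degenerate inputs behave as separable / intercept-only", {
  x <- matrix(c(1:10), ncol = 1)
  y <- rep(c(0L, 1L), each = 5)
  scorer <- fit_logistic(x, y)
  expect_equal(as.integer(scorer(x) >= 0.5), y)  # separable: training acc 1

  const <- matrix(1, 10, 1)
  y2 <- c(rep(1L, 3), rep(0L, 7))
  s2 <- fit_logistic(const, y2)
  expect_equal(s2(matrix(5)), 0.3, tolerance = 1e-6)  # class prevalence

  expect_error(fit_logistic(x, rep(1L, 10)), "both outcome classes")
})

test_that("empirical AUC equals brute-force pair counting", {
  expect_equal(empirical_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                             conf = FALSE)$auc, 1.0)
  expect_equal(empirical_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0),
                             conf = FALSE)$auc, 0.5)
  expect_equal(empirical_auc(c(0.9, 0.8, 0.4), c(1, 0, 1), conf = FALSE)$auc,
               0.5)

  brute_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)  # coarse grid to force ties
    expect_equal(empirical_auc(s, l, conf = FALSE)$auc, brute_auc(s, l))
    # invariance under a strictly increasing transform
    expect_equal(empirical_auc(exp(3 * s), l, conf = FALSE)$auc,
                 brute_auc(s, l))
  }
  expect_error(empirical_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("empirical AUC agrees with pROC and the bootstrap CI brackets it", {
  set.seed(12)
  s <- runif(30); l <- rbinom(30, 1, 0.5); l[1:2] <- c(0, 1)
  ours <- empirical_auc(s, l, n_boot = 500, seed = 3)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours$auc, ref)
  expect_lte(ours$ci[1], ours$auc)
  expect_gte(ours$ci[2], ours$auc)
})

test_that("exact binomial tail matches pbinom and is monotone", {
  ks <- 0:32
  ours <- vapply(ks, binomial_null_pvalue, 0, n_total = 32, chance = 0.5)
  ref <- pbinom(ks - 1, 32, 0.5, lower.tail = FALSE)
  expect_equal(ours, ref)
  expect_equal(ours[1], 1)
  expect_true(all(diff(ours) <= 0))
  expect_error(binomial_null_pvalue(5, 32, chance = 0), "chance")
  expect_error(binomial_null_pvalue(5, 32, chance = 1.2), "chance")
  expect_error(binomial_null_pvalue(33, 32), "n_correct")
})

test_that("confusion metrics and relative improvement match hand arithmetic", {
  m <- confusion_metrics(confusion_matrix(1, 0, 0, 1))
  expect_equal(m$accuracy, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)

  m2 <- confusion_metrics(confusion_matrix(3, 0, 2, 0))
  expect_equal(m2$accuracy, 0.6)
  expect_true(is.na(m2$npv))

  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_equal(relative_improvement(0.6, 0.4), 50)
  expect_error(relative_improvement(0.5, 0), "> 0")
})

test_that("pearson correlation matches the covariance-formula oracle", {
  expect_equal(pearson_correlation(1:10, 1:10), 1.0)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1.0)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), oracle)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("SFFS selects the lone feature and dedups duplicated informative ones", {
  set.seed(17)
  x1 <- matrix(rnorm(20), ncol = 1)
  y <- rep(c(0L, 1L), 10)
  expect_equal(sffs_select(x1, y, max_subset = 1), 1L)

  co <- generate_cohort(cohort_config(seed = 2))
  x <- as.matrix(co$features[, -1])
  lab <- co$outcomes$true_class
  dup <- cbind(x[, 1], x[, 1], x[, 2:4])
  sel <- sffs_select(dup, lab, max_subset = 3)
  expect_equal(sum(sel %in% c(1L, 2L)), 1L)
  expect_true(1L %in% sel)  # tie broken toward the lower index
})

test_that("leave-one-case-out folds never see their held-out case", {
  co <- generate_cohort(cohort_config(n_cases = 16, n_noise = 3, seed = 9))
  x <- as.matrix(co$features[, -1])
  lab <- co$outcomes$true_class
  cv <- loco_evaluate(x, lab, max_subset = 3, seed = 7, n_boot = 200)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  expect_equal(sum(cv$confusion), 16)
  expect_true(all(cv$selection_frequency <= 16))
  # refit fold 5 from scratch on the other 15 cases only
  i <- 5L
  sel <- sffs_select(x[-i, ], lab[-i], max_subset = 3)
  expect_equal(sel, cv$fold_subsets[[i]])
  scorer <- fit_logistic(x[-i, sel, drop = FALSE], lab[-i])
  expect_equal(scorer(x[i, sel, drop = FALSE]), cv$scores[i])
})
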