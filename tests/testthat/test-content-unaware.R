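# Toy feature sets for exercising the LOOCV machinery quickly.
toy_separable <- function(n_per = 5, p = 8, gap = 50, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p) + gap, n_per))
  labels <- factor(rep(c("attended_odd", "attended_even"), each = n_per),
                   levels = c("attended_odd", "attended_even"))
  list(x = x, labels = labels)
}

small_grid <- svm_config(c_grid = c(0.01, 1, 100))

test_that("svm_config validates its grid and split fraction", {
  expect_equal(length(svm_config()$c_grid), 13L)
  expect_equal(svm_config()$c_grid[1], 1e-2)
  expect_equal(svm_config()$c_grid[13], 1e10)
  expect_error(svm_config(c_grid = c(1, 1)),
               class = "blinkengage_validation_error")
  expect_error(svm_config(inner_train_frac = 1),
               class = "blinkengage_validation_error")
})

test_that("the linear decision shortcut matches e1071's predict everywhere", {
  set.seed(99)
  for (i in 1:80) {
    n <- sample(4:14, 1); p <- sample(2:12, 1)
    x <- matrix(rnorm(n * p), n)
    n1 <- sample(2:(n - 2), 1)
    y <- factor(sample(rep(c("attended_odd", "attended_even"),
                           c(n1, n - n1))),
                levels = c("attended_odd", "attended_even"))
    if (i %% 2 == 0) levels(y) <- rev(levels(y))
    fit <- e1071::svm(x, y, kernel = "linear", cost = 10^sample(-2:4, 1),
                      scale = FALSE, fitted = FALSE,
                      na.action = stats::na.pass)
    expect_identical(
      as.character(blinkengage:::predict_svm(fit, x)),
      as.character(predict(fit, x, na.action = stats::na.pass)))
  }
})

test_that("perfectly separable parity groups classify at 100%", {
  toy <- toy_separable()
  rep <- loocv_classify(toy$x, toy$labels, small_grid, seed = 3)
  expect_equal(rep$percent_correct, 100)
  expect_equal(rep$n_correct, 10L)
  expect_error(loocv_classify(toy$x[1:3, ], factor(c("a", "a", "b")),
                              small_grid),
               class = "blinkengage_validation_error")
})

test_that("loocv predictions match a manually computed fold (no leakage)", {
  toy <- toy_separable(n_per = 4, gap = 3, seed = 8)
  cfg <- svm_config(c_grid = 1)     # single C: no inner split involved
  rep <- loocv_classify(toy$x, toy$labels, cfg, seed = 5)
  i <- 1
  xtr <- toy$x[-i, ]; ytr <- toy$labels[-i]
  mu <- colMeans(xtr); s <- apply(xtr, 2, sd); s[s == 0] <- 1
  fit <- e1071::svm(scale(xtr, mu, s), ytr, kernel = "linear", cost = 1,
                    scale = FALSE)
  pred <- predict(fit, scale(toy$x[i, , drop = FALSE], mu, s))
  expect_equal(as.character(rep$predicted[i]), as.character(pred))

  # the left-out row cannot influence the fold's standardization: with an
  # extreme test row, the loocv prediction must still equal the manual
  # computation whose center/scale come from the training rows only
  x2 <- toy$x; x2[i, ] <- x2[i, ] * 1e6
  rep2 <- loocv_classify(x2, toy$labels, cfg, seed = 5)
  pred2 <- predict(fit, scale(x2[i, , drop = FALSE], mu, s))
  expect_equal(as.character(rep2$predicted[i]), as.character(pred2))
})

test_that("loocv is reproducible and ties go to the smallest C", {
  toy <- toy_separable(seed = 6)
  a <- loocv_classify(toy$x, toy$labels, small_grid, seed = 11)
  b <- loocv_classify(toy$x, toy$labels, small_grid, seed = 11)
  expect_identical(a$predicted, b$predicted)
  expect_identical(a$chosen_c, b$chosen_c)
  # widely separated data: every adequately regularized C classifies the
  # inner test perfectly -> ties, broken towards the smallest C
  tie_grid <- svm_config(c_grid = c(1, 100, 1e4))
  tied <- loocv_classify(toy$x, toy$labels, tie_grid, seed = 11)
  expect_true(all(tied$chosen_c == 1))
})

test_that("label-shuffled data stays at chance level", {
  set.seed(21)
  accs <- numeric(40)
  x <- matrix(rnorm(12 * 10), 12)
  for (s in 1:40) {
    set.seed(1000 + s)
    labels <- factor(sample(rep(c("attended_odd", "attended_even"),
                                c(7, 5))),
                     levels = c("attended_odd", "attended_even"))
    x_s <- matrix(rnorm(12 * 10), 12)
    accs[s] <- loocv_classify(x_s, labels, small_grid,
                              seed = s)$percent_correct
  }
  majority <- 100 * 7 / 12
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - majority), 3 * se + 10)
  expect_lt(mean(accs), 75)   # far from the separable regime
})

test_that("permutation test p-values follow the add-one convention", {
  toy <- toy_separable(seed = 2)
  pt <- permutation_test(toy$x, toy$labels, small_grid, n_perm = 100,
                         seed = 4)
  # separable observed accuracy tops every permuted accuracy
  expect_equal(pt$observed$percent_correct, 100)
  expect_equal(pt$p_value, (1 + sum(pt$null_percent_correct >= 100)) / 101)
  expect_lte(pt$p_value, 0.05)
  expect_true(pt$cutoff_95 %in% pt$null_percent_correct)

  # an observed value below the whole null gets p near 1
  fake_obs <- pt$observed
  fake_obs$percent_correct <- -1
  pt2 <- permutation_test(toy$x, toy$labels, small_grid, n_perm = 100,
                          seed = 4, observed = fake_obs)
  expect_equal(pt2$p_value, 1)

  # reproducibility of the null distribution
  pt3 <- permutation_test(toy$x, toy$labels, small_grid, n_perm = 100,
                          seed = 4)
  expect_identical(pt$null_percent_correct, pt3$null_percent_correct)
  # permuted labels carry no skill: the null mean cannot exceed the
  # majority-class rate (leave-one-out nulls sit at or below chance
  # because leaving a sample out tilts the training majority against it)
  majority <- 100 * 5 / 10
  expect_lt(mean(pt$null_percent_correct),
            majority + 3 * sd(pt$null_percent_correct) / sqrt(100))
  expect_gt(mean(pt$null_percent_correct), 10)
})

test_that("the simulated cohort is classified near-perfectly at 5 s intervals", {
  co <- simulate_cohort(cohort_params(seed = 19))
  f <- build_features(co$participants, co$events, co$schedules, 5)
  rep <- loocv_classify(f$x, f$labels, svm_config(), seed = 19)
  expect_gte(rep$n_correct, 19L)
})
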