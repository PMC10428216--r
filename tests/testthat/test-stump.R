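test_that("a perfectly separable column gives the midpoint rule", {
  p <- tibble::tibble(kinase = paste0("k", 1:4),
                      label = c("active", "active", "inactive", "inactive"),
                      c1 = c(0.4, 0.5, 1.5, 1.6))
  m <- fit_stump(p)
  expect_identical(m$column, "c1")
  expect_equal(m$threshold, 1.0)
  expect_identical(m$orientation, "active")
  expect_equal(m$train_impurity, 0)
  expect_equal(m$train_balanced_accuracy, 1)
})

test_that("ties between identical separable columns go to the lower column index", {
  p <- tibble::tibble(kinase = paste0("k", 1:4),
                      label = c("active", "active", "inactive", "inactive"),
                      c1 = c(0.4, 0.5, 1.5, 1.6),
                      c2 = c(0.4, 0.5, 1.5, 1.6))
  expect_identical(fit_stump(p)$column, "c1")
})

test_that("single-class and all-constant inputs are rejected", {
  p <- tibble::tibble(kinase = c("a", "b"), label = c("active", "active"),
                      c1 = c(1, 2))
  expect_error(fit_stump(p), "single class", class = "kinoflex_fit_error")
  q <- tibble::tibble(kinase = c("a", "b"), label = c("active", "inactive"),
                      c1 = c(1, 1))
  expect_error(fit_stump(q), "constant", class = "kinoflex_fit_error")
})

test_that("fit_stump equals the exhaustive brute-force oracle exactly", {
  for (s in 1:60) {
    panel <- random_panel(s)
    got <- fit_stump(panel)
    want <- oracle_fit_stump(panel)
    expect_identical(got$column, want$column)
    expect_identical(got$threshold, want$threshold)
    expect_identical(got$orientation, want$orientation)
    expect_identical(got$train_impurity, want$imp)
  }
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  y <- c("active", "active", "inactive", "inactive")
  expect_equal(balanced_accuracy(y, y), 1)
  expect_equal(balanced_accuracy(y, rep("active", 4)), 0.5)
  # sensitivity 1, specificity 0.5 -> 0.75
  expect_equal(balanced_accuracy(y, c("active", "active", "active", "inactive")), 0.75)
  expect_error(balanced_accuracy(rep("active", 3), rep("active", 3)),
               "single class", class = "kinoflex_stats_error")
})

test_that("resampled evaluation is seed-deterministic with correct split sizes", {
  panel <- gen_fluctuation_panel(panel_spec(seed = 2))   # 43 x 223 default
  expect_identical(nrow(panel), 43L)
  expect_identical(sum(!names(panel) %in% c("kinase", "label")), 223L)
  ev1 <- resampled_evaluation(panel, repeats = 10, seed = 5)
  ev2 <- resampled_evaluation(panel, repeats = 10, seed = 5)
  expect_identical(ev1$records, ev2$records)
  expect_identical(ev1$n_train, 30)
  expect_identical(ev1$n_validation, 13)
  expect_equal(sum(ev1$column_frequency$frequency), 1)
  # mean/sd consistent with records (population sd)
  ba <- ev1$records$balanced_accuracy
  expect_equal(ev1$mean_balanced_accuracy, mean(ba))
  expect_equal(ev1$sd_balanced_accuracy, sqrt(mean((ba - mean(ba))^2)))
})

test_that("a noiseless separable panel reaches the no-noise ceiling", {
  panel <- gen_fluctuation_panel(panel_spec(
    n_active = 10, n_inactive = 12, n_columns = 12, signal_column = 5,
    mu_active = 0.4, mu_inactive = 1.6, sigma_within = 0.05,
    background_mu = 1.0, background_sigma = 0.05, corr_block = integer(0),
    seed = 19))
  ev <- resampled_evaluation(panel, repeats = 25, seed = 4)
  expect_equal(ev$mean_balanced_accuracy, 1)
  expect_equal(ev$sd_balanced_accuracy, 0)
  expect_identical(ev$column_frequency$column, "c5")
})

test_that("label-shuffled panels score at chance", {
  panel <- gen_fluctuation_panel(panel_spec(seed = 23))
  bas <- vapply(1:50, function(s) {
    shuffled <- panel
    shuffled$label <- withr::with_seed(s, sample(panel$label))
    resampled_evaluation(shuffled, repeats = 5, seed = s)$mean_balanced_accuracy
  }, 0)
  expect_lt(abs(mean(bas) - 0.5), 0.06)
})

test_that("ablation with rounds = 1 equals one resampled evaluation", {
  panel <- gen_fluctuation_panel(panel_spec(n_active = 8, n_inactive = 8,
                                            n_columns = 10, signal_column = 3,
                                            corr_block = integer(0), seed = 29))
  ab <- ablation_cascade(panel, rounds = 1, repeats = 10, seed = 7)
  ev <- resampled_evaluation(panel, repeats = 10, seed = 7)
  expect_identical(ab$rounds$selected_column, glance(ev)$modal_column)
  expect_equal(ab$rounds$mean_balanced_accuracy, ev$mean_balanced_accuracy)
  expect_equal(ab$rounds$sd_balanced_accuracy, ev$sd_balanced_accuracy)
})

test_that("ablation walks signal then correlated block, and decays to chance", {
  # correlated block at rho 0.95 backs up the planted signal: the whole
  # correlated group is consumed before any background column
  for (s in 1:5) {
    panel <- gen_fluctuation_panel(panel_spec(seed = 400 + s))
    ab <- ablation_cascade(panel, rounds = 3, repeats = 30, seed = s)
    sel <- ab$rounds$selected_column
    expect_true(all(sel %in% c("c120", "c121", "c122")))
  }

  # single informative column: after its removal only noise remains
  bas <- vapply(1:10, function(s) {
    panel <- gen_fluctuation_panel(panel_spec(n_active = 10, n_inactive = 11,
                                              n_columns = 12, signal_column = 6,
                                              corr_block = integer(0),
                                              seed = 500 + s))
    ab <- ablation_cascade(panel, rounds = 2, repeats = 10, seed = s)
    ab$rounds$mean_balanced_accuracy[2]
  }, 0)
  expect_lt(abs(mean(bas) - 0.5), 0.08)
})

test_that("the Lasso corroborates the planted signal column", {
  top_hits <- vapply(1:20, function(s) {
    panel <- gen_fluctuation_panel(panel_spec(n_active = 12, n_inactive = 12,
                                              n_columns = 15, signal_column = 9,
                                              mu_active = 0.4, mu_inactive = 1.6,
                                              sigma_within = 0.1,
                                              corr_block = integer(0),
                                              seed = 600 + s))
    sel <- lasso_select(panel, penalty = 0.05)
    nrow(sel) > 0 && sel$column[1] == "c9"
  }, TRUE)
  expect_gte(mean(top_hits), 0.9)
})

test_that("a huge penalty shrinks the Lasso selection to nothing", {
  panel <- gen_fluctuation_panel(panel_spec(n_active = 10, n_inactive = 10,
                                            n_columns = 8, signal_column = 2,
                                            corr_block = integer(0), seed = 37))
  expect_identical(nrow(lasso_select(panel, penalty = 50)), 0L)
})

test_that("at penalty ~ 0 the Lasso matches an unpenalised logistic fit", {
  # 2-column orthogonal design, well-conditioned
  withr::with_seed(41, {
    n <- 60
    x1 <- rep(c(-1, 1), each = n / 2)
    x2 <- rep(c(-1, 1), times = n / 2)
    eta <- 0.8 * x1 - 0.5 * x2
    y <- ifelse(runif(n) < 1 / (1 + exp(-eta)), "active", "inactive")
  })
  panel <- tibble::tibble(kinase = paste0("k", 1:n), label = y,
                          c1 = x1, c2 = x2)
  sel <- lasso_select(panel, penalty = 1e-7)
  Xs <- scale(cbind(x1, x2))
  fit <- stats::glm(factor(y, levels = c("inactive", "active")) ~ Xs,
                    family = stats::binomial())
  want <- stats::coef(fit)[2:3]
  got <- setNames(sel$coefficient, sel$column)[c("c1", "c2")]
  expect_equal(unname(got), unname(want), tolerance = 1e-4)
})
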