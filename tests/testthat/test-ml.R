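test_that("classifier metrics: exact ranks, nulls, invariances", {
  ## printed toy: perfect ranking
  m <- evaluate_classifier(c(0.9, 0.8, 0.3, 0.1) - 0.5,
                           c("AFib", "AFib", "AFlu", "AFlu"))
  expect_equal(m$accuracy, 1)
  expect_equal(m$roc_auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  ## label-independent scores give ROC about 0.5
  set.seed(41)
  s <- rnorm(2000)
  y <- rep(c("AFib", "AFlu"), 1000)
  expect_equal(roc_auc(s, y), 0.5, tolerance = 0.05)
  ## invariance under monotone transforms of the scores
  s2 <- rnorm(50)
  y2 <- sample(c("AFib", "AFlu"), 50, replace = TRUE)
  expect_equal(roc_auc(s2, y2), roc_auc(exp(3 * s2), y2))
  expect_error(roc_auc(s2, rep("AFib", 50)), class = "heatrr_invalid")
})

test_that("rank AUC matches the trapezoidal reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:5) {
    s <- round(rnorm(60), 1)  # rounding forces ties
    y <- sample(c("AFib", "AFlu"), 60, replace = TRUE)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = factor(y, levels = c("AFlu", "AFib")), predictor = s,
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(s, y), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("SVM separates blobs and scores deterministically", {
  set.seed(43)
  x <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
  y <- rep(c("AFlu", "AFib"), each = 30)
  m <- train_svm(x, y, cost = 1, gamma = 0.5)
  p <- predict(m, x)
  expect_equal(mean(as.character(p$class) == y), 1)
  ## scores orient toward the positive class
  expect_true(mean(p$score[y == "AFib"]) > mean(p$score[y == "AFlu"]))
  ## a duplicated training point classifies like the original
  p2 <- predict(m, x[c(1, 1), , drop = FALSE])
  expect_equal(p2$score[1], p2$score[2])
  expect_error(train_svm(x, rep("AFib", 60)), class = "heatrr_invalid")
})

test_that("the default SVM search grid has 2 x 3 x 3 x |n_sub| cells", {
  expect_equal(nrow(svm_grid()), 18)
  expect_equal(nrow(svm_grid(n_sub = 10:22)), 234)
})

test_that("cross-validation is stratified, leakage-free and seeded", {
  set.seed(44)
  x <- rbind(matrix(rnorm(200, -1.5), 100, 2), matrix(rnorm(200, 1.5), 100, 2))
  y <- rep(c("AFlu", "AFib"), each = 100)
  cv <- cross_validate(x, y, model = "svm",
                       grid = data.frame(kernel = "radial", cost = 1,
                                         gamma = 0.5),
                       folds = 10, repeats = 2, seed = 1)
  expect_equal(nrow(cv$per_fold), 20)
  expect_gt(cv$mean_accuracy, 0.95)
  expect_gt(cv$mean_roc, 0.98)
  ## identical seed, identical result
  cv2 <- cross_validate(x, y, model = "svm",
                        grid = data.frame(kernel = "radial", cost = 1,
                                          gamma = 0.5),
                        folds = 10, repeats = 2, seed = 1)
  expect_identical(cv$per_fold, cv2$per_fold)
  ## permuted labels land at chance level
  set.seed(45)
  yp <- sample(y)
  cvp <- cross_validate(x, yp, model = "svm",
                        grid = data.frame(kernel = "radial", cost = 1,
                                          gamma = 0.5),
                        folds = 10, repeats = 2, seed = 1)
  expect_lt(abs(cvp$mean_accuracy - 0.5), 3 * max(cvp$sd_accuracy, 0.05))
  ## stratification fails loudly on tiny classes
  expect_error(
    cross_validate(x[1:12, ], c(rep("AFib", 2), rep("AFlu", 10)),
                   model = "threshold", folds = 10, repeats = 1, seed = 1),
    class = "heatrr_invalid")
})

test_that("the threshold classifier works on a single decisive feature", {
  set.seed(46)
  x <- matrix(c(rnorm(50, 0), rnorm(50, 4)), ncol = 1)
  y <- rep(c("AFlu", "AFib"), each = 50)
  cv <- cross_validate(x, y, model = "threshold", folds = 10, repeats = 2,
                       seed = 3)
  expect_gt(cv$mean_accuracy, 0.9)
  expect_gt(cv$mean_roc, 0.95)
})

test_that("CNN gradients match numerical differentiation", {
  set.seed(47)
  par <- heatrr:::cnn_init(12L, hidden = 4L)
  x <- rnorm(12)
  y <- 1
  cache <- heatrr:::cnn_forward(par, x, dropout = 0, train = FALSE)
  g <- heatrr:::cnn_backward(par, cache, y)
  loss <- function(p) {
    c2 <- heatrr:::cnn_forward(p, x, dropout = 0, train = FALSE)
    -(y * log(c2$p) + (1 - y) * log(1 - c2$p))
  }
  eps <- 1e-6
  for (w in c("W1", "W3", "W5", "W6", "b2", "b5", "b6")) {
    pick <- seq_len(min(3, length(par[[w]])))
    for (i in pick) {
      pp <- par; pp[[w]][i] <- pp[[w]][i] + eps
      pm <- par; pm[[w]][i] <- pm[[w]][i] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(as.numeric(g[[w]])[i], num, tolerance = 1e-4)
    }
  }
})

test_that("CNN outputs probabilities and learns a separable task", {
  set.seed(48)
  n <- 40
  x <- rbind(matrix(rnorm(10 * n / 2, -1), n / 2, 10),
             matrix(rnorm(10 * n / 2, 1), n / 2, 10))
  y <- rep(c(0, 1), each = n / 2)
  m <- train_cnn(x, y, dropout = 0, epochs = 60, lr = 5e-3, seed = 1)
  p <- predict_cnn(m, x)
  expect_true(all(p > 0 & p < 1))
  expect_gt(mean((p > 0.5) == y), 0.95)
  ## input shorter than the receptive field errors
  expect_error(train_cnn(x[, 1:5], y, epochs = 1), class = "heatrr_invalid")
})
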