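sim_boot_data <- function(n = 120, seed = 31, signal = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(-0.6 + signal * X[, 1]))
  list(X = X, y = y)
}

test_that("B = 0 gives the point estimate only, with an NA CI", {
  d <- sim_boot_data()
  pe <- bootstrap_performance(d$X, d$y, B = 0, seed = 1)
  expect_true(is.na(pe$auc_lo) && is.na(pe$auc_hi))
  full <- fit_logistic(d$X, d$y)
  expect_equal(pe$auc, auc(full$fitted, d$y))
})

test_that("bootstrap results are reproducible under a seed", {
  d <- sim_boot_data()
  a <- bootstrap_performance(d$X, d$y, B = 40, seed = 9)
  b <- bootstrap_performance(d$X, d$y, B = 40, seed = 9)
  expect_identical(a, b)
  c_ <- bootstrap_performance(d$X, d$y, B = 40, seed = 10)
  expect_false(identical(a$auc_lo, c_$auc_lo))
})

test_that(".632 estimates blend apparent and out-of-bag with the fixed weights", {
  d <- sim_boot_data(n = 150, seed = 32)
  B <- 60; seed <- 5
  pe <- bootstrap_performance(d$X, d$y, B = B, seed = seed)

  # independent recomputation of the same resampling stream
  idx_case <- which(d$y == 1); idx_ctrl <- which(d$y == 0)
  full <- fit_logistic(d$X, d$y)
  thr <- dichotomize(full$fitted, d$y)$threshold
  apparent <- classification_metrics(full$fitted, d$y, thr)
  oob <- matrix(NA_real_, B, 4)
  set.seed(seed)
  for (b in seq_len(B)) {
    take <- c(sample(idx_case, length(idx_case), replace = TRUE),
              sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
    out_idx <- setdiff(seq_along(d$y), unique(take))
    fb <- suppressWarnings(fit_logistic(d$X[take, ], d$y[take]))
    if (isFALSE(fb$converged)) next
    p_in <- predict(fb, d$X[take, ])
    if (length(out_idx) > 0 && length(unique(d$y[out_idx])) == 2) {
      thr_b <- dichotomize(p_in, d$y[take])$threshold
      oob[b, ] <- classification_metrics(predict(fb, d$X[out_idx, ]),
                                         d$y[out_idx], thr_b)
    }
  }
  blend <- 0.368 * apparent + 0.632 * colMeans(oob, na.rm = TRUE)
  expect_equal(pe$sens632, blend[[1]], tolerance = 1e-12)
  expect_equal(pe$spec632, blend[[2]], tolerance = 1e-12)
  expect_equal(pe$ppv632, blend[[3]], tolerance = 1e-12)
  expect_equal(pe$npv632, blend[[4]], tolerance = 1e-12)
  # and the blend weights are those of the worked example:
  expect_equal(0.368 * 0.1 + 0.632 * 0.2, 0.1632)
})

test_that("a constant predictor is a .632 fixed point (apparent = out-of-bag)", {
  # fit_fn that ignores covariates: predicts the training prevalence
  const_fit <- function(X, y) {
    structure(list(p = mean(y)), class = "const_fit")
  }
  d <- sim_boot_data(n = 100, seed = 33, signal = 0)
  # predict method registered locally for the test
  assign("predict.const_fit",
         function(object, newdata = NULL, ...) {
           rep(object$p, if (is.null(newdata)) 1 else nrow(newdata))
         }, envir = globalenv())
  on.exit(rm("predict.const_fit", envir = globalenv()), add = TRUE)
  pe <- bootstrap_performance(d$X, d$y, fit_fn = const_fit, B = 30, seed = 2)
  # every probability equal: threshold rule classifies everyone positive
  expect_equal(pe$sens632, 1)
  expect_equal(pe$spec632, 0)
  expect_equal(pe$auc, 0.5)
})

test_that(".632 estimate lies between apparent and mean out-of-bag", {
  d <- sim_boot_data(n = 200, seed = 34)
  pe <- bootstrap_performance(d$X, d$y, B = 50, seed = 3)
  expect_true(all(!is.na(c(pe$sens632, pe$spec632, pe$ppv632, pe$npv632))))
  expect_true(all(c(pe$sens632, pe$spec632, pe$ppv632, pe$npv632) >= 0 &
                    c(pe$sens632, pe$spec632, pe$ppv632, pe$npv632) <= 1))
})

test_that("bootstrap CI width shrinks roughly as n^(-1/2)", {
  wide <- local({
    d <- sim_boot_data(n = 200, seed = 35)
    pe <- bootstrap_performance(d$X, d$y, B = 150, seed = 4)
    pe$auc_hi - pe$auc_lo
  })
  narrow <- local({
    d <- sim_boot_data(n = 2000, seed = 35)
    pe <- bootstrap_performance(d$X, d$y, B = 150, seed = 4)
    pe$auc_hi - pe$auc_lo
  })
  expect_lt(narrow, wide)
})

test_that("stratified resampling preserves the case/control counts", {
  d <- sim_boot_data(n = 80, seed = 36)
  # a fit_fn that records the outcome composition it sees
  seen <- new.env(); seen$counts <- NULL
  spy_fit <- function(X, y) {
    seen$counts <- rbind(seen$counts, c(sum(y == 1), sum(y == 0)))
    fit_logistic(X, y)
  }
  invisible(bootstrap_performance(d$X, d$y, fit_fn = spy_fit, B = 10,
                                  seed = 6))
  expect_true(all(seen$counts[-1, 1] == sum(d$y == 1)))
  expect_true(all(seen$counts[-1, 2] == sum(d$y == 0)))
})
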