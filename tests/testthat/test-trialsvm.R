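fs <- 7.8125

test_that("a window equal to the HRF predictor yields beta 1 with zero residuals", {
  spec <- trial_estimation_spec(z_normalize = FALSE)
  trial <- c(20, 30)
  n <- 400
  w0 <- floor((trial[1] - spec$prestim_s) * fs)
  w1 <- floor((trial[2] + spec$poststim_s) * fs) - 1
  ts <- (w0:w1) / fs
  main <- convolve_boxcar_hrf(ts >= trial[1] & ts < trial[2], fs)
  conc <- matrix(0, n, 2)
  conc[(w0 + 1):(w1 + 1), 1] <- main
  conc[(w0 + 1):(w1 + 1), 2] <- 0.4 * main + 0.2 # amplitude + offset
  est <- estimate_trial(conc, trial, fs, spec)
  expect_equal(est, c(1, 0.4), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pure-noise trials have mean beta near zero; injected amplitude is recovered", {
  set.seed(41)
  spec <- trial_estimation_spec(z_normalize = FALSE)
  trial <- c(20, 30)
  n <- 400
  w0 <- floor((trial[1] - spec$prestim_s) * fs)
  w1 <- floor((trial[2] + spec$poststim_s) * fs) - 1
  ts <- (w0:w1) / fs
  main <- convolve_boxcar_hrf(ts >= trial[1] & ts < trial[2], fs)
  n_mc <- 200
  betas <- vapply(seq_len(n_mc), function(i) {
    conc <- matrix(stats::rnorm(n, sd = 1), n, 1)
    estimate_trial(conc, trial, fs, spec)[1]
  }, numeric(1))
  se <- stats::sd(betas) / sqrt(n_mc)
  expect_lt(abs(mean(betas)), 3 * se + 1e-3)

  amp <- 0.7
  rec <- vapply(seq_len(50), function(i) {
    conc <- matrix(stats::rnorm(n, sd = 0.05), n, 1)
    conc[(w0 + 1):(w1 + 1), 1] <- conc[(w0 + 1):(w1 + 1), 1] + amp * main
    estimate_trial(conc, trial, fs, spec)[1]
  }, numeric(1))
  expect_equal(mean(rec), amp, tolerance = 0.05)
})

test_that("degenerate windows are flagged; estimate kinds behave as documented", {
  trial <- c(20, 30)
  conc <- matrix(1, 400, 2) # zero variance everywhere
  est <- estimate_trial(conc, trial, fs, trial_estimation_spec())
  expect_equal(est, c(0, 0), ignore_attr = TRUE)
  expect_true(all(attr(est, "flagged")))

  # percent kind with a zero constant beta falls back to the raw beta
  w0 <- floor((trial[1] - 2) * fs)
  w1 <- floor((trial[2] + 12) * fs) - 1
  ts <- (w0:w1) / fs
  main <- convolve_boxcar_hrf(ts >= trial[1] & ts < trial[2], fs)
  conc3 <- matrix(0, 400, 1)
  conc3[(w0 + 1):(w1 + 1), 1] <- 0.6 * main # no constant component
  expect_warning(
    estp <- estimate_trial(conc3, trial, fs,
                           trial_estimation_spec(kind = "percent",
                                                 z_normalize = FALSE)),
    "falling back"
  )
  expect_equal(estp, 0.6, tolerance = 1e-8, ignore_attr = TRUE)
  set.seed(42)
  conc2 <- matrix(stats::rnorm(800), 400, 2)
  # t and percent kinds return finite values on noisy data without z-norm
  for (kind in c("t", "percent")) {
    est2 <- estimate_trial(conc2 + 5, trial, fs,
                           trial_estimation_spec(kind = kind, z_normalize = FALSE))
    expect_true(all(is.finite(est2)))
  }
})

test_that("training sets enumerate trials by run and onset with correct labels", {
  sess <- make_finger_tapping_session(seed = 2, n_runs = 2)
  runs <- session_runs(sess)
  pats <- build_training_set(runs)
  expect_equal(nrow(pats$features), 2 * 2 * 12) # runs x conditions x trials
  expect_equal(ncol(pats$features), 20)
  expect_equal(as.vector(table(pats$run)), c(24, 24))
  expect_equal(as.vector(table(pats$label)), c(24, 24))
  # ordered by run then onset
  expect_true(all(diff(pats$run) >= 0))
  expect_true(all(tapply(pats$onset_s, pats$run, function(o) all(diff(o) > 0))))
  # brute-force trial count oracle
  n_trials <- sum(vapply(runs, function(r) {
    sum(vapply(r$protocol$conditions, nrow, integer(1)))
  }, numeric(1)))
  expect_equal(nrow(pats$features), n_trials)

  expect_error(build_training_set(runs, channels = integer(0)), "empty channel mask")
  runs2 <- runs
  names(runs2[[2]]$protocol$conditions) <- c("x", "y")
  expect_error(build_training_set(runs2), "conditions mismatch")
})

test_that("pattern extraction is independent of the order conditions are listed", {
  sess <- make_finger_tapping_session(seed = 6, n_runs = 1,
                                      trials_per_condition = 4)
  runs <- session_runs(sess)
  pats1 <- build_training_set(runs, conditions = c("left", "right"))
  pats2 <- build_training_set(runs, conditions = c("right", "left"))
  expect_equal(pats1$features, pats2$features) # onsets fix the row order
  expect_equal(as.character(pats1$label), as.character(pats2$label))
})

test_that("a separable toy problem trains to 100% and predicts its own labels", {
  set.seed(43)
  n_per <- 10
  f1 <- cbind(matrix(stats::rnorm(n_per * 5, 1, 0.1), n_per, 5),
              matrix(stats::rnorm(n_per * 5, 0, 0.1), n_per, 5))
  f2 <- cbind(matrix(stats::rnorm(n_per * 5, 0, 0.1), n_per, 5),
              matrix(stats::rnorm(n_per * 5, 1, 0.1), n_per, 5))
  pats <- structure(list(
    features = rbind(f1, f2),
    label = factor(rep(c("a", "b"), each = n_per)),
    run = rep(1L, 2 * n_per), onset_s = seq_len(2 * n_per),
    spec = trial_estimation_spec()
  ), class = "trial_patterns")
  fit <- train_classifier(pats)
  expect_equal(as.character(predict(fit, pats)), as.character(pats$label))
  expect_error(train_classifier(subset_patterns <- structure(
    list(features = f1, label = factor(rep("a", n_per)),
         run = rep(1L, n_per), onset_s = 1:n_per, spec = NULL),
    class = "trial_patterns"
  )), "fewer than 2 classes")
})

test_that("three-class decoding with distinct topographies is above chance", {
  set.seed(44)
  n_per <- 12
  mk <- function(active) {
    m <- matrix(stats::rnorm(n_per * 9, 0, 0.5), n_per, 9)
    m[, active] <- m[, active] + 1
    m
  }
  feats <- rbind(mk(1:3), mk(4:6), mk(7:9))
  pats <- structure(list(
    features = feats,
    label = factor(rep(c("a", "b", "c"), each = n_per)),
    run = rep(rep(1:2, each = n_per / 2), 3),
    onset_s = seq_len(3 * n_per), spec = NULL
  ), class = "trial_patterns")
  cv <- cross_validate(pats)
  expect_equal(length(cv$accuracy), 2L) # fold count = run count
  expect_gt(cv$mean_accuracy, 1 / 3 + 0.2)
})

test_that("leave-one-run-out is perfect on separable runs and at chance when shuffled", {
  sess <- make_finger_tapping_session(seed = 8)
  pats <- build_training_set(session_runs(sess))
  cv <- cross_validate(pats)
  expect_equal(cv$accuracy, rep(1, 3))
  expect_equal(cv$mean_accuracy, 1)

  # destroying the label structure brings accuracy to chance
  set.seed(45)
  null_accs <- vapply(1:20, function(i) {
    shuf <- pats
    for (r in 1:3) {
      idx <- which(shuf$run == r)
      shuf$label[idx] <- shuf$label[sample(idx)]
    }
    cross_validate(shuf)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(null_accs) - 0.5), 0.12)
  expect_error(cross_validate(subset_patterns(pats, pats$run == 1)), "2 runs")
})

test_that("the permutation test is calibrated, extreme-case exact, and seed-stable", {
  sess <- make_finger_tapping_session(seed = 10)
  pats <- build_training_set(session_runs(sess))
  pt <- permutation_test(pats, n_perm = 99, seed = 7)
  # observed 100% is at least as large as every null accuracy
  expect_equal(pt$observed, 1)
  expect_equal(pt$p_value, (1 + sum(pt$null >= 1)) / 100)
  # balanced two-class null centers on chance
  expect_lt(abs(mean(pt$null) - 0.5), 0.1)
  pt2 <- permutation_test(pats, n_perm = 99, seed = 7)
  expect_identical(pt$null, pt2$null) # determinism contract
  expect_output(print(pt), "permutation test")
  expect_error(permutation_test(pats, n_perm = 0), "n_perm")
})

test_that("class-mean patterns are lateralized like the driven channel groups", {
  sess <- make_finger_tapping_session(seed = 13)
  pats <- build_training_set(session_runs(sess))
  cm <- class_mean_patterns(pats)
  # left tapping drives right-hemisphere channels 11-20 and vice versa
  expect_gt(mean(cm["left", 11:20]), mean(cm["left", 1:10]))
  expect_gt(mean(cm["right", 1:10]), mean(cm["right", 11:20]))
  # sign test across channels: every driven channel exceeds its mirror
  expect_true(all(cm["left", 11:20] > cm["left", 1:10]))
  expect_true(all(cm["right", 1:10] > cm["right", 11:20]))
})

test_that("pattern exports are faithful", {
  sess <- make_finger_tapping_session(seed = 14, n_runs = 1,
                                      trials_per_condition = 3)
  pats <- build_training_set(session_runs(sess))
  f <- withr::local_tempfile(fileext = ".csv")
  write_patterns_csv(pats, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), nrow(pats$features))
  expect_equal(as.matrix(df[, -(1:3)]), pats$features,
               ignore_attr = TRUE, tolerance = 1e-12)
  fs2 <- withr::local_tempfile(fileext = ".svm")
  write_patterns_sparse(pats, fs2)
  first <- strsplit(readLines(fs2)[1], " ")[[1]]
  expect_equal(as.integer(first[1]), as.integer(pats$label[1]))
  expect_equal(length(first) - 1L, sum(pats$features[1, ] != 0))
})
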