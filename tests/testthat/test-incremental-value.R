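test_that("classification metrics match the confusion-matrix definitions", {
  z <- probs_from_counts(tp = 24, fn = 8, tn = 27, fp = 6)
  m <- classification_metrics(z$probs, z$labels)
  expect_equal(round(m$sensitivity, 1), 75.0)
  expect_equal(round(m$specificity, 1), 81.8)
  expect_equal(round(m$accuracy, 1), 78.5)
  # perfect probabilities
  mp <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(mp[1:3]), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100))
  # threshold 0 classifies everything as an event
  m0 <- classification_metrics(z$probs, z$labels, threshold = 0)
  expect_equal(m0$sensitivity, 100)
  expect_equal(m0$specificity, 0)
  expect_error(classification_metrics(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- runif(n)
    m <- classification_metrics(p, y)
    ne <- sum(y == 1); nn <- sum(y == 0)
    expect_equal(m$accuracy, (m$sensitivity * ne + m$specificity * nn) / n)
  }
})

test_that("roc_auc equals the exhaustive pairwise oracle on small inputs", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(52)
  for (i in 1:150) {
    n <- sample(3:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # coarse grid forces ties
    expect_equal(suppressWarnings(roc_auc(s, y)), auc_pair_oracle(s, y))
  }
})

test_that("roc_auc flips under label exchange and is 0.5 for constant scores", {
  set.seed(53)
  s <- runif(20); y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y), 1 - roc_auc(s, 1 - y))
  expect_equal(roc_auc(c(rep(0, 5), rep(1, 5)), rep(c(0, 1), each = 5)), 1)
  expect_warning(a <- roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), "constant")
  expect_equal(a, 0.5)
})

test_that("paired DeLong comparison agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  for (i in 1:10) {
    n <- 60
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s1 <- rnorm(n) + y
    s2 <- rnorm(n) + 0.5 * y
    ours <- compare_auc(s1, s2, y)
    ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                          pROC::roc(y, s2, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$auc_old, as.numeric(pROC::auc(pROC::roc(y, s1, quiet = TRUE))))
  }
})

test_that("DeLong comparison is rank-invariant and null on self-comparison", {
  set.seed(55)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(40)
  self <- compare_auc(s, s, y)
  expect_equal(self$diff, 0)
  expect_equal(self$p.value, 1)
  mono <- compare_auc(s, plogis(2 * s + 1), y)  # strictly monotone transform
  expect_equal(mono$diff, 0)
})

test_that("adding an informative covariate is detected, a null one is not", {
  set.seed(56)
  run <- function(beta2) {
    n <- 200
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.2 + 0.8 * x1 + beta2 * x2))
    f0 <- glm.fit(cbind(1, x1), y, family = binomial())$fitted.values
    f1 <- glm.fit(cbind(1, x1, x2), y, family = binomial())$fitted.values
    compare_auc(f0, f1, y)$p.value < 0.05
  }
  expect_gt(mean(replicate(150, run(0.8))), 0.5)
  # nested-model null: the paired test must not be anticonservative
  expect_lt(mean(replicate(150, run(0))), 0.08)
})

test_that("NRI matches its movement-indicator formula", {
  # every event up, every nonevent down -> maximal NRI of 2
  up <- nri(c(0.2, 0.3, 0.6, 0.7), c(0.3, 0.4, 0.5, 0.6), c(1, 1, 0, 0))
  expect_equal(up$nri, 2)
  # no change -> 0 with p = 1
  none <- nri(c(0.2, 0.8), c(0.2, 0.8), c(0, 1))
  expect_equal(none$nri, 0)
  expect_equal(none$p.value, 1)
  # hand enumeration: events (+,+,-), nonevents (+,-,-) -> 2/3
  old <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  new <- c(0.6, 0.7, 0.4, 0.6, 0.4, 0.3)
  y <- c(1, 1, 1, 0, 0, 0)
  r <- nri(old, new, y)
  expect_equal(r$nri, 2 / 3)
  expect_equal(r$components$up_events, 2)
  expect_equal(r$components$down_nonevents, 2)
  expect_equal(r$se, sqrt(3 / 9 + 3 / 9))
  expect_error(nri(old, new, rep(1, 6)), "nonevent")
})

test_that("IDI matches its mean-probability formula", {
  # +0.1 for all events, -0.1 for all nonevents -> IDI = 0.2
  old <- c(0.5, 0.6, 0.4, 0.3)
  new <- old + c(0.1, 0.1, -0.1, -0.1)
  y <- c(1, 1, 0, 0)
  expect_equal(idi(old, new, y)$idi, 0.2)
  expect_equal(idi(old, old, y)$idi, 0)
  expect_equal(idi(old, old, y)$p.value, 1)
  # IDI equals the change in discrimination slope
  set.seed(57)
  po <- runif(30); pn <- runif(30); yy <- rbinom(30, 1, 0.5); yy[1:2] <- c(0, 1)
  slope <- function(p) mean(p[yy == 1]) - mean(p[yy == 0])
  expect_equal(idi(po, pn, yy)$idi, slope(pn) - slope(po))
})

test_that("swapping event and nonevent labels negates NRI and IDI", {
  set.seed(58)
  po <- runif(24); pn <- runif(24)
  y <- rbinom(24, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(nri(po, pn, y)$nri, -nri(po, pn, 1 - y)$nri)
  expect_equal(idi(po, pn, y)$idi, -idi(po, pn, 1 - y)$idi)
  expect_true(abs(nri(po, pn, y)$nri) <= 2)
  expect_true(abs(idi(po, pn, y)$idi) <= 2)
})

test_that("reclassification report combines NRI, IDI, counts and bootstrap", {
  set.seed(59)
  y <- rep(c(1, 0), each = 20)
  po <- plogis(rnorm(40, ifelse(y == 1, 0.5, -0.5)))
  pn <- plogis(rnorm(40, ifelse(y == 1, 1.2, -1.2)))
  rep <- reclassification_report(po, pn, y, n_boot = 200, seed = 9)
  expect_equal(rep$nri$nri, nri(po, pn, y)$nri)
  cnt <- rep$counts
  expect_equal(cnt$events_corrected + cnt$events_still_misclassified +
                 cnt$events_newly_misclassified,
               sum(y == 1 & (po < 0.5 | pn < 0.5)))
  expect_true(rep$bootstrap$nri_ci[1] <= rep$nri$nri &
                rep$nri$nri <= rep$bootstrap$nri_ci[2])
  # bootstrap is seeded: identical on re-run
  rep2 <- reclassification_report(po, pn, y, n_boot = 200, seed = 9)
  expect_identical(rep$bootstrap, rep2$bootstrap)
})
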