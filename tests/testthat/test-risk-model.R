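test_that("univariate tables dispatch chi-squared and t tests correctly", {
  # diabetes-history style 2x2: 5/33 vs 18/32 exposed
  coh <- data.frame(
    sample_id = sprintf("p%02d", 1:65),
    group = rep(c("non_atherosclerotic", "atherosclerotic"), c(33, 32)),
    diabetes = c(rep(c("yes", "no"), c(5, 28)), rep(c("yes", "no"), c(18, 14))),
    age = c(rnorm(33, 69.3, 4.9), rnorm(32, 71.4, 5.8)))
  coh$group <- factor(coh$group,
                      levels = c("non_atherosclerotic", "atherosclerotic"))
  tab <- univariate_tables(coh, c("diabetes", "age"))
  prow <- tab[tab$variable == "diabetes", ]
  expect_identical(prow$type, "categorical")
  expect_equal(prow$p,
               chisq.test(table(coh$diabetes, coh$group))$p.value)
  expect_lt(prow$p, 0.005)   # strong imbalance: p rounds to 0.001
  arow <- tab[tab$variable == "age", ]
  expect_equal(arow$p, t.test(age ~ group, coh, var.equal = TRUE)$p.value)
})

test_that("identical groups give t = 0, p = 1; zero margins are flagged", {
  coh <- data.frame(sample_id = paste0("p", 1:20),
                    group = rep(c("a", "b"), 10),
                    x = rep(c(1, 2, 3, 4), 5),
                    cat = "same")
  coh$x <- rep(rep(c(1, 2), each = 2), 5)  # same values in both groups
  tab <- univariate_tables(coh, c("x", "cat"))
  expect_equal(tab$statistic[tab$variable == "x"], 0)
  expect_equal(tab$p[tab$variable == "x"], 1)
  expect_match(tab$note[tab$variable == "cat"], "zero margin")
  expect_true(is.na(tab$p[tab$variable == "cat"]))
})

test_that("forward logistic with a single candidate matches a Newton oracle", {
  set.seed(41)
  n <- 80
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$x))
  fit <- forward_logistic(d, "y", "x", alpha_enter = 1 - 1e-12)
  b_oracle <- newton_logistic(cbind(1, d$x), d$y)
  expect_equal(unname(fit$coefficients$B), unname(b_oracle), tolerance = 1e-6)
  expect_equal(fit$coefficients$exp_B, exp(fit$coefficients$B))
  expect_true(all(fit$coefficients$ci_lower <= fit$coefficients$exp_B &
                  fit$coefficients$exp_B <= fit$coefficients$ci_upper))
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("affine covariate rescaling rescales B and preserves predictions", {
  set.seed(42)
  n <- 120
  d <- data.frame(x = rnorm(n, 50, 10), z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1 + 0.08 * (d$x - 50) + 0.5 * d$z))
  d2 <- d
  d2$x <- d$x / 10
  f1 <- logistic_model(d, "y", c("x", "z"))
  f2 <- logistic_model(d2, "y", c("x", "z"))
  b1 <- setNames(f1$coefficients$B, f1$coefficients$term)
  b2 <- setNames(f2$coefficients$B, f2$coefficients$term)
  expect_equal(unname(b2["x"]), unname(10 * b1["x"]), tolerance = 1e-6)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
  expect_equal(roc_auc(f1$fitted, d$y), roc_auc(f2$fitted, d$y))
  m1 <- classification_metrics(f1$fitted, d$y)
  m2 <- classification_metrics(f2$fitted, d$y)
  expect_equal(m1$accuracy, m2$accuracy)
})

test_that("a covariate equal to the label triggers the separation flag", {
  d <- data.frame(y = rep(c(0, 1), each = 10))
  d$x <- d$y
  expect_warning(fit <- forward_logistic(d, "y", "x"), "separation")
  expect_true(fit$flags$separation)
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(43)
  d <- data.frame(x = rnorm(50))
  d$x2 <- 2 * d$x - 1
  d$y <- rbinom(50, 1, plogis(d$x))
  expect_warning(fit <- logistic_model(d, "y", c("x", "x2")), "collinear")
  expect_identical(fit$selected, "x")
})

test_that("LOOCV is deterministic, perfect on separable data, chance-bounded on noise", {
  d <- data.frame(y = rep(c(0, 1), each = 10))
  d$x <- c(rnorm(10, -3, 0.2), rnorm(10, 3, 0.2))
  r <- suppressWarnings(loocv_accuracy(d, "y", "x"))
  expect_equal(r$accuracy, 100)
  expect_identical(r$accuracy,
                   suppressWarnings(loocv_accuracy(d, "y", "x"))$accuracy)
  # a label-independent covariate cannot beat chance out of sample; with
  # exactly balanced classes LOOCV even dips below 50% (each held-out
  # patient tilts the refit intercept toward the opposite class)
  set.seed(44)
  acc <- replicate(15, {
    dn <- data.frame(y = rep(c(0, 1), 50), x = rnorm(100))
    loocv_accuracy(dn, "y", "x")$accuracy
  })
  expect_lt(mean(acc), 55)
  expect_gt(mean(acc), 30)
})

test_that("LOOCV accuracy does not exceed in-sample accuracy on average", {
  set.seed(45)
  optimism <- replicate(30, {
    n <- 40
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- rbinom(n, 1, plogis(0.4 * d$x1))
    fit <- logistic_model(d, "y", c("x1", "x2"))
    ins <- classification_metrics(fit$fitted, d$y)$accuracy
    ins - loocv_accuracy(d, "y", c("x1", "x2"))$accuracy
  })
  expect_gt(mean(optimism), 0)
})

test_that("marker Q_rel columns join the cohort by sample id", {
  q <- matrix(1:6 / 7, 2, 3,
              dimnames = list(c("miR-1", "miR-2"), c("a", "b", "c")))
  expr <- structure(list(q_rel = q), class = "expression_matrix")
  coh <- data.frame(sample_id = c("c", "a"))
  out <- assemble_model_data(coh, expr, "miR-1")
  expect_equal(out$`qrel_miR_1`, unname(q["miR-1", c("c", "a")]))
  expect_error(assemble_model_data(data.frame(sample_id = "zz"), expr, "miR-1"),
               "missing sample")
  expect_error(assemble_model_data(coh, expr, "miR-9"), "absent")
})
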