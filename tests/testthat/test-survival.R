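test_that("classification metrics match definitions and the pairwise oracle", {
  sep <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  lab <- c("RC", "RC", "RC", "NRC", "NRC")
  m <- classification_metrics(sep, lab)
  expect_equal(m$auroc, 100)
  expect_equal(m$accuracy, 100)

  allnrc <- classification_metrics(c(0.1, 0.2, 0.3, 0.4), c("RC", "RC", "NRC", "NRC"))
  expect_equal(allnrc$specificity, 100)
  expect_equal(allnrc$sensitivity, 0)

  set.seed(41)
  sc <- round(runif(20), 1)          # rounding forces ties
  lb <- sample(c("RC", "NRC"), 20, replace = TRUE, prob = c(0.4, 0.6))
  if (length(unique(lb)) == 1) lb[1] <- setdiff(c("RC", "NRC"), lb[1])
  got <- classification_metrics(sc, lb)
  expect_equal(got$auroc, pairwise_auroc_oracle(sc, lb), tolerance = 1e-12)

  # AUROC invariant under strictly monotone transforms
  expect_equal(classification_metrics(stats::qlogis(pmin(pmax(sc, .01), .99)), lb)$auroc,
               got$auroc, tolerance = 1e-12)

  expect_error(classification_metrics(sc, rep("RC", 20)), "single class")
})

test_that("patient aggregation follows the most-suspicious-slide rule", {
  preds <- data.frame(
    patient_id = c("a", "b", "b", "c", "c"),
    p_rc = c(0.3, 0.2, 0.9, 0.4, 0.45),
    label = c("NRC", "RC", "RC", "NRC", "NRC")
  )
  agg <- aggregate_patient(preds)
  expect_equal(agg$score[agg$patient_id == "a"], 0.3)   # single slide: identity
  expect_equal(agg$score[agg$patient_id == "b"], 0.9)   # max rule
  expect_equal(agg$group[agg$patient_id == "b"], "high")
  expect_equal(aggregate_patient(preds, method = "mean")$score[2], 0.55)

  shuffled <- aggregate_patient(preds[sample(nrow(preds)), ])
  expect_equal(shuffled, agg)
})

test_that("cox_univariate agrees with the reference fitter and its identities", {
  # two groups with identical data: HR exactly 1
  rec0 <- data.frame(time = rep(c(10, 20, 30, 40), 2),
                     event = rep(c(1, 0, 1, 1), 2),
                     group = rep(c("high", "low"), each = 4))
  f0 <- cox_univariate(rec0)
  expect_equal(f0$hr, 1, tolerance = 1e-6)

  set.seed(43)
  n <- 300
  x <- rbinom(n, 1, 0.4)
  t_raw <- rexp(n, rate = 0.01 * ifelse(x == 1, 2.3, 1))
  rec <- data.frame(time = t_raw, event = 1L,
                    group = ifelse(x == 1, "high", "low"))
  fit <- cox_univariate(rec, horizon = 60)
  oracle <- survival::coxph(
    survival::Surv(pmin(time, 60), as.integer(event & time <= 60)) ~
      I(group == "high"),
    data = rec, ties = "breslow"
  )
  expect_equal(fit$beta, unname(stats::coef(oracle)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(diag(stats::vcov(oracle)))), tolerance = 1e-6)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  expect_error(cox_univariate(data.frame(time = 1:4, event = 0L,
                                         group = rep(c("high", "low"), 2))),
               "no events")
  expect_error(cox_univariate(data.frame(time = 1:4, event = 1L,
                                         group = "high")), "empty")
})

test_that("cox estimates concentrate at HR 1 under label permutation", {
  spec <- tiny_spec(n_rc = 150, n_nrc = 150, n_instances = c(2, 2), dim = 2,
                    true_hr = 2.3, seed = 6)
  sim <- gen_cohort(spec)
  pat <- unique(sim$cohort[, c("patient_id", "label", "time_months", "event")])
  set.seed(44)
  hrs <- vapply(1:50, function(i) {
    g <- sample(pat$label)
    cox_univariate(data.frame(time = pat$time_months, event = pat$event,
                              group = ifelse(g == "RC", "high", "low")))$hr
  }, numeric(1))
  expect_gte(stats::median(hrs), 0.8)
  expect_lte(stats::median(hrs), 1.25)
})

test_that("parameter recovery: mean Cox estimate within 10% of truth", {
  hrs <- vapply(1:20, function(s) {
    spec <- tiny_spec(n_rc = 1000, n_nrc = 1000, n_instances = c(2, 2),
                      dim = 2, true_hr = 2.3, seed = s)
    sim <- gen_cohort(spec)
    pat <- unique(sim$cohort[, c("patient_id", "label", "time_months", "event")])
    cox_univariate(data.frame(time = pat$time_months, event = pat$event,
                              group = ifelse(pat$label == "RC", "high", "low")))$hr
  }, numeric(1))
  expect_lt(abs(mean(hrs) - 2.3) / 2.3, 0.10)
})

test_that("km_table matches the product-limit definition and survfit", {
  # no events: flat at 1
  flat <- km_table(data.frame(time = c(10, 20, 30), event = 0L, group = "g"))
  expect_equal(flat$survival, 1)

  # single event among n drops survival to (n-1)/n
  one <- km_table(data.frame(time = c(5, 10, 20, 30), event = c(1, 0, 0, 0),
                             group = "g"))
  expect_equal(one$survival, c(1, 3 / 4))

  set.seed(45)
  rec <- data.frame(time = sample(1:40, 30, replace = TRUE),
                    event = rbinom(30, 1, 0.6),
                    group = rep(c("high", "low"), 15))
  km <- km_table(rec)
  for (g in c("high", "low")) {
    kg <- km[km$group == g, ]
    expect_equal(kg$survival[1], 1)
    expect_true(all(diff(kg$survival) <= 1e-12))   # non-increasing
    # explicit product oracle
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            data = rec[rec$group == g, ])
    ev <- sf$time[sf$n.event > 0]
    expect_equal(kg$time[-1], ev)
    expect_equal(kg$survival[-1], sf$surv[sf$n.event > 0], tolerance = 1e-12)
  }
  expect_error(km_table(data.frame(time = 1, event = 1L, group = "a")[0, ]),
               "empty")
})

test_that("chi-squared association matches the textbook formula and chisq.test", {
  tab <- matrix(c(39, 30, 38, 77), nrow = 2)   # [[39,38],[30,77]]
  got <- chi_square_assoc(tab)
  a <- 39; b <- 38; c <- 30; d <- 77; n <- a + b + c + d
  expect_equal(got$statistic,
               n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
               tolerance = 1e-12)
  oracle <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(got$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-10)

  flat <- chi_square_assoc(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  # general r x 2 path against chisq.test
  set.seed(46)
  t3 <- matrix(rpois(8, 20) + 1, nrow = 4)
  expect_equal(chi_square_assoc(t3)$statistic,
               unname(stats::chisq.test(t3, correct = FALSE)$statistic),
               tolerance = 1e-10)
  expect_error(chi_square_assoc(matrix(c(0, 0, 5, 5), 2)), "margin")
})
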