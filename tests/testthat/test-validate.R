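test_that("cross-tabulation counts every record once and checks inputs", {
  ct <- cross_tabulate(c("primary", "primary", "duplicate"),
                       c("primary", "primary", "duplicate"))
  expect_equal(unlist(ct[c("a", "b", "c", "d", "n")]),
               c(a = 2, b = 0, c = 0, d = 1, n = 3))
  expect_error(cross_tabulate(c("primary"), c("primary", "duplicate")),
               "same records")
  expect_error(cross_tabulate(a = -1, b = 0, c = 0, d = 0))
})

test_that("sensitivity and specificity are exact ratios with flagged margins", {
  ct <- cross_tabulate(a = 2296, b = 10, c = 0, d = 316)
  est <- sensitivity_specificity(ct)
  expect_equal(unname(est["sensitivity"]), 1)
  expect_equal(unname(est["specificity"]), 316 / 326)
  # perfect agreement
  expect_equal(unname(sensitivity_specificity(
    cross_tabulate(a = 5, b = 0, c = 0, d = 3))), c(1, 1))
  # empty duplicate margin -> specificity undefined, not silently 0
  est0 <- sensitivity_specificity(cross_tabulate(a = 4, b = 0, c = 0, d = 0))
  expect_true(is.na(est0["specificity"]))
  expect_equal(unname(est0["sensitivity"]), 1)
})

test_that("exact binomial interval reproduces its defining tail equations", {
  # published-precision checks
  expect_equal(round(binom_ci(2296, 2296)[["lower"]], 3), 0.998)
  expect_equal(binom_ci(2296, 2296)[["upper"]], 1)
  expect_equal(round(binom_ci(316, 326), 3),
               c(lower = 0.944, upper = 0.985))
  # boundary closed forms
  expect_equal(binom_ci(0, 10)[["lower"]], 0)
  expect_equal(binom_ci(0, 10)[["upper"]], 1 - 0.025^(1 / 10))
  expect_equal(binom_ci(10, 10)[["lower"]], 0.025^(1 / 10))
  # tail-equation oracle: lower solves P(X >= x | p) = alpha/2,
  # upper solves P(X <= x | p) = alpha/2
  cases <- rbind(c(3, 7), c(1, 10), c(9, 10), c(25, 50), c(316, 326),
                 c(160, 169), c(142, 20083))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]; n <- cases[i, 2]
    ci <- binom_ci(x, n)
    lo <- stats::uniroot(function(p) 1 - pbinom(x - 1, n, p) - 0.025,
                         c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    hi <- stats::uniroot(function(p) pbinom(x, n, p) - 0.025,
                         c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    expect_equal(ci[["lower"]], lo, tolerance = 1e-10)
    expect_equal(ci[["upper"]], hi, tolerance = 1e-10)
  }
  expect_true(all(is.na(binom_ci(0, 0))))
})

test_that("Wilson interval is available and differs where documented", {
  w <- binom_ci(316, 326, method = "wilson")
  e <- binom_ci(316, 326)
  expect_equal(round(w[["upper"]], 3), 0.983)  # vs exact 0.985
  expect_gt(e[["upper"]], w[["upper"]])
})

test_that("Pearson chi-square uses the uncorrected closed form", {
  ct <- cross_tabulate(a = 2296, b = 10, c = 0, d = 316)
  ch <- pearson_chi2(ct)
  expect_equal(round(ch$statistic, 3), 2530.549)
  expect_lt(ch$p_value, 0.001)
  # exact independence
  expect_equal(pearson_chi2(cross_tabulate(a = 10, b = 10, c = 10, d = 10))$statistic, 0)
  # agrees with the expected-count formulation sum (O-E)^2 / E
  set.seed(99)
  for (i in 1:200) {
    cells <- rpois(4, lambda = sample(c(2, 20, 200), 1)) + 1
    ct <- cross_tabulate(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    o <- matrix(cells, 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(pearson_chi2(ct)$statistic, sum((o - e)^2 / e),
                 tolerance = 1e-9)
  }
  # zero margin -> undefined
  expect_true(is.na(pearson_chi2(cross_tabulate(a = 5, b = 0, c = 3, d = 0))$statistic))
})

test_that("single-threshold AUC is the trapezoid closed form", {
  expect_equal(binary_roc_auc(1, 1), 1)
  expect_equal(binary_roc_auc(0.5, 0.5), 0.5)
  expect_equal(binary_roc_auc(1, 0.969), 0.9845)
  # equals numeric trapezoid over the ROC polyline
  sens <- 0.97; spec <- 0.83
  xs <- c(0, 1 - spec, 1); ys <- c(0, sens, 1)
  trap <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  expect_equal(binary_roc_auc(sens, spec), trap)
})

test_that("report formatting matches the stated rounding policy", {
  expect_equal(uidlink:::fmt_pct(0.96933), "96.9%")
  expect_equal(uidlink:::fmt_pct(1), "100%")
  expect_equal(uidlink:::fmt_pct(0.99845, 1), "99.8%")  # round-half-up at 1 dp
  expect_equal(uidlink:::fmt_chi2(2530.5489), "2530.549")
  expect_equal(uidlink:::fmt_p(0.0001), "p < 0.001")
  expect_equal(uidlink:::fmt_p(0.042), "p = 0.042")
  expect_equal(uidlink:::round_half_up(0.5), 1)
  expect_equal(uidlink:::round_half_up(2.5), 3)  # half-up, not banker's
})

test_that("adding a gender-discordant collision record degrades specificity only", {
  for (seed in 1:5) {
    sim <- simulate_roster(roster_config(n_persons = 40, n_records = 70,
                                         collision_pairs = 2, missing_rate = 0,
                                         noise_rate = 0, seed = seed))
    fit <- validate_roster(sim$roster)
    # plant a new individual sharing an existing service number, other gender:
    # pick a number currently observed with a single gender so the flipped
    # record is a genuinely new (gender, number) pair
    single <- names(which(tapply(sim$roster$gender, sim$roster$service_number,
                                 function(g) length(unique(g))) == 1L))[1]
    row1 <- sim$roster[match(single, sim$roster$service_number), ]
    extra <- row1
    extra$gender <- if (row1$gender == "M") "F" else "M"
    aug <- rbind(sim$roster, extra)
    fit2 <- validate_roster(aug)
    expect_lte(fit2$estimates[["specificity"]], fit$estimates[["specificity"]])
    expect_equal(fit2$estimates[["sensitivity"]], 1)
  }
})

test_that("validation object exposes the standard accessor methods", {
  sim <- simulate_roster(roster_config(n_persons = 60, n_records = 100,
                                       collision_pairs = 3, missing_rate = 0,
                                       noise_rate = 0, seed = 2))
  fit <- validate_roster(sim$roster)
  expect_s3_class(fit, "uid_validation")
  expect_named(coef(fit), c("sensitivity", "specificity"))
  ci <- confint(fit)
  expect_equal(rownames(ci), c("sensitivity", "specificity"))
  expect_true(all(ci[, "lower"] <= coef(fit) & coef(fit) <= ci[, "upper"]))
  expect_output(print(fit), "sensitivity 100%")
  expect_output(summary(fit), "Cross-tabulation")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("an empty roster yields flagged-undefined statistics, not zeros", {
  x <- data.frame(gender = NA_character_, service_number = NA_character_)
  fit <- suppressMessages(run_validation(x, quiet = TRUE))
  expect_equal(unname(fit$counts["n_clean"]), 0L)
  expect_true(all(is.na(fit$estimates)))
  expect_true(is.na(fit$chi2$statistic))
  expect_true(is.na(fit$auc))
})
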