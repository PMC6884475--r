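test_that("all F statistics vanish on effect-free data", {
  null_tbl <- tibble::tibble(
    participant = rep(sprintf("p%d", 1:6), each = 2),
    group = rep(c("A", "A", "B", "B", "C", "C"), each = 2),
    phase = rep(c("first", "last"), 6),
    value = rep(rep(c(1, 2), each = 2), 3)  # same subject spread per group
  )
  out <- tidy(mixed_anova(null_tbl))
  expect_equal(out$statistic, c(0, 0, 0))
})

test_that("mixed ANOVA matches the independent reference fit on the 6-participant fixture", {
  fx <- anova_fixture()
  out <- tidy(mixed_anova(fx))
  frozen <- anova_fixture_expected
  expect_equal(out$statistic[1], frozen$f_group, tolerance = 1e-6)
  expect_equal(out$statistic[2], frozen$f_phase, tolerance = 1e-6)
  expect_equal(out$statistic[3], frozen$f_interaction, tolerance = 1e-6)
  expect_equal(out$df1, c(2, 1, 2))
  expect_equal(out$df2, c(3, 3, 3))

  # recompute the oracle in-session as well
  fit <- stats::aov(value ~ group * phase + Error(factor(participant) / phase),
                    data = fx)
  s <- summary(fit)
  expect_equal(out$statistic[1],
               s[["Error: factor(participant)"]][[1]]["group", "F value"],
               tolerance = 1e-9)
  expect_equal(out$statistic[3],
               s[["Error: factor(participant):phase"]][[1]]["group:phase",
                                                            "F value"],
               tolerance = 1e-9)

  # decomposition: SS_total equals the sum of all components
  an <- mixed_anova(fx)
  ss_sum <- sum(an$table$ss) + an$table$ss_error[1] + an$table$ss_error[2]
  expect_equal(ss_sum, an$ss_total, tolerance = 1e-8 * an$ss_total)
})

test_that("the full 3x15 design reports the published degrees of freedom", {
  tbl <- simulate_null_table(n_per_group = 15, seed = 5)
  out <- tidy(mixed_anova(tbl))
  expect_equal(out$df1, c(2, 1, 2))
  expect_equal(out$df2, c(42, 42, 42))
  expect_equal(out$gg_epsilon[2:3], c(1, 1))  # vacuous at two within levels
})

test_that("unbalanced or incomplete designs are rejected", {
  tbl <- simulate_null_table(n_per_group = 4, seed = 6)
  expect_error(mixed_anova(tbl[-1, ]), "within level")
  tbl2 <- tbl
  tbl2$group[tbl2$participant == "ND01"] <- "VO"
  expect_error(mixed_anova(tbl2), "balanced")
})

test_that("Greenhouse-Geisser epsilon follows Box's formula and its bounds", {
  expect_equal(gg_epsilon(matrix(c(2, 0.3, 0.3, 1), 2, 2)), 1)

  # compound symmetry at k = 3: sphericity holds, epsilon = 1
  cs <- matrix(0.4, 3, 3); diag(cs) <- 1.3
  expect_equal(gg_epsilon(cs), 1)

  # fixed non-spherical 3x3: independent evaluation via the eigenvalues of
  # the double-centered covariance
  S <- matrix(c(1.0, 0.5, 0.1, 0.5, 1.2, 0.3, 0.1, 0.3, 2.0), 3, 3)
  C <- diag(3) - 1 / 3
  lam <- eigen(C %*% S %*% C, symmetric = TRUE)$values
  expect_equal(gg_epsilon(S), sum(lam)^2 / (2 * sum(lam^2)),
               tolerance = 1e-12)

  # bounds on random PSD matrices
  set.seed(8)
  for (k in c(3, 4, 5)) {
    for (rep in 1:20) {
      X <- matrix(rnorm(6 * k), 6, k)
      eps <- gg_epsilon(crossprod(X) / 5)
      expect_gte(eps, 1 / (k - 1))
      expect_lte(eps, 1)
    }
  }
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("simple main effects use the published df conventions", {
  tbl <- simulate_null_table(n_per_group = 15, seed = 9)
  se <- simple_main_effects(tbl)
  within_rows <- se[se$effect == "phase", ]
  expect_equal(unique(within_rows$df1), 1)
  expect_equal(unique(within_rows$df2), 14)
  between_rows <- se[se$effect == "group", ]
  expect_equal(unique(between_rows$df1), 2)
  expect_equal(unique(between_rows$df2), 42)

  # zero-noise null fixture: every simple-effect F is 0
  null_tbl <- tibble::tibble(
    participant = rep(sprintf("p%d", 1:6), each = 2),
    group = rep(c("A", "A", "B", "B", "C", "C"), each = 2),
    phase = rep(c("first", "last"), 6),
    value = rep(rep(c(1, 2), each = 2), 3)
  )
  expect_true(all(simple_main_effects(null_tbl)$statistic == 0))

  expect_identical(nrow(simple_main_effects(tbl,
                                            significant_interaction = FALSE)),
                   0L)
})

test_that("Shaffer's procedure reproduces the k = 3 threshold sequence", {
  out <- shaffer_multicomp(c(0.001, 0.04, 0.2), k_groups = 3)
  expect_equal(out$multiplier[order(out$p.value)], c(3, 1, 1))
  expect_equal(out$reject, c(TRUE, TRUE, FALSE))

  expect_false(any(shaffer_multicomp(rep(1, 3), k_groups = 3)$reject))

  # sequential stopping: smallest p above alpha/3 blocks everything
  blocked <- shaffer_multicomp(c(0.02, 0.03, 0.04), k_groups = 3)
  expect_false(any(blocked$reject))

  expect_error(shaffer_multicomp(c(-0.1, 0.5, 0.2), k_groups = 3), "0, 1")
  expect_error(shaffer_multicomp(c(0.1, 0.5), k_groups = 3), "pairwise")
})

test_that("Shaffer rejects at least everything Holm rejects", {
  set.seed(10)
  for (rep in 1:200) {
    p <- runif(3)^2
    shaffer <- shaffer_multicomp(p, k_groups = 3)$reject
    holm <- stats::p.adjust(p, method = "holm") <= 0.05
    expect_true(all(shaffer[holm]))
  }
})

test_that("analyze_experiment runs both planned ANOVAs and triggers follow-ups", {
  metrics <- synthetic_metrics()
  res <- analyze_experiment(metrics)
  expect_s3_class(res, "lk_analysis")
  expect_named(res$results, c("sdlp", "swv"))
  expect_named(res$results$sdlp, c("training", "interference"))

  training_sdlp <- res$results$sdlp$training
  expect_lt(training_sdlp$anova$table$p.value[3], 0.05)
  expect_false(is.null(training_sdlp$simple_effects))
  expect_true(all(c("comparison", "multiplier", "p.adjusted", "reject") %in%
                    names(training_sdlp$comparisons)))

  # deterministic given the metrics table, including through CSV round trip
  res2 <- analyze_experiment(metrics)
  expect_identical(tidy(res), tidy(res2))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  res3 <- analyze_experiment(tibble::as_tibble(utils::read.csv(path)))
  expect_equal(tidy(res), tidy(res3), tolerance = 1e-12)

  expect_error(analyze_experiment(metrics[metrics$session != "posttest", ]),
               "posttest")
})
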