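# delayed-entry Cox fits and per-region testing

test_that("Cox optimum matches the grid-search partial-likelihood oracle", {
  d <- exp_fixture(n = 40, hr = 2, seed = 7)
  fit <- fit_cox(d, "x")
  expect_gt(fit$hr, 1.2); expect_lt(fit$hr, 3.3)
  grid <- seq(-2, 2, by = 0.001)
  pll <- vapply(grid, cox_pll, 0, entry = d$entry_age, exit = d$exit_age,
                event = d$event, x = d$x)
  expect_equal(cox_pll(fit$log_hr, d$entry_age, d$exit_age, d$event, d$x),
               max(pll), tolerance = 1e-4)
  expect_lt(abs(grid[which.max(pll)] - fit$log_hr), 0.001)
  # Wald CI reconstruction identity
  expect_equal(fit$ci_low, exp(fit$log_hr - 1.959964 * fit$se_log_hr))
  expect_equal(fit$ci_high, exp(fit$log_hr + 1.959964 * fit$se_log_hr))
})

test_that("risk sets honour delayed entry (hand-built 5-subject table)", {
  # subjects: (entry, exit, event, x)
  d <- data.frame(entry_age = c(0, 2, 4, 1, 3),
                  exit_age = c(5, 6, 7, 3.5, 8),
                  event = c(1, 1, 1, 1, 0),
                  x = c(1, 0, 1, 0, 1))
  # event at t=3.5: at risk {1 (0<3.5<=5), 2, 4, 5 (3<3.5<=8)}; 3 enters at 4
  # event at t=5: at risk {1, 2, 3, 5}
  # event at t=6: at risk {2, 3, 5}
  # event at t=7: at risk {3, 5}
  beta <- 0.3
  ebx <- exp(beta * d$x)
  hand <- (beta * d$x[4] - log(ebx[1] + ebx[2] + ebx[4] + ebx[5])) +
    (beta * d$x[1] - log(ebx[1] + ebx[2] + ebx[3] + ebx[5])) +
    (beta * d$x[2] - log(ebx[2] + ebx[3] + ebx[5])) +
    (beta * d$x[3] - log(ebx[3] + ebx[5]))
  expect_equal(cox_pll(beta, d$entry_age, d$exit_age, d$event, d$x), hand)
  # and coxph agrees with the oracle's optimum on these data
  fit <- fit_cox(d, "x")
  o <- optimize(function(b) -cox_pll(b, d$entry_age, d$exit_age, d$event, d$x),
                c(-5, 5), tol = 1e-9)
  expect_equal(fit$log_hr, o$minimum, tolerance = 1e-6)
})

test_that("degenerate inputs are refused with clear errors", {
  d <- exp_fixture(40, 2, 1)
  d$z <- 1
  expect_error(fit_cox(d, "z"), "degenerate")
  d0 <- d; d0$event <- 0
  expect_error(fit_cox(d0, "x"), "no events")
  expect_error(fit_cox(d, "missing_col"), "not found")
})

test_that("constant adjustment covariates are dropped, not fatal", {
  d <- exp_fixture(40, 2, 2)
  d$sex <- "female"
  expect_message(fit_cox(d, "x", adjustments = "sex"), "constant adjustment")
})

test_that("type-I error is close to nominal under the null", {
  # 400 null replicates here (the 1000-replicate version runs in the
  # acceptance suite); binomial 3-sigma band around 0.05
  set.seed(61)
  rej <- 0L
  n_rep <- 400L
  for (r in seq_len(n_rep)) {
    d <- exp_fixture(n = 100, hr = 1, seed = 5000 + r)
    if (fit_cox(d, "x")$p <= 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_rep, 0.05 - 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(rej / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("cluster-robust standard errors respond to family clustering", {
  set.seed(71)
  cc <- cohort_config(n_samples = 400, seed = 8)
  ph <- simulate_survival(cc, data.frame(sample_id = sprintf("S%04d", 1:400),
                                         grp = rep(0:1, 200)))
  # duplicate subjects into families of two: robust SE must differ from naive
  ph2 <- rbind(ph, ph)
  ph2$family_id <- rep(ph$family_id, 2)
  naive <- fit_cox(ph2, "grp")
  robust <- fit_cox(ph2, "grp", cluster_col = "family_id")
  expect_equal(robust$log_hr, naive$log_hr, tolerance = 1e-8)
  expect_gt(robust$se_log_hr / naive$se_log_hr, 1.2)
})

test_that("test_regions ranks a planted region first and skips degenerates", {
  set.seed(81)
  n <- 600
  samples <- sprintf("S%04d", 1:n)
  cmat <- cbind(r_plant = as.integer(runif(n) < 0.065),
                r_null1 = as.integer(runif(n) < 0.05),
                r_null2 = as.integer(runif(n) < 0.08))
  rownames(cmat) <- samples
  wins <- 0L
  for (r in 1:20) {
    cc <- cohort_config(n_samples = n, log_hr_per_covariate = c(carrier0 = 0.35),
                        seed = 300 + r)
    ph <- simulate_survival(cc, data.frame(sample_id = samples,
                                           carrier0 = cmat[, "r_plant"]))
    res <- test_regions(cmat, ph)
    if (res$region_id[1] == "r_plant") wins <- wins + 1L
  }
  expect_gte(wins / 20, 0.8)

  # all-ones column is degenerate and must be skipped with a message
  cm2 <- cbind(cmat, r_ones = 1L)
  cc <- cohort_config(n_samples = n, seed = 999)
  ph <- simulate_survival(cc, data.frame(sample_id = samples, stringsAsFactors = FALSE))
  expect_message(res2 <- test_regions(cm2, ph), "degenerate")
  expect_false("r_ones" %in% res2$region_id)
  expect_error(test_regions(cmat[1:10, , drop = FALSE],
                            ph[!ph$sample_id %in% samples[1:5], ]),
               "absent from phenotype")
})

test_that("permutation null gives uniform region p-values", {
  set.seed(91)
  n <- 400
  samples <- sprintf("S%04d", 1:n)
  cc <- cohort_config(n_samples = n, seed = 17)
  ph <- simulate_survival(cc, data.frame(sample_id = samples, stringsAsFactors = FALSE))
  cmat <- sapply(1:60, function(j) as.integer(runif(n) < runif(1, 0.05, 0.3)))
  colnames(cmat) <- sprintf("r%02d", 1:60); rownames(cmat) <- samples
  res <- test_regions(cmat, ph)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
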