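make_design <- function() {
  expand.grid(x = c(0.5, 2, 5.5, 11.5, 26.5, 40),
              y = c(0, 5, 10, 15, 20, 25, 30),
              z = c(2, 4, 8, 16, 32, 50))
}

test_that("noiseless generated records recover the published coefficients exactly", {
  truth <- vmsbr_coefficients()
  d <- make_design()
  d$w <- vmsbr_threshold(d$x, d$y, d$z, truth)
  fit <- vmsbr_fit(d)
  expect_equal(as.numeric(coef(fit)), as.numeric(truth), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  ## generate -> fit -> regenerate round trip
  expect_equal(predict(fit, d), log(d$w), tolerance = 1e-10)

  rc_truth <- rc_coefficients()
  d2 <- expand.grid(x = c(0.5, 2, 5.5, 26.5), y = c(0, 10, 20, 30))
  d2$rc <- recovery_coefficient(d2$x, d2$y, rc_truth)
  fit2 <- rc_fit(d2)
  expect_equal(as.numeric(coef(fit2)), as.numeric(rc_truth), tolerance = 1e-8)
  expect_equal(predict(fit2, d2), d2$rc, tolerance = 1e-10)
})

test_that("noisy fits recover coefficients within their standard errors", {
  truth <- vmsbr_coefficients()
  d <- make_design()[1:252, ]
  X <- cbind(d$x^(1/3), d$y^(1/3), log(d$z), d$x^(1/3) * log(d$z),
             d$y^(1/3) * log(d$z), (d$x * d$y)^(1/3), 1)
  sigma <- 0.05
  se <- sigma * sqrt(diag(solve(crossprod(X))))
  set.seed(42)
  hits <- replicate(20, {
    d$log_w <- drop(X %*% as.numeric(truth)) + rnorm(nrow(d), 0, sigma)
    fit <- vmsbr_fit(d)
    all(abs(as.numeric(coef(fit)) - as.numeric(truth)) <= 3 * se)
  })
  ## P(|err| < 3 SE) ~ 0.997 per coefficient; all 7 jointly ~ 0.98
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate designs raise informative fitting errors", {
  d <- make_design()[1:6, ]
  d$w <- vmsbr_threshold(d$x, d$y, d$z)
  expect_error(vmsbr_fit(d), "at least 7")
  ## motion-free records: every y-dependent RC term collapses
  d2 <- data.frame(x = c(1, 2, 4, 8, 16), y = 0)
  d2$rc <- recovery_coefficient(d2$x, d2$y)
  expect_error(rc_fit(d2), "collinear.*y", perl = TRUE)
  ## single volume value: 1/x collinear with the intercept
  d3 <- data.frame(x = 2, y = c(0, 5, 10, 15, 20))
  d3$rc <- recovery_coefficient(d3$x, d3$y)
  expect_error(rc_fit(d3), "collinear")
  expect_error(vmsbr_fit(data.frame(x = 1, y = 1)), "z")
})

test_that("fitted model objects expose the standard methods", {
  d <- make_design()
  set.seed(7)
  d$log_w <- vmsbr_log_threshold(d$x, d$y, d$z) + rnorm(nrow(d), 0, 0.02)
  fit <- vmsbr_fit(d)
  expect_s3_class(coef(fit), "vmsbr_coefficients")
  expect_length(residuals(fit), nrow(d))
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-10)  # OLS with intercept
  expect_true(fit$r_squared > 0.99 && fit$r_squared <= 1)
  s <- summary(fit)
  expect_s3_class(s, "summary.threshold_model_fit")
  expect_output(print(fit), "VMSBR")
  expect_output(print(s), "R\\^2")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3L))
  ## w-scale predictions exponentiate the log predictions
  expect_equal(predict(fit, d, type = "w"), exp(predict(fit, d)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("simulator-driven recovery records support an accurate RC fit", {
  ## measured SBR from simulated images (no threshold scan needed): the
  ## fitted RC surface should predict held-out degradation ratios well
  grid <- expand.grid(d = c(10, 13, 17, 22, 28, 37), y = c(0, 5, 10, 15, 20, 25))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- lesion_phantom(sphere_volume_cm3(grid$d[i]), grid$y[i], 10,
                           spacing_mm = c(2.5, 2.5, 2.5))
    run <- vmsbr_segment_phantom(spec, mesh_separation = FALSE)
    data.frame(x = sphere_volume_cm3(grid$d[i]), y = grid$y[i],
               rc = 10 / run$sbr$degraded_sbr)
  })
  rec <- do.call(rbind, rows)
  ## leave-one-out cross-validated predictive quality (deterministic)
  press <- vapply(seq_len(nrow(rec)), function(i) {
    f <- rc_fit(rec[-i, ])
    predict(f, rec[i, ]) - rec$rc[i]
  }, 0)
  r2_loo <- 1 - sum(press^2) / sum((rec$rc - mean(rec$rc))^2)
  expect_gt(r2_loo, 0.9)
  fit <- rc_fit(rec)
  expect_gt(fit$r_squared, 0.9)
  ## recovery improves the measurement wherever correction is predicted
  ## upward (the noiseless linear blur chain only ever under-measures SBR)
  improves <- abs(predict(fit, rec) - rec$rc) < abs(1 - rec$rc)
  expect_gte(mean(improves), 0.9)
})
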