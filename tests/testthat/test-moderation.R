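# Moderated regression, Johnson-Neyman regions, stratified profiles.

gen_mod_data <- function(n, b0 = 60, b1 = -50, b2 = -5, b3 = -40,
                         noise_sd = 2, carrier_p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n, 0.15, 0.05)
  w <- rbinom(n, 1, carrier_p)
  age <- rnorm(n, 68, 8)
  edu <- rnorm(n, 13, 5)
  y <- b0 + b1 * x + b2 * w + b3 * x * w - 0.3 * (age - 68) +
    rnorm(n, sd = noise_sd)
  data.frame(y = y, x = x, w = w, age = age, education = edu)
}

fake_fit <- function(b2, b3, v22, v33, v23, df = 200) {
  cf <- c(b0 = 0, b1 = 0, b2 = b2, b3 = b3)
  V <- diag(1e-4, 4)
  dimnames(V) <- list(names(cf), names(cf))
  V["b2", "b2"] <- v22
  V["b3", "b3"] <- v33
  V["b2", "b3"] <- V["b3", "b2"] <- v23
  structure(list(coefficients = cf, vcov = V, df = df),
            class = "moderation_fit")
}

test_that("a noiseless design is fit exactly with the exact delta R2", {
  d <- gen_mod_data(80, noise_sd = 0, seed = 1)
  f <- suppressWarnings(   # lm warns about the intentionally perfect fit
    fit_moderation(d$y, d$x, d$w, d[, c("age", "education")])
  )
  expect_lt(max(abs(residuals(f))), 1e-8)
  expect_equal(f$R2_full, 1, tolerance = 1e-10)
  red <- lm(y ~ x + w + age + education, data = d)
  expect_equal(f$delta_R2, 1 - summary(red)$r.squared, tolerance = 1e-8)
  expect_equal(unname(coef(f)[c("b1", "b2", "b3")]), c(-50, -5, -40),
               tolerance = 1e-8)
})

test_that("delta R2 equals the squared semipartial correlation of x:w", {
  d <- gen_mod_data(150, noise_sd = 6, seed = 2)
  f <- fit_moderation(d$y, d$x, d$w, d[, c("age", "education")])
  # squared semipartial: correlation of y with the part of x:w orthogonal
  # to every other predictor
  e <- residuals(lm(I(x * w) ~ x + w + age + education, data = d))
  sr2 <- cor(d$y, e)^2
  expect_equal(f$delta_R2, sr2, tolerance = 1e-8)
  expect_gte(f$delta_R2, 0)
  expect_equal(f$vcov, t(f$vcov))
})

test_that("interaction p-values are uniform when no moderation is planted", {
  set.seed(7)
  ps <- replicate(1000, {
    d <- gen_mod_data(60, b3 = 0, noise_sd = 4)
    f <- fit_moderation(d$y, d$x, d$w, d$age)
    f$table["b3", "Pr(>|t|)"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted coefficients are recovered within 3 SE", {
  set.seed(13)
  ok <- replicate(20, {
    d <- gen_mod_data(250, noise_sd = 2)
    f <- fit_moderation(d$y, d$x, d$w, d[, c("age", "education")])
    se <- sqrt(diag(f$vcov))
    all(abs(coef(f)[c("b1", "b2", "b3")] - c(-50, -5, -40)) <=
          3 * se[c("b1", "b2", "b3")])
  })
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate moderation designs are rejected", {
  d <- gen_mod_data(50, seed = 3)
  expect_error(fit_moderation(d$y, d$x, rep(0, 50), d$age), "both values")
  expect_error(fit_moderation(d$y, d$x, factor(rep("c", 50)), d$age),
               "two levels")
  expect_error(fit_moderation(d$y[1:5], d$x[1:5], d$w[1:5]), "at least 10")
  expect_error(fit_moderation(d$y, d$x, d$w, data.frame(a = d$x, b = d$x)),
               "collinear")
})

test_that("Johnson-Neyman thresholds satisfy |t| = t_crit and match grid probing", {
  d <- gen_mod_data(220, b3 = -60, noise_sd = 8, seed = 21)
  f <- fit_moderation(d$y, d$x, d$w, d[, c("age", "education")])
  jn <- johnson_neyman(f)
  expect_s3_class(jn, "jn_region")
  expect_gt(length(jn$thresholds), 0)
  for (thr in jn$thresholds)
    expect_lt(abs(abs(jn$theta_t(thr)) - jn$t_crit), 1e-6)
  # dense grid-probing oracle over a wide x range
  xs <- seq(-2, 2, length.out = 1e5)
  tv <- abs(jn$theta_t(xs)) - jn$t_crit
  crossings <- xs[which(diff(sign(tv)) != 0)]
  expect_equal(length(crossings), length(jn$thresholds))
  expect_true(all(abs(sort(crossings) - sort(jn$thresholds)) < 1e-4))
})

test_that("JN handles the closed-form and degenerate special cases", {
  # b3 = 0 with significant b2: no finite threshold, significant everywhere
  f0 <- fake_fit(b2 = 5, b3 = 0, v22 = 0.25, v33 = 0, v23 = 0)
  jn0 <- johnson_neyman(f0)
  expect_length(jn0$thresholds, 0)
  expect_match(jn0$direction, "everywhere")
  # b2 = 0, cov = 0: symmetric closed-form thresholds
  f1 <- fake_fit(b2 = 0, b3 = 2, v22 = 1, v33 = 0.04, v23 = 0)
  jn1 <- johnson_neyman(f1)
  tc <- jn1$t_crit
  want <- sqrt(tc^2 * 1 / (4 - tc^2 * 0.04))
  expect_equal(sort(jn1$thresholds), c(-want, want), tolerance = 1e-6)
  expect_match(jn1$direction, "outside")
  expect_error(johnson_neyman(fake_fit(1, 1, v22 = -1, v33 = 1, v23 = 0)),
               "variance")
})

test_that("flipping the planted interaction flips the conditional-effect sign", {
  dneg <- gen_mod_data(300, b2 = -8, b3 = -80, noise_sd = 4, seed = 31)
  dpos <- gen_mod_data(300, b2 = 8, b3 = 80, noise_sd = 4, seed = 31)
  fn <- fit_moderation(dneg$y, dneg$x, dneg$w, dneg$age)
  fp <- fit_moderation(dpos$y, dpos$x, dpos$w, dpos$age)
  jnn <- johnson_neyman(fn)
  jnp <- johnson_neyman(fp)
  expect_gt(length(jnn$thresholds), 0)
  expect_gt(length(jnp$thresholds), 0)
  # beyond the upper threshold the genotype effect is significant in both
  # fits, with opposite sign
  xhi_n <- max(jnn$thresholds) + 0.05
  xhi_p <- max(jnp$thresholds) + 0.05
  expect_lt(jnn$theta_t(xhi_n), -jnn$t_crit)
  expect_gt(jnp$theta_t(xhi_p), jnp$t_crit)
})

test_that("the x-across-w probe reports both moderator levels", {
  d <- gen_mod_data(150, seed = 41)
  f <- fit_moderation(d$y, d$x, d$w, d$age)
  jn <- johnson_neyman(f, probe = "x_across_w")
  expect_named(jn$at, c("w=0", "w=1"))
  expect_equal(unname(jn$at[["w=1"]][["effect"]]),
               unname(coef(f)["b1"] + coef(f)["b3"]), tolerance = 1e-10)
})

test_that("stratified profile finds moderation only where it is planted", {
  set.seed(61)
  hits_ci <- 0
  hits_mci <- 0
  for (r in 1:50) {
    ci <- gen_mod_data(261, b3 = -100, noise_sd = 10)
    mci <- gen_mod_data(118, b3 = 0, noise_sd = 10)
    cohort <- rbind(
      data.frame(group = "CI", ci),
      data.frame(group = "MCI", mci)
    )
    cohort$apoe_e4 <- ifelse(cohort$w == 1, "carrier", "noncarrier")
    cohort$apoe_genotype <- ifelse(cohort$w == 1, "e3e4", "e3e3")
    cohort$delayed_recall <- cohort$y
    prof <- subgroup_moderation_profile(cohort, cohort$x)
    p_ci <- prof$fits$CI$fit$table["b3", "Pr(>|t|)"]
    p_mci <- prof$fits$MCI$fit$table["b3", "Pr(>|t|)"]
    if (p_ci < 0.05) hits_ci <- hits_ci + 1
    if (p_mci > 0.05) hits_mci <- hits_mci + 1
  }
  expect_gte(hits_ci / 50, 0.8)
  expect_gte(hits_mci / 50, 0.8)
})

test_that("rare genotypes are excluded before stratified fits", {
  d <- gen_mod_data(200, seed = 71)
  cohort <- data.frame(group = "CI", d)
  cohort$apoe_e4 <- ifelse(cohort$w == 1, "carrier", "noncarrier")
  cohort$apoe_genotype <- ifelse(cohort$w == 1, "e3e4", "e3e3")
  cohort$apoe_genotype[1:40] <- "e2e3"
  cohort$apoe_e4[1:40] <- NA
  cohort$delayed_recall <- cohort$y
  prof <- subgroup_moderation_profile(cohort, cohort$x)
  expect_equal(prof$fits$CI$fit$n, 160)
  expect_equal(sum(prof$rho_table$n), 160)
  # all noncarriers: single-level moderator rejected (group skipped)
  cohort2 <- cohort
  cohort2$apoe_genotype <- "e3e3"
  cohort2$apoe_e4 <- "noncarrier"
  w <- capture_warnings(p2 <- subgroup_moderation_profile(cohort2, cohort2$x))
  expect_true(any(grepl("skipped", w)))
  expect_null(p2$fits$CI)
})
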