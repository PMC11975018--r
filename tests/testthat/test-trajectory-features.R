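test_that("transform_feature applies the spec transform and guards domain", {
  sq <- feature_spec("f")
  expect_identical(transform_feature(c(25, 0, NA), sq), c(5, 0, NA))
  none <- feature_spec("f", transform = "none")
  expect_identical(transform_feature(c(1.5, NA, 2), none), c(1.5, NA, 2))
  expect_error(transform_feature(c(4, -1), sq), "negative value")
  expect_error(feature_spec("f", "sqrt", nonneg = FALSE), "non-negativity")
})

test_that("fixed effects are recovered when random effects are absent", {
  # truth: beta = (2, 0.5, -0.1), G = 0, sigma^2 = 1, n = 400; identity
  # transform so the oracle is exactly Gaussian (no clamping)
  set.seed(101)
  n <- 400; tt <- 0:3
  lat <- matrix(2 + 0.5 * rep(tt, each = n) - 0.1 * rep(tt^2, each = n) +
                  rnorm(n * 4), n)
  panel <- data.frame(pid = rep(sprintf("S%04d", seq_len(n)), each = 4),
                      visit_month = rep(c(0, 6, 12, 18), times = n),
                      score = as.vector(t(lat)))
  class(panel) <- c("mlbpsp_panel", "data.frame")
  fit <- fit_feature_lmm(panel, feature_spec("score", transform = "none"))
  # tolerance: 3 x the OLS standard errors on the same data (true G = 0)
  d <- data.frame(y = panel$score, t = panel$visit_month / 6)
  se <- summary(lm(y ~ t + I(t^2), d))$coefficients[, 2]
  expect_true(all(abs(fit$beta - c(2, 0.5, -0.1)) < 3 * se))
  # the unstructured-G ML fit matches the empirical 4x4 marginal covariance,
  # so individual components trade off; the identified quantity is the
  # implied marginal covariance V = Z G Z' + sigma^2 I, which must be close
  # to the true sigma^2 I (each sample (co)variance has sd ~ sqrt(2/n))
  Z <- cbind(1, 0:3, (0:3)^2)
  V <- Z %*% fit$G %*% t(Z) + fit$sigma2 * diag(4)
  expect_lt(max(abs(V - diag(4))), 3.5 * sqrt(2 / n))
})

test_that("a perfectly constant feature yields the degenerate fit", {
  lat <- matrix(3, 20, 4)  # raw value 9 everywhere
  panel <- panel_from_latent(lat)
  fit <- fit_feature_lmm(panel, feature_spec("bdi_cognitive"))
  expect_equal(fit$beta, c(3, 0, 0))
  expect_true(all(fit$ranef[c("intercept", "slope", "quad")] == 0))
  expect_true(fit$degenerate)
})

test_that("fewer than 3 distinct visit times is a hard error", {
  lat <- matrix(rnorm(40, 5), 20, 2)
  panel <- panel_from_latent(lat, visit_months = c(0, 6))
  expect_error(fit_feature_lmm(panel, feature_spec("bdi_cognitive")),
               "distinct visit times")
})

test_that("empirical-Bayes effects equal the closed-form conditional means", {
  set.seed(7)
  arch <- phenotype_archetype(1, 1, list(bdi_cognitive = c(4, 0.3, -0.05)),
                              G = diag(c(0.5, 0.05, 0.01)), sigma = 0.4)
  cfg <- cohort_config(n_participants = 60, seed = 7)
  panel <- apply_missingness(simulate_cohort(cfg, list(arch)), cfg)
  fit <- fit_feature_lmm(panel, feature_spec("bdi_cognitive"))
  oracle <- eb_oracle(panel, "bdi_cognitive", fit)
  got <- as.matrix(fit$ranef[c("intercept", "slope", "quad")])
  rownames(got) <- fit$ranef$pid
  expect_lt(max(abs(got[rownames(oracle), ] - oracle)), 1e-4)
  # mean of EB effects ~ 0 and shrinkage: var(b0_hat) <= G[1,1]
  expect_lt(max(abs(colMeans(got))), 0.05)
  expect_lte(var(got[, 1]), fit$G[1, 1] + 1e-8)
})

test_that("random-intercept-only fits match the scalar shrinkage formula", {
  # balanced data, G = diag(tau^2, 0, 0): b0_hat = tau^2/(tau^2 + s^2/n_i) * r_i
  set.seed(15)
  n <- 80; tau <- 0.8; s <- 0.5
  b0 <- rnorm(n, sd = tau)
  lat <- 5 + outer(b0, rep(1, 4)) + matrix(rnorm(n * 4, sd = s), n)
  panel <- panel_from_latent(lat)
  fit <- fit_feature_lmm(panel, feature_spec("bdi_cognitive"))
  oracle <- eb_oracle(panel, "bdi_cognitive", fit)
  got <- as.matrix(fit$ranef[c("intercept", "slope", "quad")])
  rownames(got) <- fit$ranef$pid
  expect_lt(max(abs(got[rownames(oracle), ] - oracle)), 1e-4)
  # hand-computed scalar special case at the fitted variance components,
  # valid when the fitted slope variances collapse to ~0
  if (max(diag(fit$G)[2:3]) < 1e-4) {
    d <- data.frame(y = sqrt(panel$bdi_cognitive), t = panel$visit_month / 6,
                    pid = panel$pid)
    resid_means <- tapply(d$y - cbind(1, d$t, d$t^2) %*% fit$beta, d$pid, mean)
    shrink <- fit$G[1, 1] / (fit$G[1, 1] + fit$sigma2 / 4)
    expect_lt(max(abs(got[names(resid_means), 1] - shrink * resid_means)), 0.02)
  }
})

test_that("ML estimates agree with a brute-force profiled likelihood grid", {
  # intercept-only truth; the grid oracle maximizes the exact marginal
  # likelihood of the random-intercept model over (tau, sigma) with profiled
  # GLS fixed effects. The full quadratic-G model nests it, so its ML
  # log-likelihood must match or exceed the grid optimum.
  set.seed(33)
  n <- 30; tau <- 1; s <- 0.6
  lat <- 5 + outer(rnorm(n, sd = tau), rep(1, 4)) + matrix(rnorm(n * 4, sd = s), n)
  panel <- panel_from_latent(lat)
  d <- data.frame(y = sqrt(panel$bdi_cognitive), t = panel$visit_month / 6)
  X <- cbind(1, d$t, d$t^2)
  y <- matrix(d$y, ncol = 4, byrow = TRUE)
  loglik_ri <- function(tau2, s2) {
    Vi <- matrix(tau2, 4, 4) + s2 * diag(4)
    Vinv <- solve(Vi)
    Xi <- cbind(1, 0:3, (0:3)^2)
    A <- n * t(Xi) %*% Vinv %*% Xi
    bvec <- t(Xi) %*% Vinv %*% colSums(y)
    beta <- solve(A, bvec)
    r <- sweep(y, 2, Xi %*% beta)
    -0.5 * (n * determinant(Vi)$modulus + sum((r %*% Vinv) * r) +
              4 * n * log(2 * pi))
  }
  grid <- expand.grid(tau2 = seq(0.2, 2.5, by = 0.01),
                      s2 = seq(0.1, 0.9, by = 0.01))
  ll <- mapply(loglik_ri, grid$tau2, grid$s2)
  fit <- fit_feature_lmm(panel, feature_spec("bdi_cognitive"))
  ll_fit <- {
    # marginal log-likelihood of the fitted model, computed independently
    total <- 0
    Xi <- cbind(1, 0:3, (0:3)^2)
    Vi <- Xi %*% fit$G %*% t(Xi) + fit$sigma2 * diag(4)
    Vinv <- solve(Vi)
    r <- sweep(y, 2, Xi %*% fit$beta)
    -0.5 * (n * determinant(Vi)$modulus + sum((r %*% Vinv) * r) +
              4 * n * log(2 * pi))
  }
  expect_gte(ll_fit, max(ll) - 1e-3)
  # the quadratic-G model is more flexible than the grid model, so its
  # variance split can drift; it must still sit near the grid optimum
  best <- grid[which.max(ll), ]
  expect_lt(abs(fit$G[1, 1] - best$tau2), 0.2)
  expect_lt(abs(fit$sigma2 - best$s2), 0.1)
  expect_lt(max(abs(fit$beta - c(5, 0, 0))), 3 * 1 / sqrt(n))
})

test_that("estimates are stable under 20% MCAR row deletion", {
  set.seed(51)
  arch <- phenotype_archetype(1, 1, list(bdi_cognitive = c(4, 0.4, -0.08)),
                              G = diag(c(0.4, 0.04, 0.005)), sigma = 0.3)
  cfg <- cohort_config(n_participants = 400, miss_visit_rates = rep(0, 4),
                       item_miss_rate = 0, seed = 51)
  panel <- simulate_cohort(cfg, list(arch))
  fit_full <- fit_feature_lmm(panel, feature_spec("bdi_cognitive"))
  drop <- sample(nrow(panel), round(0.2 * nrow(panel)))
  panel_thin <- panel[-drop, ]
  class(panel_thin) <- class(panel)
  fit_thin <- fit_feature_lmm(panel_thin, feature_spec("bdi_cognitive"))
  expect_lt(max(abs(fit_full$beta - fit_thin$beta)), 0.1)
})

test_that("fits are deterministic", {
  set.seed(1)
  lat <- 4 + matrix(rnorm(200), 50, 4)
  panel <- panel_from_latent(lat)
  f1 <- fit_feature_lmm(panel, feature_spec("bdi_cognitive"))
  f2 <- fit_feature_lmm(panel, feature_spec("bdi_cognitive"))
  expect_identical(f1, f2)
})

test_that("random-effects matrix assembles 3 columns per feature with fallback", {
  fake_fit <- function(feature, pids, values) {
    structure(list(feature = feature,
                   ranef = data.frame(pid = pids, intercept = values,
                                      slope = values / 2, quad = values / 4)),
              class = "mlbpsp_lmm_fit")
  }
  pids <- sprintf("S%02d", 1:5)
  fits <- lapply(paste0("f", 1:17), fake_fit, pids = pids, values = 1:5)
  M <- extract_random_effects(fits)
  expect_equal(dim(M), c(5, 51))
  expect_match(colnames(M)[1:3], "__(intercept|slope|quad)$")

  # single feature with all-zero effects
  M0 <- extract_random_effects(list(fake_fit("f", pids, rep(0, 5))))
  expect_true(all(M0 == 0) && ncol(M0) == 3)

  # participant never observed for one feature: prior-mean fallback + provenance
  fits2 <- list(fake_fit("a", pids, 1:5), fake_fit("b", pids[1:4], 1:4))
  M2 <- extract_random_effects(fits2, pids = pids)
  expect_equal(unname(M2["S05", 4:6]), c(0, 0, 0))
  prov <- attr(M2, "provenance")
  expect_equal(nrow(prov), 1L)
  expect_equal(prov$pid, "S05")

  # participant in no fit is a hard error
  expect_error(extract_random_effects(fits2, pids = c(pids, "S99")), "S99")
})
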