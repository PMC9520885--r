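test_that("latent factors recover a planted batch and are orthonormal", {
  set.seed(60)
  n <- 120; G <- 60
  batch <- rbinom(n, 1, 0.5)
  E <- matrix(rnorm(G * n, sd = 0.6), G, n)
  E[1:(G / 2), ] <- E[1:(G / 2), ] +
    matrix(2 * batch, G / 2, n, byrow = TRUE)
  covs <- data.frame(sex = rbinom(n, 1, 0.5))
  f <- estimate_latent_factors(E, covs, 3)
  expect_gt(abs(cor(f[, 1], batch)), 0.95)
  expect_equal(crossprod(f), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  f0 <- estimate_latent_factors(E, covs, 0)
  expect_equal(ncol(f0), 0L)
  expect_error(estimate_latent_factors(E, covs, n), "n_factors")
})

test_that("cis-eQTL scan matches closed-form OLS on a hand dataset", {
  # n = 6, one variant, one gene, no covariates
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.2, 1.1, 2.3, -0.1, 0.9, 2.6)
  D <- matrix(rep(x, 1), ncol = 1, dimnames = list(NULL, "v1"))
  E <- matrix(y, 1, 6, dimnames = list("g1", NULL))
  rec <- cis_eqtl_scan(D, c(v1 = 100), E, c(g1 = 200), maf_min = 0)
  ref <- summary(lm(y ~ x))$coefficients
  expect_equal(rec$beta, ref["x", 1], tolerance = 1e-10)
  expect_equal(rec$se, ref["x", 2], tolerance = 1e-10)
  expect_equal(rec$stat, ref["x", 3], tolerance = 1e-10)
  expect_equal(rec$p, ref["x", 4], tolerance = 1e-10)
  expect_equal(rec$stat, rec$beta / rec$se, tolerance = 1e-8)

  # with covariates, against lm()
  set.seed(61)
  n <- 80
  covs <- data.frame(a = rnorm(n), b = factor(sample(c("x", "y"), n, TRUE)))
  dos <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  expr <- matrix(rnorm(n) + 0.4 * dos[, 1], 1, n,
                 dimnames = list("g1", NULL))
  rec2 <- cis_eqtl_scan(dos, c(v1 = 100), expr, c(g1 = 500), covariates = covs)
  ref2 <- summary(lm(expr[1, ] ~ covs$a + covs$b + dos[, 1]))$coefficients
  expect_equal(rec2$beta, ref2[4, 1], tolerance = 1e-8)
  expect_equal(rec2$p, ref2[4, 4], tolerance = 1e-8)

  # MAF filter and cis-window filter
  dos3 <- cbind(v1 = rbinom(n, 2, 0.3), v2 = c(1, rep(0, n - 1)))
  expr3 <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("g1", "g2"), NULL))
  rec3 <- cis_eqtl_scan(dos3, c(v1 = 100, v2 = 150), expr3,
                        c(g1 = 500, g2 = 9e6))
  expect_false("v2" %in% rec3$variant)        # MAF 0.005 < 0.05
  expect_equal(attr(rec3, "excluded"), "v2")
  expect_false("g2" %in% rec3$gene)           # outside the 500-kb window
  expect_error(cis_eqtl_scan(dos3 + 2, c(v1 = 1, v2 = 2), expr3,
                             c(g1 = 5, g2 = 10)), "dosages")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(62)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # q <= 0.10 selects the same set as the classic step-up rule
  m <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= 0.10 * seq_len(m) / m)))
  classic <- if (k > 0) ord[seq_len(k)] else integer(0)
  expect_setequal(which(q <= 0.10), classic)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
})

test_that("conditional models adjust and fail loudly on collinearity", {
  set.seed(63)
  n <- 400
  z <- rbinom(n, 2, 0.5)
  x <- rbinom(n, 2, 0.5)          # independent of z
  y <- 0.5 * x + rnorm(n)
  expect_error(conditional_effect(x, cbind(x), y), "target")
  un <- conditional_effect(x, cbind(z), y)
  ref <- summary(lm(y ~ z + x))$coefficients
  expect_equal(un$beta, ref["x", 1], tolerance = 1e-8)
  expect_equal(un$se, ref["x", 2], tolerance = 1e-8)
  expect_error(conditional_effect(x, cbind(2 * x), y), "collinear")

  # independent conditioning leaves the effect essentially unchanged
  deltas <- replicate(40, {
    z <- rbinom(n, 2, 0.5); x <- rbinom(n, 2, 0.5)
    y <- 0.5 * x + rnorm(n)
    marg <- summary(lm(y ~ x))$coefficients["x", ]
    con <- conditional_effect(x, cbind(z), y)
    abs(con$beta - marg[1]) / marg[2]
  })
  expect_gt(mean(deltas < 2), 0.95)

  # conditioning on the true causal variant attenuates a proxy
  atten <- replicate(40, {
    causal <- rbinom(n, 1, 0.5)
    proxy <- ifelse(runif(n) < 0.85, causal, rbinom(n, 1, 0.5))
    y <- 0.8 * causal + rnorm(n)
    t_marg <- abs(summary(lm(y ~ proxy))$coefficients["proxy", 3])
    t_cond <- abs(conditional_effect(proxy, cbind(causal), y)$stat)
    t_cond < t_marg
  })
  expect_gte(mean(atten), 0.95)
})

test_that("kinship LMM collapses to OLS under identity kinship", {
  set.seed(64)
  n <- 150
  covs <- data.frame(a = rnorm(n))
  dose <- rbinom(n, 2, 0.3)
  y <- 0.3 * dose + covs$a + rnorm(n)
  f <- lmm_test(y, dose, covs, diag(n))
  ref <- summary(lm(y ~ a + dose, data = cbind(covs, dose = dose)))
  expect_lt(abs(f$beta - ref$coefficients["dose", 1]), 1e-6)
  expect_true(all(c(f$sigma_g2, f$sigma_e2) >= 0))
  expect_error(lmm_test(y, dose, covs, matrix(rnorm(n * n), n)),
               "symmetric")
})

test_that("kinship LMM maximises the restricted likelihood and recovers a 1:1 ratio", {
  # oracle: dense-matrix restricted likelihood maximised on a fine grid
  set.seed(68)
  n <- 30
  K2 <- simulate_kinship(rep(3, 10))
  g <- drop(t(chol(K2)) %*% rnorm(n))
  y <- 1.2 * g + rnorm(n)
  d <- rbinom(n, 2, 0.4)
  f <- lmm_test(y, d, NULL, K2)
  X <- cbind(1, d)
  remll <- function(lam, s2e) {
    V <- s2e * (lam * K2 + diag(n))
    cv <- chol(V); Vi <- chol2inv(cv)
    B <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% B
    -0.5 * (2 * sum(log(diag(cv))) + drop(t(r) %*% Vi %*% r) +
              determinant(t(X) %*% Vi %*% X, log = TRUE)$modulus)
  }
  grid <- expand.grid(lam = exp(seq(log(f$lambda) - 0.5,
                                    log(f$lambda) + 0.5, 0.01)),
                      s2e = seq(0.5, 1.5, 0.02) * f$sigma_e2)
  vals <- mapply(remll, grid$lam, grid$s2e)
  # the analytic profile optimum is within one grid step of the grid max
  best <- grid[which.max(vals), ]
  expect_lt(abs(log(best$lam) - log(f$lambda)), 0.05)
  expect_lt(abs(remll(f$lambda, f$sigma_e2) - max(vals)), 0.05)

  # recovery: genetic:residual 1:1 over sib-quartet families, n = 500;
  # the ratio estimate is noisy, so the centre is tested tightly and the
  # per-replicate spread loosely
  set.seed(65)
  K <- simulate_kinship(rep(4, 125))
  ek <- eigen(K, symmetric = TRUE)
  half <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  lams <- replicate(60, {
    gg <- half %*% rnorm(500)
    yy <- drop(gg) + rnorm(500)
    lmm_test(yy, rbinom(500, 2, 0.3), NULL, K)$lambda
  })
  expect_true(median(lams) >= 0.7 && median(lams) <= 1.4)
  expect_gte(mean(lams >= 1 / 3 & lams <= 3), 0.9)
})

test_that("ordinal regression equals binary logistic with two categories and recovers effects", {
  set.seed(66)
  n <- 400
  x <- rbinom(n, 2, 0.4)
  y2 <- rbinom(n, 1, plogis(-0.3 + 0.7 * x))
  rec <- ordinal_logistic(ordered(y2), x)
  ref <- summary(glm(y2 ~ x, family = binomial()))$coefficients
  expect_lt(abs(rec$beta - ref["x", 1]), 1e-6)

  # proportional-odds recovery at beta = 1.5
  est <- replicate(100, {
    x <- rbinom(300, 2, 0.3)
    lat <- 1.5 * x + rlogis(300)
    y <- cut(lat, c(-Inf, 0.8, 2.5, Inf),
             labels = c("mild", "moderate", "severe"), ordered_result = TRUE)
    tryCatch(ordinal_logistic(y, x)$beta, error = function(e) NA)
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 1.5), 0.15)
  expect_error(ordinal_logistic(ordered(rep(1, 10)), rnorm(10)), "single")
})

test_that("stratified additive test recovers planted within-stratum odds ratios", {
  set.seed(67)
  n <- 3000
  stratum <- sample(c("AA", "GG"), n, replace = TRUE)
  modifier <- rbinom(n, 2, 0.3)
  eta <- -0.5 + log(1.5) * modifier * (stratum == "GG")
  status <- rbinom(n, 1, plogis(eta))
  res <- stratified_additive_test(status, modifier, stratum)
  expect_equal(nrow(res), 2L)
  gg <- res[res$stratum == "GG", ]
  expect_lt(abs(gg$beta - log(1.5)), 3 * gg$se)
  expect_true(gg$ci_lo < gg$or && gg$or < gg$ci_hi)

  # constant modifier within a stratum
  res2 <- stratified_additive_test(status, ifelse(stratum == "AA", 1,
                                                  modifier), stratum)
  expect_equal(res2$note[res2$stratum == "AA"], "no modifier variation")
  expect_true(is.na(res2$beta[res2$stratum == "AA"]))

  # null modifier: CI covers 1 in about 95% of replicates
  cover <- replicate(200, {
    st <- sample(c("AA", "GG"), 400, replace = TRUE)
    mo <- rbinom(400, 2, 0.3)
    y <- rbinom(400, 1, 0.4)
    r <- stratified_additive_test(y, mo, st)
    r$ci_lo[1] <= 1 & 1 <= r$ci_hi[1]
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("global-null Monte Carlo matches structure and limits", {
  r <- global_null_test(k = 0, R = diag(7), n_draws = 1e4, seed = 1)
  expect_equal(r$p, 1)

  # identity R at modest draws: within 4 MC SE of the binomial tail
  tail_p <- 1 - pbinom(2, 7, 0.05)
  r2 <- global_null_test(k = 3, R = diag(7), n_draws = 2e5, seed = 2)
  expect_lt(abs(r2$p - tail_p), 4 * sqrt(tail_p * (1 - tail_p) / 2e5))

  # positive equicorrelation concentrates exceedances: tail above the
  # independence value
  Req <- matrix(0.9, 7, 7); diag(Req) <- 1
  r3 <- global_null_test(k = 3, R = Req, n_draws = 2e5, seed = 3)
  expect_gt(r3$p, tail_p)

  # k defaults to the observed exceedance count
  r4 <- global_null_test(p_values = c(0.01, 0.03, 0.2, 0.6, 0.04, 0.5, 0.9),
                         R = diag(7), n_draws = 1e4, seed = 4)
  expect_equal(r4$k, 3L)
  expect_warning(global_null_test(k = 1, R = diag(3), n_draws = 100),
                 "1e4")
  expect_error(global_null_test(k = 9, R = diag(7)), "exceed")
  expect_error(global_null_test(k = 1, R = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})
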