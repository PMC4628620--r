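test_that("eigen-rotated likelihood equals the dense MVN oracle on small pedigrees", {
  for (s in 1:3) {
    ped <- simulate_pedigree(n_founders = 4, n_generations = 2,
                             mean_offspring = 1.2, immigrant_rate = 0.3,
                             seed = s)
    kin <- kinship(ped)
    eig <- kinship_eigen(kin)
    A <- 2 * kin$phi
    set.seed(s + 100)
    y <- rnorm(nrow(ped))
    X <- cbind(1, rnorm(nrow(ped)))
    fit <- polygenic_fit(y, X, eig, se = FALSE)
    for (k in 1:30) {
      h2 <- runif(1, 0.01, 0.99); s2 <- runif(1, 0.2, 3)
      expect_equal(ecgherit:::rotated_loglik(fit, h2 * s2, (1 - h2) * s2),
                   dense_loglik(y, X, A, h2 * s2, (1 - h2) * s2),
                   tolerance = 1e-8)
    }
  }
})

test_that("optimum dominates random feasible points and matches the oracle's grid maximum", {
  e <- get_shared_ped()
  set.seed(21)
  sim <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0.5, sigma2_e = 0.5)
  X <- cbind(`(Intercept)` = rep(1, nrow(e$ped)))
  fit <- polygenic_fit(unname(sim$y), X, e$eig, se = FALSE)
  for (h2 in runif(50)) {
    delta_ll <- fit$loglik - ecgherit:::profile_loglik(fit, h2)
    expect_gte(delta_ll, -1e-6)
  }
})

test_that("degenerate relatedness and boundary cases are handled", {
  # unrelated individuals: 2*Phi = I, variance components unidentifiable
  ped <- pedigree(paste0("f", 1:30), rep("0", 30), rep("0", 30),
                  rep(1:2, 15))
  kin <- kinship(ped)
  set.seed(2)
  expect_error(polygenic_fit(rnorm(30), cbind(rep(1, 30)),
                             kinship_eigen(kin)),
               "identifiable")
  # sigma2_e -> 0 on a deep pedigree: h2 estimate approaches the upper boundary
  e <- get_shared_ped()
  sim <- simulate_phenotype(e$ped, e$eig, sigma2_g = 1, sigma2_e = 0,
                            seed = 3)
  fit <- suppressWarnings(polygenic_fit(unname(sim$y),
                                        cbind(rep(1, nrow(e$ped))), e$eig))
  expect_gt(fit$h2, 0.95)
  # pure noise: estimate lands exactly on the lower boundary, SE undefined
  noise <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0, sigma2_e = 1,
                              seed = 1)
  fit0 <- suppressWarnings(polygenic_fit(unname(noise$y),
                                         cbind(rep(1, nrow(e$ped))), e$eig))
  expect_identical(fit0$h2, 0)
  expect_warning(expect_true(is.na(h2_standard_error(fit0))), "boundary")
})

test_that("boundary LRT of h2 = 0 follows the 50:50 chi-square mixture", {
  fit <- list(loglik = -10, loglik_null = -10)
  class(fit) <- "polygenic"
  expect_equal(lrt_h2_zero(fit)$p, 0.5)
  fit$loglik <- -10 + 3.84 / 2
  expect_equal(lrt_h2_zero(fit)$p, 0.5 * pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(round(lrt_h2_zero(fit)$p, 3), 0.025)
  fit$loglik <- -10.1
  expect_error(lrt_h2_zero(fit), "optimizer")
})

test_that("nested LRT compares identical samples only and is exact for equal fits", {
  e <- get_shared_ped()
  n <- nrow(e$ped)
  sim <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0.4, sigma2_e = 0.6,
                            seed = 4)
  y <- unname(sim$y)
  X1 <- cbind(`(Intercept)` = rep(1, n))
  set.seed(5)
  X2 <- cbind(X1, snp = rbinom(n, 2, 0.3))
  f1 <- polygenic_fit(y, X1, e$eig, se = FALSE)
  f2 <- polygenic_fit(y, X2, e$eig, se = FALSE)
  eq <- lrt_nested(f1, f1)
  expect_equal(eq$lambda, 0)
  expect_equal(eq$p, 1)
  lt <- lrt_nested(f2, f1)
  expect_equal(lt$df, 1)
  expect_gte(lt$lambda, 0)
  # adding a column never decreases the maximized log-likelihood
  expect_gte(f2$loglik, f1$loglik - 1e-8)
  expect_error(lrt_nested(f2, polygenic_fit(y[-1], X1[-1, , drop = FALSE],
                                            kinship_eigen(e$kin,
                                                          e$ped$id[-1]),
                                            se = FALSE)),
               "different individual")
})

test_that("standard errors shrink like 1/sqrt(n) and match sampling spread", {
  e <- get_shared_ped()
  n <- nrow(e$ped)
  X <- cbind(`(Intercept)` = rep(1, n))
  set.seed(6)
  fits <- replicate(40, {
    sim <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0.4, sigma2_e = 0.6)
    f <- polygenic_fit(unname(sim$y), X, e$eig, se = TRUE)
    c(f$h2, f$h2_se)
  })
  emp_sd <- sd(fits[1, ])
  mean_se <- mean(fits[2, ], na.rm = TRUE)
  expect_gt(mean_se, emp_sd / 2)
  expect_lt(mean_se, emp_sd * 2)
})

test_that("formula interface, methods and serialization work end to end", {
  e <- get_shared_ped()
  n <- nrow(e$ped)
  set.seed(7)
  snp <- rbinom(n, 2, 0.3)
  sim <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0.5, sigma2_e = 0.45,
                            dosages = matrix(snp, n, 1,
                                             dimnames = list(e$ped$id, "rs1")),
                            snp_sets = list(own = list(snps = "rs1",
                                                       fraction = 0.05)))
  d <- data.frame(id = e$ped$id, y = unname(sim$y), rs1 = snp)
  fit <- polygenic(y ~ rs1, data = d, kinship = e$kin)
  expect_s3_class(fit, "polygenic")
  expect_named(coef(fit), c("(Intercept)", "rs1"))
  expect_equal(nobs(fit), n)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(length(residuals(fit)), n)
  expect_equal(residuals(fit, "conditional"),
               residuals(fit) - predict(fit))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(n, 2))
  expect_output(print(summary(fit)), "total-variance")
  an <- anova(fit, polygenic(y ~ 1, data = d, kinship = e$eig))
  expect_equal(an$df[2], 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, tmp)
  js <- jsonlite::read_json(tmp)
  expect_equal(js$h2, fit$h2, tolerance = 1e-12)
  # missing rows are dropped
  d$y[1:5] <- NA
  expect_equal(polygenic(y ~ 1, data = d, kinship = e$kin)$n, n - 5)
})

test_that("explained variance adjustment is unbiased for pure-noise SNPs", {
  e <- get_shared_ped()
  n <- nrow(e$ped)
  set.seed(8)
  vs <- replicate(30, {
    D <- matrix(rbinom(n * 10, 2, 0.3), n, 10,
                dimnames = list(e$ped$id, paste0("s", 1:10)))
    sim <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0.4, sigma2_e = 0.6)
    f <- polygenic_fit(unname(sim$y), cbind(1, D), e$eig, se = FALSE)
    c(raw = explained_variance(f, adjust = FALSE),
      adj = explained_variance(f, adjust = TRUE))
  })
  expect_gt(mean(vs["raw", ]), 0.005)       # clearly inflated
  expect_lt(mean(vs["adj", ]), 0.004)       # adjustment removes the bulk
})
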