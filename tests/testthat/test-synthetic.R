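test_that("simulated pedigrees validate, grow with generations and honor consanguinity", {
  ped0 <- simulate_pedigree(n_founders = 20, n_generations = 3,
                            mean_offspring = 2, consanguinity_rate = 0,
                            immigrant_rate = 0.3, seed = 1)
  kin0 <- kinship(ped0)
  expect_true(all(kin0$F == 0))            # no cousin matings -> no inbreeding

  ped <- simulate_pedigree(n_founders = 30, n_generations = 4,
                           mean_offspring = 2.4, consanguinity_rate = 0.2,
                           immigrant_rate = 0.3, seed = 2)
  kin <- kinship(ped)
  expect_true(any(abs(kin$F - 0.0625) < 1e-12))   # first-cousin offspring
  small <- simulate_pedigree(n_founders = 10, n_generations = 2,
                             mean_offspring = 2, seed = 3)
  expect_lt(nrow(small), nrow(ped))
  expect_error(simulate_pedigree(n_founders = 1), "at least 2")
  # unmatable configuration goes extinct after bounded retries
  expect_error(simulate_pedigree(n_founders = 2, n_generations = 3,
                                 mean_offspring = 0.01, immigrant_rate = 0,
                                 seed = 4, max_retries = 3), "extinct")
})

test_that("default pedigree configuration matches the cohort's scale and kinship level", {
  ped <- simulate_pedigree(seed = 11)
  expect_gt(nrow(ped), 1000)
  expect_lt(nrow(ped), 2300)
  kin <- kinship(ped)
  med <- median(kin$phi[upper.tri(kin$phi)])
  expect_gt(med, 0.002)
  expect_lt(med, 0.008)
  expect_gt(median(kin$F[kin$F > 0]), 0)  # skewed nonzero inbreeding present
})

test_that("gene dropping respects Mendelian transmission and allele frequencies", {
  founders <- pedigree(paste0("f", 1:400), rep("0", 400), rep("0", 400),
                       rep(1:2, 200))
  D <- gene_drop(founders, c(a = 0.5, b = 0.1), seed = 5)
  expect_true(all(D %in% 0:2))
  expect_lt(abs(mean(D[, "a"]) - 1), 0.1)
  expect_lt(abs(mean(D[, "b"]) - 0.2), 0.06)
  expect_error(gene_drop(founders, c(0.5, 0)), "inside")
  expect_error(gene_drop(founders, 1), "inside")

  # homozygous-absent parents cannot transmit the allele
  trio <- ped_trio()
  for (k in 1:20) {
    d <- gene_drop(trio, 1e-9, seed = k)   # founders essentially 0 dosage
    if (d["F", 1] == 0 && d["M", 1] == 0) expect_equal(unname(d["C", 1]), 0)
  }
})

test_that("sibling genotype correlation approaches 1/2 under gene dropping", {
  ped <- ped_sibs()
  D <- gene_drop(ped, rep(0.5, 10000), seed = 6)
  r <- cor(D["S1", ], D["S2", ])
  expect_equal(r, 0.5, tolerance = 0.05)
})

test_that("phenotype components are scaled to their variance targets exactly", {
  e <- get_shared_ped()
  n <- nrow(e$ped)
  D <- gene_drop(e$ped, setNames(rep(0.3, 8), paste0("s", 1:8)), seed = 7)
  sim <- simulate_phenotype(
    e$ped, e$eig, sigma2_g = 0.28, sigma2_e = 0.66, dosages = D,
    snp_sets = list(own = list(snps = colnames(D), fraction = 0.06)),
    seed = 8)
  rv <- sim$truth$realized_variances
  expect_equal(rv$polygenic, 0.28, tolerance = 1e-10)
  expect_equal(rv$residual, 0.66, tolerance = 1e-10)
  expect_equal(rv$snp_own, 0.06, tolerance = 1e-10)
  expect_equal(sim$truth$h2_narrow, 0.34)
  expect_equal(unname(sim$y),
               with(sim$truth$components, snp_own + polygenic + residual))
  # no signal at all: fitted h2 near zero
  noise <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0, sigma2_e = 1,
                              seed = 9)
  f <- suppressWarnings(polygenic_fit(unname(noise$y), cbind(rep(1, n)),
                                      e$eig))
  expect_lt(f$h2, 0.1)
  # requesting variance from a monomorphic SNP set fails
  Dmono <- matrix(2, n, 1, dimnames = list(e$ped$id, "m1"))
  expect_error(simulate_phenotype(
    e$ped, e$eig, 0.3, 0.6, dosages = Dmono,
    snp_sets = list(x = list(snps = "m1", fraction = 0.1))), "zero variance")
})

test_that("covariate effects enter the phenotype linearly", {
  e <- get_shared_ped()
  n <- nrow(e$ped)
  covs <- data.frame(age = rnorm(n, 50, 10))
  sim <- simulate_phenotype(e$ped, e$eig, sigma2_g = 0.4, sigma2_e = 0.6,
                            covariates = covs,
                            covariate_effects = c(age = 0.02), seed = 10)
  expect_equal(sim$truth$components$covariates, 0.02 * covs$age)
})

test_that("cohort bundles are reproducible from the seed and internally consistent", {
  b1 <- simulate_ecg_cohort(seed = 21, n_founders = 30, n_generations = 4,
                            mean_offspring = 2.3)
  b2 <- simulate_ecg_cohort(seed = 21, n_founders = 30, n_generations = 4,
                            mean_offspring = 2.3)
  expect_identical(b1$cohort, b2$cohort)
  expect_identical(b1$dosages, b2$dosages)
  expect_identical(b1$catalog, b2$catalog)

  ch <- b1$cohort
  # back-solved amplitudes reproduce the simulated products
  sl <- (ch$S_V1 + pmax(ch$R_V5, ch$R_V6)) * ch$qrs_ms
  expect_equal(sl, (0.55 + 0.45) * (ch$S_V1 / 0.55) * ch$qrs_ms,
               tolerance = 1e-8)
  cv <- (ch$R_aVL + ch$S_V3) * ch$qrs_ms
  expect_true(all(cv > 0))
  # catalog: 71 rows, one unavailable id, per-trait index counts 21/36/9/2
  expect_equal(nrow(b1$catalog), 71)
  expect_true("rs_unavail" %in% b1$catalog$id)
  sel <- suppressMessages(select_index_snps(b1$catalog,
                                            available = colnames(b1$dosages)))
  expect_equal(unname(table(sel$source_trait)[c("QRS", "QT", "PR", "12LS")]),
               c(21, 36, 9, 2), ignore_attr = TRUE)
  # flagged individuals are exactly the ones the exclusion step drops
  ex <- apply_exclusions(ch, "PR")
  flagged <- rowSums(ch[, c("atrial_fibrillation", "myocardial_infarction",
                            "bundle_branch_block", "av_block", "pacemaker",
                            "wpw", "pregnancy",
                            "antiarrhythmic_or_digoxin")]) > 0
  pr_out <- ch$pr_ms >= 320 | ch$pr_ms <= 80
  expect_equal(!ex$kept, flagged | pr_out)
})

test_that("end-to-end: pipeline recovers the configured variance composition", {
  b <- simulate_ecg_cohort(seed = 31, n_founders = 60, n_generations = 5,
                           mean_offspring = 2.4)
  pt <- prepare_traits(b$cohort)
  kin <- kinship(b$pedigree)
  sel <- suppressMessages(select_index_snps(b$catalog,
                                            available = colnames(b$dosages)))
  # sampling SD of h2_hat is ~0.07 per trait at this cohort size; deviations
  # should scatter around zero across traits, with the QRS SNP signal visible
  devs <- vapply(c("QRS", "QT", "PR", "SL", "CV", "12LS"), function(tr) {
    y <- setNames(pt$traits[[tr]], pt$traits$id)
    row <- run_three_models(tr, y, kin, b$dosages, sel, se = FALSE)
    if (tr == "QRS") {
      expect_gt(row$dh2_12, 0)
      expect_lt(row$p_lrt_12, 0.05)
    }
    row$h2_m1 - b$truth[[tr]]$h2_narrow
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.06)
  expect_lt(max(abs(devs)), 0.18)
})
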