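test_that("rank-based inverse normal transform matches the Blom formula", {
  # n = 5 distinct values: Phi^-1((r - 3/8) / (5 - 3/4 + 1))
  y <- c(10, 30, 20, 50, 40)
  got <- rankInverseNormal(y)
  expect_equal(got[order(y)],
               qnorm((1:5 - 3 / 8) / (5 - 2 * 3 / 8 + 1)),
               tolerance = 1e-12)
  expect_equal(round(pnorm(sort(got)), 3), c(0.119, 0.310, 0.5, 0.690,
                                             0.881))
  # symmetric around zero, middle value exactly 0
  s <- rankInverseNormal(c(1, 2, 3))
  expect_equal(s[2], 0)
  expect_equal(s[1], -s[3])
  # rank-based: invariant to strictly increasing transforms; NA preserved
  z <- c(rnorm(10), NA)
  expect_equal(rankInverseNormal(z), rankInverseNormal(exp(z)))
  expect_true(is.na(rankInverseNormal(z)[11]))
  expect_error(rankInverseNormal(rep(2, 5)), "degenerate")
  expect_error(rankInverseNormal(c(1, 2)), "at least 3")
})

test_that("variant filters apply the missingness and MAF cutoffs", {
  set.seed(22)
  n <- 100
  calls <- matrix(rbinom(n * 100, 1, 0.3), n, 100)
  # variants 1-3 fail missingness (21%), 4-7 fail MAF
  for (v in 1:3) calls[sample(n, 21), v] <- NA
  for (v in 4:6) calls[, v] <- rbinom(n, 1, 0.001)
  calls[, 7] <- c(rep(1, 100))            # alt freq 1 -> MAF 0
  calls[, 7][1:100] <- 1
  panel <- makePanel(calls)
  flt <- filterVariants(panel, assocConfig(genoMaxMissing = 0.2,
                                           mafMin = 0.01))
  expect_equal(length(flt$keep), 93L)
  expect_equal(unname(flt$reasons[1:3]), rep("missingness", 3))
  expect_equal(unname(flt$reasons[4:7]), rep("maf", 4))
  # conservation: retained + excluded = total, reasons exhaustive
  expect_equal(sum(flt$report$n), 100L)
  # MAF folding: alt frequency 0.995 -> MAF 0.005 < 0.01
  calls2 <- matrix(rbinom(200 * 2, 1, 0.5), 200, 2)
  calls2[, 1] <- c(rep(1, 199), 0)
  flt2 <- filterVariants(makePanel(calls2))
  expect_equal(unname(flt2$reasons[1]), "maf")
})

test_that("no-covariate fits equal closed-form simple regression", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    g <- rbinom(n, 1, 0.4)
    if (sd(g) == 0) next
    y <- 0.3 * g + rnorm(n)
    fit <- fitSingleVariant(y, g)
    # textbook OLS
    beta <- cov(y, g) / var(g)
    a <- mean(y) - beta * mean(g)
    res <- y - a - beta * g
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 / ((n - 1) * var(g)))
    expect_equal(fit$beta, beta, tolerance = 1e-10)
    expect_equal(fit$se, se, tolerance = 1e-10)
    expect_equal(fit$tstat, beta / se, tolerance = 1e-10)
    expect_equal(fit$p, 2 * pt(-abs(beta / se), n - 2), tolerance = 1e-10)
    expect_equal(fit$n_used, n)
  }
})

test_that("covariate-adjusted fits match lm() and report the genotype row", {
  set.seed(24)
  n <- 80
  lines <- sprintf("DGRP_%03d", 1:n)
  cov <- CovariateTable(lines, data.frame(
    symbiont = sample(c("neg", "pos"), n, TRUE),
    sv1 = sample(paste0("st", 1:3), n, TRUE),
    sv2 = sample(paste0("st", 1:2), n, TRUE),
    sv3 = sample(paste0("st", 1:3), n, TRUE),
    sv4 = sample(paste0("st", 1:2), n, TRUE),
    sv5 = sample(paste0("st", 1:3), n, TRUE)))
  g <- rbinom(n, 1, 0.3)
  y <- 0.8 * g + (covariateData(cov)$symbiont == "pos") * 0.5 + rnorm(n)
  fit <- fitSingleVariant(y, g, cov)
  ref <- summary(lm(y ~ g + symbiont + sv1 + sv2 + sv3 + sv4 + sv5,
                    data = covariateData(cov)))$coefficients["g", ]
  expect_equal(fit$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(fit$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(fit$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  # exact fit: p floored at the smallest representable, never 0
  fexact <- fitSingleVariant(2 * g, g)
  expect_equal(fexact$beta, 2)
  expect_gt(fexact$p, 0)
  expect_lte(fexact$p, .Machine$double.xmin)
  # monomorphic in sample -> skipped
  expect_null(fitSingleVariant(rnorm(10), rep(1, 10)))
})

test_that("runGwas ranks a spiked causal variant first and is deterministic", {
  cfg <- simConfig(nLines = 200, nVariants = 200, missingRate = 0,
                   causalEffects = data.frame(variant = 10L, beta = 1.5,
                                              study = 1L, pheno = 1L),
                   seed = 77)
  sim <- simulatePanel(cfg)
  y <- phenotypeValues(sim$registry, "S01", "ph01", "F")
  gw <- runGwas(y, sim$panel, sim$covariates)
  causal <- variantInfo(sim$panel)$variant_id[10]
  expect_equal(gw$results$variant_id[1], causal)
  expect_true(all(diff(gw$results$p) >= 0))
  gw2 <- runGwas(y, sim$panel, sim$covariates)
  expect_identical(gw$results, gw2$results)
  # association p is invariant to increasing transforms of y under RINT
  gw3 <- runGwas(exp(y / 2), sim$panel, sim$covariates)
  expect_equal(gw3$results$p, gw$results$p, tolerance = 1e-12)
  # permuting phenotype labels destroys the signal
  set.seed(1)
  yp <- setNames(sample(y), names(y))
  gwp <- runGwas(yp, sim$panel, sim$covariates)
  expect_gt(gwp$results$p[gwp$results$variant_id == causal], 1e-6)
  expect_error(runGwas(y[1:5], sim$panel, sim$covariates),
               "insufficient sample")
})

test_that("significance summary counts thresholds and Bonferroni", {
  res <- data.frame(p = c(1e-7, 1e-6, 1e-4, 0.01, 0.5))
  sm <- significanceSummary(res, assocConfig())
  expect_equal(sm$counts$n[sm$counts$threshold == 1e-3], 3)
  expect_equal(sm$counts$n[sm$counts$threshold == 1e-5], 2)
  expect_equal(sm$bonferroni$threshold, 0.01)
  expect_equal(sm$bonferroni$n, 4)  # p <= 0.01 is inclusive
  expect_equal(significanceSummary(res, nVariants = 10)$bonferroni$threshold,
               0.005)
  allOne <- data.frame(p = rep(1, 4))
  expect_true(all(significanceSummary(allOne)$counts$n == 0))
})

test_that("qqData produces matched expected/observed quantiles", {
  m <- 200
  p <- (seq_len(m) - 0.5) / m
  qq <- qqData(data.frame(p = sample(p)))
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  one <- qqData(data.frame(p = 0.2))
  expect_equal(nrow(one), 1L)
  expect_equal(one$expected, -log10(0.5))  # (1 - 0.5)/1
})

test_that("covariate screen runs KW per factor, one ANOVA, and Shapiro", {
  set.seed(26)
  n <- 100
  lines <- sprintf("DGRP_%03d", 1:n)
  cov <- CovariateTable(lines, data.frame(
    symbiont = rep(c("neg", "pos"), each = n / 2),
    sv1 = sample(paste0("st", 1:3), n, TRUE),
    sv2 = sample(paste0("st", 1:3), n, TRUE),
    sv3 = sample(paste0("st", 1:3), n, TRUE),
    sv4 = sample(paste0("st", 1:3), n, TRUE),
    sv5 = rep("st1", n)))                    # single category -> skipped
  y <- setNames(rnorm(n) + 3 * (covariateData(cov)$symbiont == "pos"),
                lines)
  scr <- covariateScreen(y, cov)
  expect_equal(nrow(scr$kruskal), 5L)       # sv5 skipped
  expect_match(scr$skipped, "sv5")
  kwSym <- scr$kruskal[scr$kruskal$covariate == "symbiont", ]
  expect_lt(kwSym$p, 0.01)
  # oracle: base kruskal.test on the same data
  ref <- kruskal.test(y, factor(covariateData(cov)$symbiont))
  expect_equal(kwSym$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(nrow(scr$anova), 5L)         # all usable factors jointly
  expect_lt(scr$anova$p[scr$anova$term == "symbiont"], 0.01)
  expect_true(scr$shapiro$p >= 0 && scr$shapiro$p <= 1)
  # flat phenotype across groups -> KW statistic 0
  flat <- setNames(rep(c(1, 2), n / 2), lines)
  scr2 <- covariateScreen(flat, cov)
  expect_equal(scr2$kruskal$statistic[scr2$kruskal$covariate == "symbiont"],
               0, tolerance = 1e-12)
})

test_that("genotype groups partition values and conserve counts", {
  y <- c(1, 2, 3, 4, 5)
  g <- c(0, 0, 1, 1, NA)
  grp <- genotypeGroupValues(y, g)
  expect_equal(grp$ref, c(1, 2))
  expect_equal(grp$alt, c(3, 4))
  expect_equal(sum(grp$counts), 5)
  allRef <- genotypeGroupValues(y, rep(0, 5))
  expect_equal(unname(allRef$counts), c(5, 0, 0))
})

test_that("PheWAS lookup ranks driven phenotypes on top", {
  cfg <- simConfig(nLines = 200, nVariants = 80, missingRate = 0,
                   causalEffects = data.frame(variant = c(4L, 4L),
                                              beta = c(1.5, 1.5),
                                              study = c(1L, 2L),
                                              pheno = c(1L, 1L)),
                   nStudies = 2, phenosPerStudy = 2, seed = 33)
  sim <- simulatePanel(cfg)
  store <- list()
  for (key in c("S01:ph01:F", "S01:ph02:F", "S02:ph01:F", "S02:ph02:F")) {
    parts <- strsplit(key, ":")[[1]]
    y <- phenotypeValues(sim$registry, parts[1], parts[2], parts[3])
    store[[key]] <- runGwas(y, sim$panel, sim$covariates)
  }
  vid <- variantInfo(sim$panel)$variant_id[4]
  ph <- phewasLookup(vid, store)
  expect_lte(nrow(ph), length(store))
  expect_setequal(ph$phenotype[1:2], c("S01:ph01:F", "S02:ph01:F"))
  expect_true(all(diff(ph$p) >= 0))
  empty <- phewasLookup("X:999999999", store)
  expect_equal(nrow(empty), 0L)
  expect_match(attr(empty, "notice"), "no stored phenotype")
})
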