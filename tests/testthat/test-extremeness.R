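test_that("minimum-tie ranking follows the stated convention", {
  expect_equal(rankMinTies(c(5, 1, 1, 9)), c(3, 1, 1, 4))
  expect_equal(rankMinTies(1:7), 1:7)
  expect_equal(rankMinTies(rep(4, 5)), rep(1L, 5))
  expect_equal(rankMinTies(c(2, NA, 1)), c(2, NA, 1))
  expect_error(rankMinTies(c(1, NA, NA)), "at least 2")
})

test_that("the 15% cutoff is rounded up inclusively", {
  expect_equal(extremenessCutoff(8), 2L)    # raw 1.2 -> 2
  expect_equal(extremenessCutoff(12), 2L)   # raw 1.8 -> 2
  expect_equal(extremenessCutoff(20), 3L)   # raw 3.0 stays 3
  expect_equal(extremenessCutoff(1), 1L)
  expect_true(all(sapply(1:200, function(r)
    extremenessCutoff(r) >= 0.15 * r)))     # c >= c_raw always
})

test_that("extremeness bands follow the verbatim rule (upper band wider)", {
  r <- 1:10
  a <- assignExtremeness(r, 10, 2)
  expect_equal(as.integer(a), c(-1L, -1L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
  # R_max = 3, c = 1: rank 1 -> -1; ranks 2, 3 -> +1 (r >= 3 - 1)
  a3 <- assignExtremeness(1:3, 3, 1)
  expect_equal(as.integer(a3), c(-1L, 1L, 1L))
  expect_false(attr(a3, "degenerate"))
  # dense distinct ranks: count(-1) = c, count(+1) = c + 1
  for (n in c(10, 17, 40)) {
    cc <- extremenessCutoff(n)
    an <- assignExtremeness(1:n, n, cc)
    expect_equal(sum(an == -1), cc)
    expect_equal(sum(an == 1), cc + 1)
    expect_lte(mean(an != 0), (2 * cc + 1) / n)
  }
  # all-tied vector collapses to one rank: degenerate overlap flagged
  deg <- assignExtremeness(rep(1L, 4), 1, 1)
  expect_true(attr(deg, "degenerate"))
  expect_true(all(deg == -1L))
})

test_that("FoE and adjusted values do the stated arithmetic", {
  expect_equal(fractionOfExtremeness(c(-1, 0, 1, 0)), 0.5)
  expect_equal(fractionOfExtremeness(rep(0, 7)), 0)
  expect_equal(fractionOfExtremeness(c(-1, 1, 1)), 1)
  expect_error(fractionOfExtremeness(rep(NA_integer_, 3)), "undefined")
  expect_equal(adjustedExtremeness(91, 100), 0.09)
  expect_equal(adjustedExtremeness(100, 100), 0)
  expect_equal(adjustedExtremeness(5, 10), 0.5)  # exactly 0.5 unadjusted
  expect_equal(adjustedExtremeness(c(1, 9), 10), c(0.1, 0.1))
})

test_that("the pipeline matches a literal transcription on small registries", {
  set.seed(31)
  for (i in 1:10) {
    nL <- sample(4:8, 1); nP <- sample(2:6, 1)
    vals <- matrix(sample(1:5, nL * nP, replace = TRUE) + rnorm(nL * nP,
                   sd = ifelse(i %% 2, 0, 0.3)), nL, nP)
    vals[sample(length(vals), floor(length(vals) / 6))] <- NA
    # keep phenotypes rankable (>= 2 values)
    keep <- colSums(!is.na(vals)) >= 2
    vals <- vals[, keep, drop = FALSE]
    if (!ncol(vals)) next
    colnames(vals) <- sprintf("ph%02d", seq_len(ncol(vals)))
    reg <- makeRegistry(vals)
    got <- extremenessPipeline(reg, minPhenos = 1)
    rownames(vals) <- sprintf("DGRP_%03d", seq_len(nL))
    oracle <- oracleExtremeness(vals)
    hasAny <- oracle$n > 0
    expect_equal(setNames(got$records$foe, got$records$line),
                 oracle$foe[hasAny][got$records$line])
    expect_equal(setNames(got$records$n_phenos, got$records$line),
                 setNames(as.integer(oracle$n[hasAny]),
                          names(oracle$n[hasAny]))[got$records$line])
    # per-phenotype assignments agree value for value
    for (k in seq_len(nrow(got$assignments))) {
      row <- got$assignments[k, ]
      expect_identical(row$assignment,
                       oracle$assignments[row$line, row$pheno])
    }
  }
})

test_that("planted extreme lines and rounding violations are detected", {
  set.seed(32)
  nL <- 30; nP <- 12
  vals <- matrix(rnorm(nL * nP), nL, nP)
  vals[1, ] <- 99          # line 1 at the max of every phenotype
  reg <- makeRegistry(vals)
  ext <- extremenessPipeline(reg, minPhenos = 5)
  expect_equal(ext$records$foe[ext$records$line == "DGRP_001"], 1)

  # R_max = 6: c_raw = 0.9 -> c = 1, and adjusted(1/6) = 0.167 > 0.15,
  # so every -1 at rank 1 is a counted violation
  v6 <- matrix(c(1:6, 6:1), 6, 2)
  reg6 <- makeRegistry(v6)
  ext6 <- extremenessPipeline(reg6, minPhenos = 1)
  a <- ext6$assignments
  low <- a[a$assignment == -1 & a$rank == 1, ]
  expect_true(all(low$violation))
  expect_equal(ext6$violations$n, sum(a$violation))
  expect_gt(ext6$violations$n, 0)

  # min_phenos exclusion never changes other lines' FoE
  vals2 <- vals
  vals2[2, 3:nP] <- NA     # line 2 drops below the threshold
  ext2 <- extremenessPipeline(makeRegistry(vals2), minPhenos = 5)
  expect_false("DGRP_002" %in% ext2$records$line)
  # FoE is rank-based: increasing transform changes nothing
  ext3 <- extremenessPipeline(makeRegistry(exp(vals / 4)), minPhenos = 5)
  expect_equal(ext3$records$foe, ext$records$foe)
})

test_that("category filtering and empty selections behave as declared", {
  set.seed(33)
  r1 <- makeRegistry(matrix(rnorm(60), 10, 6), studyId = "S01",
                     categories = "Life history traits, Aging")
  r2 <- makeRegistry(matrix(rnorm(60), 10, 6), studyId = "S02",
                     categories = "Morphology")
  reg <- mergeRegistries(r1, r2)
  ext <- extremenessPipeline(reg, categories = c("life history traits"),
                             minPhenos = 1)
  expect_true(all(ext$assignments$study == "S01"))
  expect_error(extremenessPipeline(reg, categories = "Metabolism",
                                   minPhenos = 1), "no phenotypes")
})

test_that("cross-sex pairing picks extreme/moderate within tolerance", {
  recs <- data.frame(
    line = rep(c("DGRP_001", "DGRP_002", "DGRP_003", "DGRP_004"), each = 2),
    sex = rep(c("F", "M"), 4),
    n_phenos = 60,
    foe = c(0.4, 0.4, 0.1, 0.1, 0.5, 0.3, 0.25, 0.22),
    stringsAsFactors = FALSE)
  pair <- crossSexPairings(recs, tol = 0.05)
  expect_equal(pair$extreme$line, "DGRP_001")
  expect_equal(pair$moderate$line, "DGRP_002")
  # |0.5 - 0.3| > 0.05 excludes DGRP_003 from candidacy
  expect_false("DGRP_003" %in% pair$candidates$line)
  # permutation invariance
  pair2 <- crossSexPairings(recs[sample(nrow(recs)), ], tol = 0.05)
  expect_equal(pair2$candidates, pair$candidates)
  # no line with both sexes -> notice
  solo <- recs[recs$sex == "F", ]
  expect_match(crossSexPairings(solo)$notice, "both sexes")
})
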