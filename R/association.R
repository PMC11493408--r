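## Per-variant covariate-adjusted linear association ("GWAS-lite"
## mirroring the PLINK2 --glm hide-covar semantics), covariate screening,
## threshold/QQ summaries and phenome-wide (PheWAS) lookup.

#' Association configuration
#'
#' Mirrors the per-variant GLM settings used on full reference panels:
#' variants are dropped when their missing-call fraction exceeds
#' \code{genoMaxMissing} (\code{--geno 0.2}) or their minor-allele frequency
#' falls below \code{mafMin} (\code{--maf 0.01}); phenotypes are rank-based
#' inverse-normal transformed (\code{--quantile-normalize}) and
#' variance-standardized before fitting.
#'
#' @param genoMaxMissing maximum missing-call fraction (default 0.2).
#' @param mafMin minimum minor-allele frequency (default 0.01).
#' @param quantileNormalize apply [rankInverseNormal()] to the phenotype.
#' @param varianceStandardize scale the (transformed) phenotype and any
#'   quantitative covariates to unit variance.
#' @param reportThresholds p-value thresholds for [significanceSummary()].
#' @param alphaBonferroni family-wise level for the Bonferroni threshold.
#' @return list of class "AssocConfig".
#' @export
assocConfig <- function(genoMaxMissing = 0.2, mafMin = 0.01,
                        quantileNormalize = TRUE,
                        varianceStandardize = TRUE,
                        reportThresholds = c(1e-3, 1e-5, 1e-6),
                        alphaBonferroni = 0.05) {
  stopifnot(genoMaxMissing >= 0, genoMaxMissing < 1,
            mafMin > 0, mafMin < 0.5)
  structure(list(genoMaxMissing = genoMaxMissing, mafMin = mafMin,
                 quantileNormalize = quantileNormalize,
                 varianceStandardize = varianceStandardize,
                 reportThresholds = sort(reportThresholds,
                                         decreasing = TRUE),
                 alphaBonferroni = alphaBonferroni),
            class = "AssocConfig")
}

#' Rank-based inverse-normal transform
#'
#' Replaces values by \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))} where r is the
#' mid-rank (average for ties), n the number of non-missing values and c
#' the offset (Blom's 3/8 by default). Missing values stay missing; output
#' is symmetric around 0 and invariant under any strictly increasing
#' transform of the input.
#'
#' @param y numeric vector (>= 3 non-missing values).
#' @param offset rank offset c (default 3/8).
#' @return transformed vector, same length and NA pattern as \code{y}.
#' @export
rankInverseNormal <- function(y, offset = 3 / 8) {
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(y[ok])) == 1L)
    stop("degenerate phenotype: all values identical", call. = FALSE)
  r <- rank(y[ok], ties.method = "average")
  out <- y
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Filter variants on missingness and minor-allele frequency
#'
#' A variant is retained iff its missing-call fraction is <=
#' \code{genoMaxMissing} and its MAF (computed on non-missing calls, folded
#' to <= 0.5) is >= \code{mafMin}. Exclusion reasons are exhaustive and
#' mutually exclusive (missingness checked first).
#'
#' @param panel a [GenotypePanel].
#' @param cfg an [assocConfig()].
#' @return list with \code{keep} (retained variant ids), \code{reasons}
#'   (per-variant: "retained", "missingness" or "maf") and \code{report}
#'   (counts by reason).
#' @export
filterVariants <- function(panel, cfg = assocConfig()) {
  calls <- genotypeCalls(panel)
  missFrac <- colMeans(is.na(calls))
  altF <- colMeans(calls, na.rm = TRUE)
  maf <- pmin(altF, 1 - altF)
  maf[is.nan(maf)] <- 0            # all calls missing
  reasons <- rep("retained", ncol(calls))
  reasons[maf < cfg$mafMin] <- "maf"
  reasons[missFrac > cfg$genoMaxMissing] <- "missingness"
  names(reasons) <- colnames(calls)
  keep <- colnames(calls)[reasons == "retained"]
  report <- as.data.frame(table(
    reason = factor(reasons, levels = c("retained", "missingness", "maf"))),
    responseName = "n", stringsAsFactors = FALSE)
  list(keep = keep, reasons = reasons, report = report,
       maf = maf, missFrac = missFrac)
}

## Covariate design matrix: categorical covariates enter as indicator
## contrasts with the most frequent category as reference; quantitative
## covariates are centered (and scaled when standardize = TRUE).
.covariateDesign <- function(cov, standardize = TRUE) {
  if (is.null(cov)) return(NULL)
  cd <- covariateData(cov)
  cols <- list()
  for (nm in names(cd)) {
    col <- cd[[nm]]
    if (is.factor(col) || is.character(col)) {
      col <- factor(col)
      ref <- names(sort(table(col), decreasing = TRUE))[1L]
      col <- stats::relevel(col, ref = ref)
      mm <- stats::model.matrix(~col)[, -1L, drop = FALSE]
      if (ncol(mm))
        colnames(mm) <- paste0(nm, "_", sub("^col", "", colnames(mm)))
      cols[[nm]] <- mm
    } else {
      x <- as.numeric(col)
      x <- x - mean(x)
      if (standardize && stats::sd(x) > 0) x <- x / stats::sd(x)
      cols[[nm]] <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- lineIds(cov)
  X
}

## OLS of y on [1, g, C]; returns the genotype row only (hide-covar).
.fitVariant <- function(y, g, C) {
  ok <- !is.na(y) & !is.na(g)
  yv <- y[ok]; gv <- g[ok]
  n <- length(yv)
  if (stats::sd(gv) == 0) return(NULL)   # monomorphic in sample
  X <- cbind(`(Intercept)` = 1, g = gv,
             if (!is.null(C)) C[ok, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!(2L %in% keep)) return(NULL)    # genotype collinear with covariates
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  dfRes <- n - qrX$rank
  if (dfRes < 1L) return(NULL)
  coefs <- qr.coef(qrX, yv)
  res <- yv - X %*% coefs
  sigma2 <- sum(res^2) / dfRes
  XtXinv <- chol2inv(qr.R(qrX))
  gi <- match("g", colnames(X))
  beta <- coefs[gi]
  se <- sqrt(sigma2 * XtXinv[gi, gi])
  if (!is.finite(se) || se == 0) {
    tstat <- sign(beta) * Inf
    p <- .Machine$double.xmin
  } else {
    tstat <- beta / se
    p <- max(2 * stats::pt(-abs(tstat), df = dfRes), .Machine$double.xmin)
  }
  list(beta = unname(beta), se = unname(se), tstat = unname(tstat),
       p = p, n_used = n, maf = min(mean(gv), 1 - mean(gv)))
}

#' Covariate-adjusted single-variant fit
#'
#' Ordinary least squares of the (transformed) phenotype on an intercept,
#' the 0/1 genotype and the covariate indicators; lines with a missing
#' phenotype or call are dropped for this variant only. Only the genotype
#' term is reported (the "hide-covar" convention); the two-sided p-value
#' comes from the t distribution on the residual degrees of freedom and is
#' floored at the smallest positive representable double. Variants that are
#' monomorphic among the used lines (or collinear with the covariates)
#' return NULL.
#'
#' @param y numeric phenotype vector (already transformed as desired).
#' @param g 0/1/NA genotype calls, same order as \code{y}.
#' @param cov optional [CovariateTable] aligned with \code{y}.
#' @param varianceStandardize passed to the covariate design.
#' @return list(beta, se, tstat, p, n_used, maf) or NULL.
#' @export
fitSingleVariant <- function(y, g, cov = NULL, varianceStandardize = TRUE) {
  C <- .covariateDesign(cov, standardize = varianceStandardize)
  .fitVariant(y, g, C)
}

#' Run a covariate-adjusted association scan
#'
#' Filters variants ([filterVariants()]), transforms the phenotype
#' (rank-based inverse normal, then unit-variance scaling when configured),
#' fits every retained variant with [fitSingleVariant()] semantics and
#' returns the results sorted by p-value. Lines are matched by canonical id
#' across phenotype, panel and covariates. Fully deterministic.
#'
#' @param y named numeric phenotype vector (names = canonical line ids), or
#'   the output of [phenotypeValues()].
#' @param panel a [GenotypePanel].
#' @param cov optional [CovariateTable].
#' @param cfg an [assocConfig()].
#' @return list with \code{results} (data.frame sorted by p: variant_id,
#'   chrom, pos, class, beta, se, tstat, p, n_used, maf), \code{top}
#'   (first 1000 rows), \code{hits} (p < 1e-3), \code{filter} report and
#'   \code{n_skipped} monomorphic-in-sample count.
#' @export
runGwas <- function(y, panel, cov = NULL, cfg = assocConfig()) {
  stopifnot(is(panel, "GenotypePanel"))
  if (is.null(names(y)))
    stop("phenotype vector must be named by line id", call. = FALSE)
  lines <- lineIds(panel)
  if (!is.null(cov)) lines <- intersect(lines, lineIds(cov))
  lines <- intersect(lines, names(y)[!is.na(y)])
  nCov <- if (is.null(cov)) 0L else 6L
  if (length(lines) < nCov + 3L)
    stop("insufficient sample: ", length(lines), " usable lines",
         call. = FALSE)
  yv <- y[lines]
  if (cfg$quantileNormalize) yv <- rankInverseNormal(yv)
  if (cfg$varianceStandardize) yv <- as.numeric(scale(yv))
  names(yv) <- lines

  calls <- genotypeCalls(panel)[match(lines, lineIds(panel)), ,
                                drop = FALSE]
  flt <- filterVariants(GenotypePanel(lines, variantInfo(panel), calls),
                        cfg)
  C <- if (is.null(cov)) NULL
       else .covariateDesign(cov, cfg$varianceStandardize)[
         match(lines, lineIds(cov)), , drop = FALSE]

  vinfo <- variantInfo(panel)
  rows <- vector("list", length(flt$keep))
  nSkip <- 0L
  for (k in seq_along(flt$keep)) {
    vid <- flt$keep[k]
    fit <- .fitVariant(yv, calls[, vid], C)
    if (is.null(fit)) { nSkip <- nSkip + 1L; next }
    rows[[k]] <- c(list(variant_id = vid), fit)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  results <- if (length(rows)) {
    data.frame(
      variant_id = vapply(rows, `[[`, character(1), "variant_id"),
      beta = vapply(rows, `[[`, numeric(1), "beta"),
      se = vapply(rows, `[[`, numeric(1), "se"),
      tstat = vapply(rows, `[[`, numeric(1), "tstat"),
      p = vapply(rows, `[[`, numeric(1), "p"),
      n_used = vapply(rows, `[[`, numeric(1), "n_used"),
      maf = vapply(rows, `[[`, numeric(1), "maf"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(), beta = numeric(), se = numeric(),
               tstat = numeric(), p = numeric(), n_used = numeric(),
               maf = numeric(), stringsAsFactors = FALSE)
  }
  mi <- match(results$variant_id, vinfo$variant_id)
  results <- cbind(results[, "variant_id", drop = FALSE],
                   vinfo[mi, c("chrom", "pos", "class"), drop = FALSE],
                   results[, -1, drop = FALSE])
  results <- results[order(results$p, results$variant_id), , drop = FALSE]
  rownames(results) <- NULL
  list(results = results,
       top = utils::head(results, 1000L),
       hits = results[results$p < 1e-3, , drop = FALSE],
       filter = flt$report, n_skipped = nSkip)
}

#' Significance counts per threshold plus the Bonferroni threshold
#'
#' For each configured threshold, counts results with p <= threshold; the
#' Bonferroni threshold is \code{alphaBonferroni / m} where m is the number
#' of tested variants (pass \code{nVariants} to use a different family
#' size, e.g. the full published panel).
#'
#' @param results result data.frame from [runGwas()].
#' @param cfg an [assocConfig()].
#' @param nVariants family size for the Bonferroni threshold (default:
#'   number of rows in \code{results}).
#' @return list with \code{counts} (data.frame threshold/n) and
#'   \code{bonferroni} (threshold, n).
#' @export
significanceSummary <- function(results, cfg = assocConfig(),
                                nVariants = nrow(results)) {
  if (!nrow(results)) stop("no association results", call. = FALSE)
  counts <- data.frame(
    threshold = cfg$reportThresholds,
    n = vapply(cfg$reportThresholds,
               function(th) sum(results$p <= th), numeric(1)))
  bonf <- cfg$alphaBonferroni / nVariants
  list(counts = counts,
       bonferroni = list(threshold = bonf,
                         n = sum(results$p <= bonf)))
}

#' Expected vs observed -log10 p pairs for a QQ plot
#'
#' @param results result data.frame with a \code{p} column.
#' @return data.frame(expected, observed) of -log10 p values, both sorted
#'   most-significant first; expected quantiles are -log10((i - 0.5)/m).
#' @export
qqData <- function(results) {
  p <- results$p
  if (!length(p)) stop("no association results", call. = FALSE)
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(sort(p)))
}

#' Advisory covariate screen
#'
#' Per-covariate Kruskal-Wallis tests (one factor at a time), a multifactor
#' ANOVA fitting all six covariates simultaneously, and a Shapiro-Wilk
#' normality test of the raw phenotype. Advisory only: the association
#' model always includes all covariates regardless of these results.
#' Single-category factors are skipped with a note.
#'
#' @param y named numeric raw phenotype vector (names = line ids).
#' @param cov a [CovariateTable].
#' @return list with \code{kruskal} (data.frame covariate/statistic/p),
#'   \code{anova} (data.frame term/df/statistic/p), \code{shapiro}
#'   (list statistic/p) and \code{skipped} notes.
#' @export
covariateScreen <- function(y, cov) {
  stopifnot(is(cov, "CovariateTable"))
  lines <- intersect(names(y)[!is.na(y)], lineIds(cov))
  yv <- y[lines]
  cd <- covariateData(cov)[match(lines, lineIds(cov)), , drop = FALSE]
  cd[] <- lapply(cd, droplevels)
  skipped <- character()
  kw <- list()
  for (nm in names(cd)) {
    if (nlevels(cd[[nm]]) < 2L) {
      skipped <- c(skipped, sprintf("%s: single category, skipped", nm))
      next
    }
    k <- stats::kruskal.test(yv, cd[[nm]])
    kw[[length(kw) + 1L]] <- data.frame(
      covariate = nm, statistic = unname(k$statistic),
      df = unname(k$parameter), p = k$p.value, stringsAsFactors = FALSE)
  }
  kruskal <- if (length(kw)) do.call(rbind, kw)
             else data.frame(covariate = character(), statistic = numeric(),
                             df = numeric(), p = numeric())
  usable <- names(cd)[vapply(cd, nlevels, integer(1)) >= 2L]
  anovaTab <- NULL
  if (length(usable)) {
    dat <- cbind(data.frame(.y = yv), cd[usable])
    fml <- stats::as.formula(paste(".y ~", paste(usable, collapse = " + ")))
    aovFit <- stats::aov(fml, data = dat)
    s <- summary(aovFit)[[1L]]
    terms <- trimws(rownames(s))
    keep <- terms != "Residuals"
    anovaTab <- data.frame(term = terms[keep], df = s$Df[keep],
                           statistic = s$`F value`[keep],
                           p = s$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  }
  sw <- stats::shapiro.test(yv)
  list(kruskal = kruskal, anova = anovaTab,
       shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
       skipped = skipped)
}

#' Per-genotype value groups for one variant
#'
#' Partitions phenotype values by genotype call (ref-homozygous,
#' alt-homozygous, missing), e.g. for the effect boxplot of a top variant.
#'
#' @param y numeric phenotype vector.
#' @param g 0/1/NA calls, same order.
#' @return list with \code{ref}, \code{alt}, \code{missing} value vectors
#'   and \code{counts}.
#' @export
genotypeGroupValues <- function(y, g) {
  stopifnot(length(y) == length(g))
  ref <- y[!is.na(g) & g == 0]
  alt <- y[!is.na(g) & g == 1]
  mis <- y[is.na(g)]
  list(ref = ref, alt = alt, missing = mis,
       counts = c(ref = length(ref), alt = length(alt),
                  missing = length(mis)))
}

#' Phenome-wide lookup of one variant
#'
#' Scans a store of per-phenotype association results (a named list of
#' [runGwas()] result data.frames, names = phenotype keys) for one variant
#' and returns its row per phenotype, sorted by ascending p.
#'
#' @param variantId "chrom:pos" identifier.
#' @param store named list of result data.frames.
#' @return data.frame(phenotype, variant_id, beta, se, tstat, p, n_used,
#'   maf) sorted by p; zero rows (with a message attribute "notice") when
#'   the variant passed filters nowhere.
#' @export
phewasLookup <- function(variantId, store) {
  rows <- list()
  for (key in names(store)) {
    res <- store[[key]]
    if (is.list(res) && !is.data.frame(res)) res <- res$results
    hit <- res[res$variant_id == variantId, , drop = FALSE]
    if (nrow(hit)) {
      hit <- hit[, c("variant_id", "beta", "se", "tstat", "p", "n_used",
                     "maf"), drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(phenotype = key, stringsAsFactors = FALSE), hit)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(phenotype = character(), variant_id = character(),
                         beta = numeric(), se = numeric(),
                         tstat = numeric(), p = numeric(),
                         n_used = numeric(), maf = numeric(),
                         stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    attr(out, "notice") <- sprintf(
      "variant %s passed filters in no stored phenotype", variantId)
  out
}
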