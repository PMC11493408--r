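## Seeded synthetic-panel generator: genotypes, covariates and
## block-correlated multi-study phenotypes with the statistical structure
## the downstream analyses assume.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Reference-panel variant catalog (published composition)
#'
#' The published DGRP freeze (dm3 assembly) variant bookkeeping: per-class
#' counts and the printed total. Used as the default class mix for
#' [simulateGenotypes()] and for Bonferroni-threshold arithmetic at the full
#' panel scale.
#'
#' @return list with \code{classes} (named integer vector over SNP,
#'   deletion, insertion, MNP) and \code{total} (the printed total count).
#' @examples
#' cat <- dgrpVariantCatalog()
#' sum(cat$classes) == cat$total
#' @export
dgrpVariantCatalog <- function() {
  list(
    classes = c(SNP = 3963420L, deletion = 293363L, insertion = 169053L,
                MNP = 12591L),
    total = 4438427L
  )
}

#' Build a validated simulation configuration
#'
#' Defaults describe a desk-scale panel: 200 lines, 1000 variants with alt
#' frequencies in [0.05, 0.5], 3 curated studies of 5 quantitative
#' phenotypes each (both sexes), within-study correlation 0.6 vs cross-study
#' 0.05 (mirroring the strong within-study block structure of real
#' multi-study panels), cross-sex correlation 0.5, 10% missing phenotype
#' cells and 2% missing genotype calls. \code{noiseSd = NA} derives
#' \code{sqrt(1 - withinCorr)} so that the correlation targets hold exactly
#' under the unit-variance factor model.
#'
#' @param nLines,nVariants panel dimensions.
#' @param mafRange alt-allele frequency bounds (low, high], high <= 0.5.
#' @param nStudies,phenosPerStudy study layout.
#' @param categoricalPerStudy extra categorical phenotypes per study.
#' @param withinCorr,crossCorr,crossSexCorr correlation targets
#'   (0 <= crossCorr <= withinCorr <= 1).
#' @param missingRate MCAR phenotype missingness.
#' @param causalEffects data.frame(variant, beta, study, pheno): spiked
#'   genotype effects (beta on the unit-variance phenotype scale), applied to
#'   both sexes of the target phenotype.
#' @param covariateEffects numeric(6): effects of symbiont, sv1..sv5 applied
#'   to every phenotype.
#' @param noiseSd unique-noise sd; NA derives sqrt(1 - withinCorr).
#' @param symbiontPrev symbiont prevalence.
#' @param svLevels categories per structural-variant covariate.
#' @param genoMissingRate MCAR genotype missingness.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a [SimConfig].
#' @export
simConfig <- function(nLines = 200, nVariants = 1000,
                      mafRange = c(0.05, 0.5),
                      nStudies = 3, phenosPerStudy = 5,
                      categoricalPerStudy = 0,
                      withinCorr = 0.6, crossCorr = 0.05,
                      crossSexCorr = 0.5,
                      missingRate = 0.1,
                      causalEffects = NULL,
                      covariateEffects = numeric(6),
                      noiseSd = NA_real_,
                      symbiontPrev = 0.5, svLevels = 3,
                      genoMissingRate = 0.02, seed = 1) {
  if (is.null(causalEffects))
    causalEffects <- data.frame(variant = integer(), beta = numeric(),
                                study = integer(), pheno = integer())
  phenosPerStudy <- rep_len(as.integer(phenosPerStudy), nStudies)
  if (is.na(noiseSd)) noiseSd <- sqrt(1 - withinCorr)
  new("SimConfig",
      nLines = as.integer(nLines), nVariants = as.integer(nVariants),
      mafRange = as.numeric(mafRange),
      nStudies = as.integer(nStudies), phenosPerStudy = phenosPerStudy,
      categoricalPerStudy = as.integer(categoricalPerStudy),
      withinCorr = as.numeric(withinCorr),
      crossCorr = as.numeric(crossCorr),
      crossSexCorr = as.numeric(crossSexCorr),
      missingRate = as.numeric(missingRate),
      causalEffects = causalEffects,
      covariateEffects = as.numeric(covariateEffects),
      noiseSd = as.numeric(noiseSd),
      symbiontPrev = as.numeric(symbiontPrev),
      svLevels = as.integer(svLevels),
      genoMissingRate = as.numeric(genoMissingRate),
      seed = as.integer(seed))
}

.simLineIds <- function(n) sprintf("DGRP_%03d", seq_len(n))

#' Simulate a homozygous biallelic genotype panel
#'
#' Per-variant alt-allele frequencies are drawn uniformly in
#' \code{mafRange}; calls are independent Bernoulli draws per line (0/1
#' homozygous coding); missing calls are injected MCAR at
#' \code{genoMissingRate}. Variant classes are sampled with probabilities
#' proportional to the published panel composition
#' ([dgrpVariantCatalog()]); positions are unique per chromosome arm.
#'
#' @param cfg a [SimConfig].
#' @return a [GenotypePanel].
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  .withSeed(cfg@seed, {
    nL <- cfg@nLines; nV <- cfg@nVariants
    arms <- c("2L", "2R", "3L", "3R", "X", "4")
    chrom <- sample(arms, nV, replace = TRUE)
    pos <- integer(nV)
    for (a in arms) {
      idx <- which(chrom == a)
      pos[idx] <- sort(sample.int(25e6, length(idx)))
    }
    cat <- dgrpVariantCatalog()
    cls <- sample(names(cat$classes), nV, replace = TRUE,
                  prob = cat$classes / sum(cat$classes))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nV, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    freq <- stats::runif(nV, cfg@mafRange[1], cfg@mafRange[2])
    calls <- matrix(stats::rbinom(nL * nV, 1L,
                                  rep(freq, each = nL)), nrow = nL)
    if (cfg@genoMissingRate > 0) {
      miss <- stats::runif(nL * nV) < cfg@genoMissingRate
      calls[miss] <- NA
    }
    variants <- data.frame(
      variant_id = paste(chrom, pos, sep = ":"),
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt), class = cls,
      stringsAsFactors = FALSE)
    storage.mode(calls) <- "double"
    GenotypePanel(.simLineIds(nL), variants, calls)
  })
}

#' Simulate the six known covariates
#'
#' Symbiont infection status is Bernoulli(\code{symbiontPrev}); the five
#' structural-variant covariates are categorical with \code{svLevels}
#' levels, category probabilities decaying geometrically (the common pattern
#' of one frequent standard arrangement plus rarer alternatives).
#'
#' @param cfg a [SimConfig].
#' @return a [CovariateTable].
#' @export
simulateCovariates <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  .withSeed(cfg@seed + 1L, {
    nL <- cfg@nLines
    probs <- 0.5 ^ seq_len(cfg@svLevels)
    probs <- probs / sum(probs)
    data <- data.frame(
      symbiont = factor(stats::rbinom(nL, 1L, cfg@symbiontPrev),
                        levels = c(0, 1), labels = c("neg", "pos")),
      stringsAsFactors = FALSE)
    for (k in 1:5)
      data[[paste0("sv", k)]] <- factor(
        sample(paste0("st", seq_len(cfg@svLevels)), nL, replace = TRUE,
               prob = probs))
    CovariateTable(.simLineIds(nL), data)
  })
}

## A pair of line-length standard-normal draws correlated at rho across
## sexes (column 1 = F, column 2 = M).
.sexPair <- function(n, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(F = z1, M = rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Simulate block-correlated multi-study phenotypes
#'
#' Each phenotype is a three-component Gaussian factor model per line:
#' a global factor loaded at \eqn{\sqrt{\rho_x}}, a study factor loaded at
#' \eqn{\sqrt{\rho_w - \rho_x}}, and unique noise with sd \code{noiseSd}.
#' With \code{noiseSd = sqrt(1 - withinCorr)} (the default derivation) the
#' expected Pearson correlation between two phenotypes is exactly
#' \code{withinCorr} within a study and \code{crossCorr} across studies.
#' Every random component is drawn as a cross-sex correlated pair at
#' \code{crossSexCorr}, so the same trait measured in females and males
#' correlates at \code{crossSexCorr} in expectation. Spiked causal variants
#' add \eqn{g\beta} (missing calls contribute the variant's mean dosage) and
#' covariate effects add \eqn{C\gamma} to every phenotype; MCAR missingness
#' is applied last. Categorical phenotypes (if requested) are 3-level codes
#' independent of the quantitative structure.
#'
#' @param cfg a [SimConfig].
#' @param panel a [GenotypePanel] over the same lines.
#' @param cov a [CovariateTable] over the same lines.
#' @return a valid [PhenotypeRegistry] with per-study tables holding F and M
#'   rows for every line.
#' @export
simulateStudyPhenotypes <- function(cfg, panel, cov) {
  stopifnot(is(cfg, "SimConfig"), is(panel, "GenotypePanel"),
            is(cov, "CovariateTable"))
  validObject(cfg)
  if (!identical(lineIds(panel), lineIds(cov)))
    stop("panel and covariate table must share the same line set",
         call. = FALSE)
  lines <- lineIds(panel)
  nL <- length(lines)
  rho_mf <- cfg@crossSexCorr
  aG <- sqrt(cfg@crossCorr)
  aS <- sqrt(cfg@withinCorr - cfg@crossCorr)
  sdE <- cfg@noiseSd
  if (any(cfg@causalEffects$pheno > max(cfg@phenosPerStudy)))
    stop("causal phenotype index out of range", call. = FALSE)

  ## covariate contribution, identical for both sexes
  cd <- covariateData(cov)
  gamma <- cfg@covariateEffects
  covShift <- gamma[1] * (as.integer(cd$symbiont) - 1)
  for (k in 1:5)
    covShift <- covShift + gamma[k + 1] *
      scale(as.integer(cd[[paste0("sv", k)]]))[, 1]

  calls <- genotypeCalls(panel)

  .withSeed(cfg@seed + 2L, {
    G <- .sexPair(nL, rho_mf)
    tables <- vector("list", cfg@nStudies)
    descr <- list()
    studyIds <- sprintf("S%02d", seq_len(cfg@nStudies))
    cats6 <- c("Life history traits", "Immunity", "Toxicity", "Resistance",
               "Fecundity", "Aging")
    for (s in seq_len(cfg@nStudies)) {
      Fs <- .sexPair(nL, rho_mf)
      nP <- cfg@phenosPerStudy[s]
      nC <- cfg@categoricalPerStudy
      phenoIds <- c(sprintf("ph%02d", seq_len(nP)),
                    if (nC) sprintf("cat%02d", seq_len(nC)))
      vals <- matrix(NA_real_, nrow = 2L * nL, ncol = nP + nC,
                     dimnames = list(NULL, phenoIds))
      sexCol <- rep(c("F", "M"), each = nL)
      for (j in seq_len(nP)) {
        E <- .sexPair(nL, rho_mf)
        y <- aG * G + aS * Fs + sdE * E   # nL x 2 (F, M)
        ce <- cfg@causalEffects
        ce <- ce[ce$study == s & ce$pheno == j, , drop = FALSE]
        for (r in seq_len(nrow(ce))) {
          g <- calls[, ce$variant[r]]
          g[is.na(g)] <- mean(g, na.rm = TRUE)
          y <- y + ce$beta[r] * g
        }
        y <- y + covShift
        vals[, j] <- c(y[, "F"], y[, "M"])
      }
      if (nC)
        for (j in seq_len(nC))
          vals[, nP + j] <- sample.int(3L, 2L * nL, replace = TRUE)
      if (cfg@missingRate > 0) {
        miss <- stats::runif(length(vals)) < cfg@missingRate
        vals[miss] <- NA
      }
      tables[[s]] <- PhenotypeTable(studyIds[s], rep(lines, 2L), sexCol,
                                    vals)
      dtype <- c(rep("quantitative", nP), rep("categorical", nC))
      for (sex in c("F", "M"))
        descr[[length(descr) + 1L]] <- data.frame(
          study_id = studyIds[s], phenotype_id = phenoIds,
          name = paste0("trait ", phenoIds, " (", studyIds[s], ")"),
          sex = sex, unit = "a.u.", dtype = dtype, is_summary = TRUE,
          stringsAsFactors = FALSE)
    }
    names(tables) <- studyIds
    studies <- data.frame(
      study_id = studyIds,
      title = paste("Synthetic study", seq_len(cfg@nStudies)),
      categories = cats6[(seq_len(cfg@nStudies) - 1L) %% 6L + 1L],
      status = "curated", stringsAsFactors = FALSE)
    PhenotypeRegistry(studies, do.call(rbind, descr), tables)
  })
}

#' Simulate a complete panel in one call
#'
#' @param cfg a [SimConfig].
#' @return list with \code{panel}, \code{covariates}, \code{registry}.
#' @export
simulatePanel <- function(cfg) {
  panel <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  reg <- simulateStudyPhenotypes(cfg, panel, cov)
  list(panel = panel, covariates = cov, registry = reg)
}

#' Emit a fixture directory of guideline-conformant TSVs
#'
#' Writes the registry ([writeRegistry()] layout), genotype calls + variant
#' metadata, covariates and a manifest listing every emitted file. Reading
#' the directory back reproduces the inputs exactly (numbers serialized at
#' full precision).
#'
#' @param reg a [PhenotypeRegistry].
#' @param panel a [GenotypePanel].
#' @param cov a [CovariateTable].
#' @param dir output directory.
#' @return character vector of emitted file names, invisibly.
#' @export
emitFixtures <- function(reg, panel, cov, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeRegistry(reg, dir)
  writeGenotypePanel(panel, file.path(dir, "genotypes.tsv"),
                     file.path(dir, "variants.tsv"))
  writeCovariateTable(cov, file.path(dir, "covariates.tsv"))
  files <- sort(setdiff(list.files(dir), "manifest.tsv"))
  .writeAtomic(function(tmp) {
    utils::write.table(data.frame(file = files, stringsAsFactors = FALSE),
                       tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, file.path(dir, "manifest.tsv"))
  invisible(files)
}
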