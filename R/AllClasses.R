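#' @import methods
NULL

#' PhenotypeTable: one study's line-by-phenotype matrix
#'
#' Holds one study's harmonized phenotyping data: one row per (line, sex)
#' combination, one column per phenotype. Line identifiers are expected in
#' canonical \code{DGRP_XXX} form (see [normalizeLineId()]); sex codes are
#' \code{"M"}, \code{"F"} or the literal string \code{"NA"} for sex-mixed or
#' population-level measurements. Values are numeric; categorical phenotypes
#' are stored as integer level codes (their dtype lives in the registry
#' descriptors, not here). Missing measurements are \code{NA}.
#'
#' Validity checks are structural (matching lengths, numeric matrix);
#' guideline-level problems such as malformed identifiers or duplicated
#' (line, sex) rows are deliberately representable so that
#' [validateRegistry()] can detect and report them.
#'
#' @slot studyId single study identifier.
#' @slot lines character vector of line identifiers, one per row.
#' @slot sex character vector of sex codes ("M"/"F"/"NA"), one per row.
#' @slot values numeric matrix, rows aligned with \code{lines}/\code{sex},
#'   columns named by phenotype identifier.
#' @export
setClass("PhenotypeTable",
  representation(
    studyId = "character",
    lines   = "character",
    sex     = "character",
    values  = "matrix"
  )
)

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  if (length(object@studyId) != 1L)
    msg <- c(msg, "studyId must be a single string")
  n <- length(object@lines)
  if (length(object@sex) != n)
    msg <- c(msg, "lines and sex must have the same length")
  if (nrow(object@values) != n)
    msg <- c(msg, "values must have one row per (line, sex) entry")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (ncol(object@values) > 0L && is.null(colnames(object@values)))
    msg <- c(msg, "values columns must be named by phenotype id")
  if (length(msg)) msg else TRUE
})

#' PhenotypeRegistry: multi-study phenome container
#'
#' The join surface for all analyses: study metadata, per-phenotype
#' descriptors (study, phenotype, name, sex, unit, dtype, summary flag) and
#' the per-study [PhenotypeTable] objects.
#'
#' @slot studies data.frame with columns \code{study_id}, \code{title},
#'   \code{categories} (comma-separated tags) and \code{status}
#'   (one of "submitted", "under_curation", "curated").
#' @slot descriptors data.frame with columns \code{study_id},
#'   \code{phenotype_id}, \code{name}, \code{sex}, \code{unit}, \code{dtype}
#'   ("quantitative" or "categorical") and \code{is_summary}.
#' @slot tables named list of [PhenotypeTable], names equal to study ids.
#' @export
setClass("PhenotypeRegistry",
  representation(
    studies     = "data.frame",
    descriptors = "data.frame",
    tables      = "list"
  )
)

setValidity("PhenotypeRegistry", function(object) {
  msg <- character()
  need_s <- c("study_id", "title", "categories", "status")
  need_d <- c("study_id", "phenotype_id", "name", "sex", "unit", "dtype",
              "is_summary")
  if (!all(need_s %in% names(object@studies)))
    msg <- c(msg, paste("studies must have columns:",
                        paste(need_s, collapse = ", ")))
  if (!all(need_d %in% names(object@descriptors)))
    msg <- c(msg, paste("descriptors must have columns:",
                        paste(need_d, collapse = ", ")))
  if (length(object@tables) &&
      (is.null(names(object@tables)) || anyDuplicated(names(object@tables))))
    msg <- c(msg, "tables must be uniquely named by study id")
  if (!all(vapply(object@tables, is, logical(1), class2 = "PhenotypeTable")))
    msg <- c(msg, "tables must all be PhenotypeTable objects")
  if (!length(msg)) {
    bad <- !(object@descriptors$study_id %in% object@studies$study_id)
    if (any(bad))
      msg <- c(msg, "every descriptor must reference an existing study")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypePanel: lines x biallelic variants over homozygous lines
#'
#' Genotype calls for near-fully homozygous inbred lines are coded 0
#' (ref/ref), 1 (alt/alt) or \code{NA} (missing); heterozygotes do not occur.
#' Variant identifiers follow the \code{chrom:pos} convention (1-based
#' positions on chromosome arms 2L, 2R, 3L, 3R, X, 4).
#'
#' @slot lines character vector of canonical line ids.
#' @slot variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{class}
#'   (SNP/deletion/insertion/MNP).
#' @slot calls numeric matrix lines x variants with entries in {0, 1, NA};
#'   columns named by variant_id.
#' @export
setClass("GenotypePanel",
  representation(
    lines    = "character",
    variants = "data.frame",
    calls    = "matrix"
  )
)

setValidity("GenotypePanel", function(object) {
  msg <- character()
  need_v <- c("variant_id", "chrom", "pos", "ref", "alt", "class")
  if (!all(need_v %in% names(object@variants)))
    msg <- c(msg, paste("variants must have columns:",
                        paste(need_v, collapse = ", ")))
  if (nrow(object@calls) != length(object@lines))
    msg <- c(msg, "calls must have one row per line")
  if (!length(msg) && ncol(object@calls) != nrow(object@variants))
    msg <- c(msg, "calls must have one column per variant")
  if (!length(msg) && anyDuplicated(object@variants$variant_id))
    msg <- c(msg, "variant ids must be unique")
  vals <- object@calls[!is.na(object@calls)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    msg <- c(msg, "calls must be 0, 1 or NA (homozygous coding)")
  if (length(msg)) msg else TRUE
})

#' CovariateTable: known covariates per line
#'
#' The six known covariates used for association correction: endosymbiont
#' (Wolbachia) infection status plus five major structural-variant genotypes,
#' treated here as opaque categorical factors.
#'
#' @slot lines character vector of canonical line ids, one row each.
#' @slot data data.frame with factor columns \code{symbiont},
#'   \code{sv1}..\code{sv5}; no missing entries.
#' @export
setClass("CovariateTable",
  representation(
    lines = "character",
    data  = "data.frame"
  )
)

setValidity("CovariateTable", function(object) {
  msg <- character()
  need <- c("symbiont", paste0("sv", 1:5))
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("covariate data must have columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@data) != length(object@lines))
    msg <- c(msg, "one covariate row per line required")
  if (anyDuplicated(object@lines))
    msg <- c(msg, "duplicate lines in covariate table")
  if (!length(msg) && anyNA(object@data))
    msg <- c(msg, "covariates must be complete (no missing values)")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters for the synthetic-panel generator
#'
#' Bundles every knob of the generative model
#' \eqn{y = g\beta + C\gamma + \mathrm{factors} + \sigma\epsilon}:
#' panel size, allele-frequency bounds, study/phenotype layout, the
#' correlation targets (within-study \eqn{\rho_w}, cross-study \eqn{\rho_x},
#' cross-sex \eqn{\rho_{mf}}), missingness, spiked causal effects and
#' covariate effects, plus the seed that makes every generator fully
#' deterministic. Construct with [simConfig()], which fills defaults and
#' validates.
#'
#' @slot nLines,nVariants panel dimensions.
#' @slot mafRange length-2 alt-allele frequency bounds in (0, 0.5].
#' @slot nStudies,phenosPerStudy study layout (phenosPerStudy recycled to
#'   nStudies).
#' @slot categoricalPerStudy number of additional categorical phenotypes
#'   appended to each study.
#' @slot withinCorr,crossCorr,crossSexCorr correlation targets.
#' @slot missingRate MCAR missingness fraction for phenotype cells.
#' @slot causalEffects data.frame(variant, beta, study, pheno).
#' @slot covariateEffects numeric length 6 (symbiont, sv1..sv5).
#' @slot noiseSd unique-noise standard deviation; NA derives
#'   \code{sqrt(1 - withinCorr)} so the correlation targets hold exactly.
#' @slot symbiontPrev symbiont infection prevalence.
#' @slot svLevels number of categories per structural-variant covariate.
#' @slot genoMissingRate MCAR missingness fraction for genotype calls.
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
  representation(
    nLines = "integer", nVariants = "integer",
    mafRange = "numeric",
    nStudies = "integer", phenosPerStudy = "integer",
    categoricalPerStudy = "integer",
    withinCorr = "numeric", crossCorr = "numeric", crossSexCorr = "numeric",
    missingRate = "numeric",
    causalEffects = "data.frame",
    covariateEffects = "numeric",
    noiseSd = "numeric",
    symbiontPrev = "numeric",
    svLevels = "integer",
    genoMissingRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nLines < 2L)
    msg <- c(msg, "nLines must be at least 2")
  if (object@nVariants < 1L || object@nStudies < 1L ||
      any(object@phenosPerStudy < 1L))
    msg <- c(msg, "all counts must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1] <= 0 || mr[1] > mr[2] || mr[2] > 0.5)
    msg <- c(msg, "mafRange must satisfy 0 < low <= high <= 0.5")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (object@genoMissingRate < 0 || object@genoMissingRate >= 1)
    msg <- c(msg, "genoMissingRate must be in [0, 1)")
  if (object@withinCorr < 0 || object@withinCorr > 1 ||
      object@crossCorr < 0 || object@crossCorr > object@withinCorr)
    msg <- c(msg, "need 0 <= crossCorr <= withinCorr <= 1")
  if (abs(object@crossSexCorr) > 1)
    msg <- c(msg, "crossSexCorr must be in [-1, 1]")
  if (length(object@covariateEffects) != 6L)
    msg <- c(msg, "covariateEffects must have length 6")
  ce <- object@causalEffects
  if (!all(c("variant", "beta", "study", "pheno") %in% names(ce)))
    msg <- c(msg, "causalEffects needs columns variant, beta, study, pheno")
  else if (nrow(ce)) {
    if (any(ce$variant < 1L) || any(ce$variant > object@nVariants))
      msg <- c(msg, "causal variant index out of range")
    if (any(ce$study < 1L) || any(ce$study > object@nStudies))
      msg <- c(msg, "causal study index out of range")
  }
  if (length(msg)) msg else TRUE
})
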