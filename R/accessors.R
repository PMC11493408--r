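#' Accessors for the panel data classes
#'
#' Slot access for [PhenotypeTable], [PhenotypeRegistry], [GenotypePanel] and
#' [CovariateTable]; always use these rather than \code{@}.
#'
#' @param x a panel data object.
#' @return the corresponding component (character vector, data.frame, matrix
#'   or list, depending on the accessor).
#' @name accessors
NULL

#' @rdname accessors
setMethod("lineIds", "PhenotypeTable", function(x) x@lines)
#' @rdname accessors
setMethod("lineIds", "GenotypePanel", function(x) x@lines)
#' @rdname accessors
setMethod("lineIds", "CovariateTable", function(x) x@lines)

#' @rdname accessors
setMethod("sexCodes", "PhenotypeTable", function(x) x@sex)

#' @rdname accessors
setMethod("phenoValues", "PhenotypeTable", function(x) x@values)

#' @rdname accessors
setMethod("studyId", "PhenotypeTable", function(x) x@studyId)

#' @rdname accessors
setMethod("studies", "PhenotypeRegistry", function(x) x@studies)
#' @rdname accessors
setMethod("descriptors", "PhenotypeRegistry", function(x) x@descriptors)
#' @rdname accessors
setMethod("phenoTables", "PhenotypeRegistry", function(x) x@tables)

#' @rdname accessors
setMethod("variantInfo", "GenotypePanel", function(x) x@variants)
#' @rdname accessors
setMethod("genotypeCalls", "GenotypePanel", function(x) x@calls)

#' @rdname accessors
setMethod("covariateData", "CovariateTable", function(x) x@data)

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable '%s': %d (line, sex) rows x %d phenotypes\n",
              object@studyId, length(object@lines), ncol(object@values)))
  tab <- table(factor(object@sex, levels = c("F", "M", "NA")))
  cat("  rows per sex:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
})

setMethod("show", "PhenotypeRegistry", function(object) {
  cat(sprintf("PhenotypeRegistry: %d studies, %d phenotype descriptors\n",
              nrow(object@studies), nrow(object@descriptors)))
  if (nrow(object@descriptors)) {
    tab <- table(factor(object@descriptors$sex, levels = c("F", "M", "NA")))
    cat("  descriptors per sex:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d lines x %d variants\n",
              length(object@lines), nrow(object@variants)))
  if (nrow(object@variants)) {
    tab <- table(object@variants$class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "CovariateTable", function(object) {
  cat(sprintf("CovariateTable: %d lines x %d covariates\n",
              length(object@lines), ncol(object@data)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d lines, %d variants, %d studies (%s phenos each)\n",
    "  rho_w=%.2f rho_x=%.2f rho_mf=%.2f noiseSd=%.3f missing=%.2f seed=%d\n"),
    object@nLines, object@nVariants, object@nStudies,
    paste(object@phenosPerStudy, collapse = ","),
    object@withinCorr, object@crossCorr, object@crossSexCorr,
    object@noiseSd, object@missingRate, object@seed))
})

#' Construct a PhenotypeTable
#'
#' @param studyId study identifier.
#' @param lines character vector of line ids (one per row).
#' @param sex character vector of sex codes "M"/"F"/"NA" (one per row).
#' @param values numeric matrix with phenotype columns (named).
#' @return a [PhenotypeTable].
#' @export
PhenotypeTable <- function(studyId, lines, sex, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("PhenotypeTable", studyId = as.character(studyId),
      lines = as.character(lines), sex = as.character(sex), values = values)
}

#' Construct a PhenotypeRegistry
#'
#' @param studies study metadata data.frame (study_id, title, categories,
#'   status).
#' @param descriptors phenotype descriptor data.frame.
#' @param tables named list of [PhenotypeTable] (names = study ids).
#' @return a [PhenotypeRegistry].
#' @export
PhenotypeRegistry <- function(studies, descriptors, tables) {
  new("PhenotypeRegistry", studies = studies, descriptors = descriptors,
      tables = tables)
}

#' Construct a GenotypePanel
#'
#' @param lines character vector of line ids.
#' @param variants variant metadata data.frame (variant_id, chrom, pos, ref,
#'   alt, class).
#' @param calls lines x variants matrix over {0, 1, NA}.
#' @return a [GenotypePanel].
#' @export
GenotypePanel <- function(lines, variants, calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  colnames(calls) <- variants$variant_id
  rownames(calls) <- lines
  new("GenotypePanel", lines = as.character(lines), variants = variants,
      calls = calls)
}

#' Construct a CovariateTable
#'
#' @param lines character vector of line ids.
#' @param data data.frame with columns symbiont, sv1..sv5 (coerced to
#'   factors).
#' @return a [CovariateTable].
#' @export
CovariateTable <- function(lines, data) {
  data <- as.data.frame(lapply(data, function(col) {
    if (is.factor(col)) col else factor(col)
  }), stringsAsFactors = FALSE)
  rownames(data) <- NULL
  new("CovariateTable", lines = as.character(lines), data = data)
}
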