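## Harmonized TSV/CSV input/output following the community data-sharing
## guidelines: line id column first, sex second (M/F/NA), phenotypes after;
## a single "NA" missing-value token on output.

.detectSep <- function(headerLine) {
  if (grepl("\t", headerLine)) "\t" else ","
}

.writeAtomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read a harmonized phenotype table (TSV/CSV)
#'
#' Expects a header row, line identifiers in the first column and sex codes
#' (M/F/NA) in the second, phenotypes after; the delimiter (tab or comma) is
#' auto-detected from the header. Line ids are normalized to canonical
#' \code{DGRP_XXX} form and both \code{"NA"} and empty cells are unified to
#' missing (a warning lists columns mixing the two conventions). All
#' phenotype columns must parse as numbers; categorical phenotypes are
#' expected as integer level codes.
#'
#' @param path file to read.
#' @param studyId study identifier to attach (default: file name stem).
#' @return a [PhenotypeTable].
#' @export
readPhenotypeTable <- function(path, studyId = NULL) {
  if (!file.exists(path))
    stop("phenotype file not found: ", path, call. = FALSE)
  if (is.null(studyId))
    studyId <- sub("\\.(tsv|csv|txt)$", "", basename(path))
  header <- readLines(path, n = 1L)
  sep <- .detectSep(header)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("phenotype file must have a line id column followed by a sex ",
         "column (M/F/NA) before any phenotypes; see the data-sharing ",
         "guidelines", call. = FALSE)
  sexRaw <- trimws(raw[[2L]])
  if (!all(toupper(sexRaw) %in% c("M", "F", "NA")))
    stop("second column must contain sex codes M/F/NA (guideline: report ",
         "line ids in the first column and sex in the second); found: ",
         paste(sQuote(utils::head(unique(
           sexRaw[!(toupper(sexRaw) %in% c("M", "F", "NA"))]), 3)),
           collapse = ", "), call. = FALSE)
  lines <- normalizeLineId(raw[[1L]])
  sex <- normalizeSexCode(sexRaw)
  phenoCols <- names(raw)[-(1:2)]
  mixed <- character()
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(phenoCols),
                 dimnames = list(NULL, phenoCols))
  for (j in seq_along(phenoCols)) {
    col <- trimws(raw[[j + 2L]])
    isNA <- col == "NA" | col == "" | is.na(col)
    if (any(col == "NA") && any(col == ""))
      mixed <- c(mixed, phenoCols[j])
    num <- suppressWarnings(as.numeric(col[!isNA]))
    if (anyNA(num)) {
      bad <- which(!isNA)[which(is.na(num))[1L]]
      stop(sprintf(
        "non-numeric value %s in quantitative column '%s' (row %d)",
        sQuote(col[bad]), phenoCols[j], bad), call. = FALSE)
    }
    vals[!isNA, j] <- num
  }
  if (length(mixed))
    warning("mixed NA conventions ('NA' and empty cells) in column(s): ",
            paste(mixed, collapse = ", "),
            "; unified to a single missing value", call. = FALSE)
  PhenotypeTable(studyId, unname(lines), sex, vals)
}

#' Write a harmonized phenotype table as TSV
#'
#' Emits the guideline layout: line id first, sex second, phenotype columns
#' in stored order, missing cells as the single literal token \code{NA}.
#' Written atomically (temp file then rename). Round-trips through
#' [readPhenotypeTable()].
#'
#' @param table a [PhenotypeTable].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePhenotypeTable <- function(table, path) {
  stopifnot(is(table, "PhenotypeTable"))
  df <- data.frame(line = lineIds(table), sex = sexCodes(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- phenoValues(table)
  # 17 significant digits so numeric values survive the round trip exactly
  for (j in seq_len(ncol(vals))) {
    col <- sprintf("%.17g", vals[, j])
    col[is.na(vals[, j])] <- NA_character_
    df[[colnames(vals)[j]]] <- col
  }
  .writeAtomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE)
  }, path)
}

#' Write / read a genotype panel as TSV pair
#'
#' Two files: a calls matrix (first column \code{line}, then one {0,1,NA}
#' column per variant) and a variant metadata table (variant_id, chrom, pos,
#' ref, alt, class).
#'
#' @param panel a [GenotypePanel].
#' @param callsPath,variantsPath file paths.
#' @return paths (write) or a [GenotypePanel] (read).
#' @export
writeGenotypePanel <- function(panel, callsPath, variantsPath) {
  stopifnot(is(panel, "GenotypePanel"))
  df <- data.frame(line = lineIds(panel), check.names = FALSE,
                   stringsAsFactors = FALSE)
  calls <- genotypeCalls(panel)
  for (j in seq_len(ncol(calls))) df[[colnames(calls)[j]]] <- calls[, j]
  .writeAtomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE)
  }, callsPath)
  .writeAtomic(function(tmp) {
    utils::write.table(variantInfo(panel), tmp, sep = "\t", quote = FALSE,
                       na = "NA", row.names = FALSE)
  }, variantsPath)
  invisible(c(callsPath, variantsPath))
}

#' @rdname writeGenotypePanel
#' @export
readGenotypePanel <- function(callsPath, variantsPath) {
  calls <- utils::read.table(callsPath, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
  variants <- utils::read.table(variantsPath, sep = "\t", header = TRUE,
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
  lines <- as.character(calls[[1L]])
  mat <- as.matrix(calls[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  GenotypePanel(lines, variants, mat)
}

#' Write / read a covariate table as TSV
#'
#' @param cov a [CovariateTable].
#' @param path file path.
#' @return the path (write) or a [CovariateTable] (read).
#' @export
writeCovariateTable <- function(cov, path) {
  stopifnot(is(cov, "CovariateTable"))
  df <- cbind(data.frame(line = lineIds(cov), stringsAsFactors = FALSE),
              as.data.frame(lapply(covariateData(cov), as.character),
                            stringsAsFactors = FALSE))
  .writeAtomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE)
  }, path)
}

#' @rdname writeCovariateTable
#' @export
readCovariateTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  CovariateTable(df[[1L]], df[, -1L, drop = FALSE])
}

#' Write a registry to a directory of guideline-conformant TSVs
#'
#' Layout: \code{studies.tsv}, \code{descriptors.tsv}, one
#' \code{pheno_<study>.tsv} per study, plus (optionally, via
#' [emitFixtures()]) genotype and covariate TSVs and a manifest.
#'
#' @param reg a [PhenotypeRegistry].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeRegistry <- function(reg, dir) {
  stopifnot(is(reg, "PhenotypeRegistry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeAtomic(function(tmp) {
    utils::write.table(studies(reg), tmp, sep = "\t", quote = FALSE,
                       na = "NA", row.names = FALSE)
  }, file.path(dir, "studies.tsv"))
  .writeAtomic(function(tmp) {
    utils::write.table(descriptors(reg), tmp, sep = "\t", quote = FALSE,
                       na = "NA", row.names = FALSE)
  }, file.path(dir, "descriptors.tsv"))
  for (tab in phenoTables(reg))
    writePhenotypeTable(tab, file.path(dir,
      paste0("pheno_", studyId(tab), ".tsv")))
  invisible(dir)
}

#' @rdname writeRegistry
#' @export
readRegistry <- function(dir) {
  studies <- utils::read.table(file.path(dir, "studies.tsv"), sep = "\t",
                               header = TRUE, colClasses = "character",
                               check.names = FALSE, stringsAsFactors = FALSE)
  descriptors <- utils::read.table(file.path(dir, "descriptors.tsv"),
                                   sep = "\t", header = TRUE,
                                   check.names = FALSE,
                                   colClasses = "character",
                                   stringsAsFactors = FALSE)
  descriptors$is_summary <- as.logical(descriptors$is_summary)
  tables <- lapply(studies$study_id, function(sid) {
    readPhenotypeTable(file.path(dir, paste0("pheno_", sid, ".tsv")),
                       studyId = sid)
  })
  names(tables) <- studies$study_id
  PhenotypeRegistry(studies, descriptors, tables)
}
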