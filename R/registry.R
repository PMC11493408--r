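#' Validate a registry against the data-sharing guidelines
#'
#' Checks each study table and descriptor for guideline violations:
#' non-canonical line identifiers, invalid sex codes, duplicated
#' (line, sex) rows, phenotype descriptors without a unit, and descriptors
#' referencing a missing study or phenotype column. The report is empty if
#' and only if the registry is clean; it never throws.
#'
#' @param reg a [PhenotypeRegistry].
#' @return data.frame with columns \code{rule}, \code{study_id},
#'   \code{location}, \code{message}; zero rows when clean.
#' @export
validateRegistry <- function(reg) {
  stopifnot(is(reg, "PhenotypeRegistry"))
  v <- list()
  add <- function(rule, study, location, message) {
    v[[length(v) + 1L]] <<- data.frame(
      rule = rule, study_id = study, location = location,
      message = message, stringsAsFactors = FALSE)
  }
  for (tab in phenoTables(reg)) {
    sid <- studyId(tab)
    bad <- !isCanonicalLineId(lineIds(tab))
    for (i in which(bad))
      add("malformed_line_id", sid, sprintf("row %d", i),
          sprintf("line id '%s' is not canonical DGRP_XXX",
                  lineIds(tab)[i]))
    badSex <- !(sexCodes(tab) %in% c("M", "F", "NA"))
    for (i in which(badSex))
      add("invalid_sex_code", sid, sprintf("row %d", i),
          sprintf("sex code '%s' is not M/F/NA", sexCodes(tab)[i]))
    key <- paste(lineIds(tab), sexCodes(tab), sep = "|")
    dup <- duplicated(key)
    for (i in which(dup))
      add("duplicate_line_sex", sid, sprintf("row %d", i),
          sprintf("(line, sex) pair (%s, %s) duplicated",
                  lineIds(tab)[i], sexCodes(tab)[i]))
  }
  d <- descriptors(reg)
  for (i in seq_len(nrow(d))) {
    unit <- d$unit[i]
    if (is.na(unit) || !nzchar(trimws(unit)))
      add("missing_unit", d$study_id[i],
          sprintf("descriptor %s:%s:%s", d$study_id[i], d$phenotype_id[i],
                  d$sex[i]),
          "phenotype has no unit metadata")
    tab <- phenoTables(reg)[[d$study_id[i]]]
    if (is.null(tab))
      add("missing_study_table", d$study_id[i],
          sprintf("descriptor %s:%s", d$study_id[i], d$phenotype_id[i]),
          "descriptor references a study with no table")
    else if (!(d$phenotype_id[i] %in% colnames(phenoValues(tab))))
      add("missing_phenotype_column", d$study_id[i],
          sprintf("descriptor %s:%s", d$study_id[i], d$phenotype_id[i]),
          "descriptor references a column absent from the study table")
  }
  key <- with(d, paste(study_id, phenotype_id, sex, sep = "|"))
  for (i in which(duplicated(key)))
    add("duplicate_descriptor", d$study_id[i],
        sprintf("descriptor %s:%s:%s", d$study_id[i], d$phenotype_id[i],
                d$sex[i]),
        "(study, phenotype, sex) descriptor duplicated")
  if (length(v)) do.call(rbind, v)
  else data.frame(rule = character(), study_id = character(),
                  location = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Summarize a registry: phenotype counts per sex, study and category
#'
#' Counts are taken over descriptors, so a phenotype measured in both sexes
#' counts once per sex; totals are additive over studies and invariant under
#' reordering.
#'
#' @param reg a [PhenotypeRegistry].
#' @return list with \code{perSex}, \code{perStudy}, \code{perCategory}
#'   data.frames and \code{total}.
#' @export
summarizeRegistry <- function(reg) {
  stopifnot(is(reg, "PhenotypeRegistry"))
  d <- descriptors(reg)
  s <- studies(reg)
  perSex <- as.data.frame(table(
    sex = factor(d$sex, levels = c("F", "M", "NA"))),
    responseName = "n_phenotypes", stringsAsFactors = FALSE)
  perStudy <- as.data.frame(table(
    study_id = factor(d$study_id, levels = sort(s$study_id))),
    responseName = "n_phenotypes", stringsAsFactors = FALSE)
  cats <- strsplit(s$categories, ",[ ]*")
  catRows <- data.frame(
    study_id = rep(s$study_id, lengths(cats)),
    category = tolower(trimws(unlist(cats))),
    stringsAsFactors = FALSE)
  nPerStudy <- perStudy$n_phenotypes[match(catRows$study_id,
                                           perStudy$study_id)]
  perCategory <- stats::aggregate(
    list(n_phenotypes = nPerStudy),
    by = list(category = catRows$category), FUN = sum)
  perCategory <- perCategory[order(perCategory$category), , drop = FALSE]
  rownames(perCategory) <- NULL
  list(perSex = perSex, perStudy = perStudy, perCategory = perCategory,
       total = nrow(d))
}

#' Extract one phenotype's per-line values
#'
#' Pulls the value vector for a (study, phenotype, sex) descriptor, named by
#' canonical line id, from the study's table (rows of the requested sex).
#'
#' @param reg a [PhenotypeRegistry].
#' @param study,pheno,sex descriptor coordinates.
#' @return named numeric vector (may contain NA).
#' @export
phenotypeValues <- function(reg, study, pheno, sex) {
  tab <- phenoTables(reg)[[study]]
  if (is.null(tab))
    stop("no such study in registry: ", study, call. = FALSE)
  if (!(pheno %in% colnames(phenoValues(tab))))
    stop("no such phenotype in study ", study, ": ", pheno, call. = FALSE)
  rows <- sexCodes(tab) == sex
  if (!any(rows))
    stop(sprintf("no rows of sex %s in study %s", sex, study),
         call. = FALSE)
  out <- phenoValues(tab)[rows, pheno]
  names(out) <- lineIds(tab)[rows]
  out
}

## Quantitative descriptors in analysis scope, with deterministic ordering.
.scopedDescriptors <- function(reg, scope = c("curated_only", "all"),
                               dtype = "quantitative") {
  scope <- match.arg(scope)
  d <- descriptors(reg)
  if (scope == "curated_only") {
    keep <- studies(reg)$study_id[studies(reg)$status == "curated"]
    d <- d[d$study_id %in% keep, , drop = FALSE]
  }
  if (!is.null(dtype)) d <- d[d$dtype %in% dtype, , drop = FALSE]
  d <- d[order(d$study_id, d$phenotype_id, d$sex), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Descriptor key string "study:pheno:sex"
#'
#' @param d descriptor data.frame rows.
#' @return character vector of keys.
#' @export
descriptorKey <- function(d) {
  paste(d$study_id, d$phenotype_id, d$sex, sep = ":")
}
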