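# Fixture builders shared across test files; everything is generated in
# code, nothing is read from disk.

# Single-study registry from a lines x phenotypes value matrix (one sex).
makeRegistry <- function(values, sex = "F", studyId = "S01",
                         dtype = NULL, unit = "a.u.",
                         status = "curated", categories = "Aging",
                         lines = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("ph%02d", seq_len(ncol(values)))
  if (is.null(lines)) lines <- sprintf("DGRP_%03d", seq_len(nrow(values)))
  if (is.null(dtype)) dtype <- rep("quantitative", ncol(values))
  tab <- PhenotypeTable(studyId, lines, rep(sex, nrow(values)), values)
  descr <- data.frame(
    study_id = studyId, phenotype_id = colnames(values),
    name = colnames(values), sex = sex, unit = unit, dtype = dtype,
    is_summary = TRUE, stringsAsFactors = FALSE)
  studies <- data.frame(study_id = studyId, title = "test study",
                        categories = categories, status = status,
                        stringsAsFactors = FALSE)
  PhenotypeRegistry(studies, descr, stats::setNames(list(tab), studyId))
}

# Merge registries that have disjoint study ids.
mergeRegistries <- function(...) {
  regs <- list(...)
  PhenotypeRegistry(
    do.call(rbind, lapply(regs, studies)),
    do.call(rbind, lapply(regs, descriptors)),
    do.call(c, lapply(regs, phenoTables)))
}

# Minimal genotype panel from a lines x variants call matrix.
makePanel <- function(calls, lines = NULL) {
  calls <- as.matrix(calls)
  if (is.null(lines)) lines <- sprintf("DGRP_%03d", seq_len(nrow(calls)))
  variants <- data.frame(
    variant_id = paste0("2L:", seq_len(ncol(calls))),
    chrom = "2L", pos = seq_len(ncol(calls)), ref = "A", alt = "T",
    class = "SNP", stringsAsFactors = FALSE)
  GenotypePanel(lines, variants, calls)
}

# Independently coded literal transcription of the extremeness procedure:
# min-tie ranks via counting, 15% cutoff rounded up, -1/0/+1 bands applied
# as stated, FoE as the per-line share of non-zero assignments.
oracleExtremeness <- function(values) {
  # values: lines x phenotypes matrix (rownames = line ids)
  foeNum <- foeDen <- stats::setNames(rep(0, nrow(values)),
                                      rownames(values))
  assignments <- matrix(NA_integer_, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    ok <- which(!is.na(v))
    if (length(ok) < 2L) next
    r <- vapply(ok, function(i) sum(v[ok] < v[i]) + 1L, integer(1))
    rmax <- max(r)
    cut <- 0.15 * rmax
    if (cut != floor(cut)) cut <- floor(cut) + 1
    for (k in seq_along(ok)) {
      a <- 0L
      if (r[k] <= cut) a <- -1L
      else if (r[k] >= rmax - cut) a <- 1L
      assignments[ok[k], j] <- a
      foeDen[ok[k]] <- foeDen[ok[k]] + 1
      if (a != 0L) foeNum[ok[k]] <- foeNum[ok[k]] + 1
    }
  }
  list(foe = ifelse(foeDen > 0, foeNum / foeDen, NA_real_),
       n = foeDen, assignments = assignments)
}
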