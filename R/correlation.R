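## Sex-stratified phenotype-phenotype correlation across and within
## studies, with BH FDR control and focal-phenotype association.

#' Spearman correlation with overlap handling
#'
#' Pairs with either value missing are dropped; the coefficient is the
#' Pearson correlation of mid-ranks (average ranks for ties) and the
#' two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df. Zero variance in
#' either ranked vector yields an undefined-correlation condition (the
#' caller is expected to skip, not propagate NaN).
#'
#' @param x,y numeric vectors indexed identically (e.g. by line).
#' @param minOverlap minimum complete pairs required (>= 3).
#' @param method "spearman" (default) or "pearson" (no ranking step).
#' @return list(rho, p, n_shared).
#' @export
spearmanCor <- function(x, y, minOverlap = 3, method = c("spearman",
                                                         "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < max(3L, minOverlap))
    stop(sprintf("insufficient overlap: %d complete pairs (need >= %d)",
                 n, max(3L, minOverlap)), call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  if (method == "spearman") {
    xs <- rank(xs, ties.method = "average")
    ys <- rank(ys, ties.method = "average")
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("undefined correlation: zero variance after ranking",
         call. = FALSE)
  rho <- stats::cor(xs, ys)
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), n_shared = n)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' \eqn{q_i = \min_{j \ge \mathrm{rank}(i)} m\, p_{(j)} / j}, clipped at 1;
#' monotone in p and never smaller than p.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  m <- length(pvals)
  if (m == 0L) return(numeric())
  o <- order(pvals)
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' All-pairs sex-stratified correlation over a registry
#'
#' Computes Spearman correlation for every unordered pair of quantitative
#' phenotype descriptors of the same sex (categorical phenotypes are
#' excluded), restricted to curated studies by default. Pairs with fewer
#' than \code{minOverlap} shared lines or with zero rank variance are
#' skipped and counted. q-values are BH-adjusted over the emitted family.
#'
#' @param reg a [PhenotypeRegistry].
#' @param scope "curated_only" (default) or "all".
#' @param minOverlap minimum shared lines per pair (default 10; Spearman
#'   p-values are unstable below ~10 pairs).
#' @return data.frame of correlation records (study/pheno/sex for both
#'   members, rho, n_shared, p, q, same_study) ordered deterministically;
#'   attribute \code{"skipped"} holds per-reason skip counts.
#' @export
correlateRegistry <- function(reg, scope = c("curated_only", "all"),
                              minOverlap = 10) {
  scope <- match.arg(scope)
  d <- .scopedDescriptors(reg, scope)
  vecs <- lapply(seq_len(nrow(d)), function(i)
    phenotypeValues(reg, d$study_id[i], d$phenotype_id[i], d$sex[i]))
  keys <- descriptorKey(d)
  skipped <- c(low_overlap = 0L, zero_variance = 0L)
  recs <- list()
  nD <- nrow(d)
  for (i in seq_len(max(0L, nD - 1L))) {
    for (j in seq((i + 1L), nD)) {
      if (d$sex[i] != d$sex[j]) next
      xi <- vecs[[i]]; yj <- vecs[[j]]
      common <- intersect(names(xi), names(yj))
      res <- tryCatch(
        spearmanCor(xi[common], yj[common], minOverlap = minOverlap),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        reason <- if (grepl("overlap", res)) "low_overlap"
                  else "zero_variance"
        skipped[reason] <- skipped[reason] + 1L
        next
      }
      recs[[length(recs) + 1L]] <- data.frame(
        study_a = d$study_id[i], pheno_a = d$phenotype_id[i],
        study_b = d$study_id[j], pheno_b = d$phenotype_id[j],
        sex = d$sex[i], rho = res$rho, n_shared = res$n_shared,
        p = res$p, same_study = d$study_id[i] == d$study_id[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs)
         else data.frame(study_a = character(), pheno_a = character(),
                         study_b = character(), pheno_b = character(),
                         sex = character(), rho = numeric(),
                         n_shared = integer(), p = numeric(),
                         same_study = logical(), stringsAsFactors = FALSE)
  out$q <- if (nrow(out)) bhAdjust(out$p) else numeric()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Within- vs cross-study summary of absolute correlations
#'
#' Summarizes |rho| separately for same-study and cross-study pairs (the
#' within-study block structure of multi-study panels makes same-study
#' pairs correlate more strongly on average).
#'
#' @param records output of [correlateRegistry()].
#' @return data.frame with rows "within"/"cross": count, median and mean of
#'   |rho| (NA summaries when a group is empty).
#' @export
withinCrossSummary <- function(records) {
  if (!nrow(records))
    stop("no correlation records to summarize", call. = FALSE)
  grp <- ifelse(records$same_study, "within", "cross")
  out <- do.call(rbind, lapply(c("within", "cross"), function(g) {
    r <- abs(records$rho[grp == g])
    data.frame(group = g, n = length(r),
               median_abs_rho = if (length(r)) stats::median(r) else NA_real_,
               mean_abs_rho = if (length(r)) mean(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Focal-phenotype association with FDR control and hit grouping
#'
#' Correlates one focal phenotype against every other quantitative
#' descriptor (same sex by default; \code{matchSex = FALSE} allows
#' cross-sex pairs, matching on shared lines), BH-adjusts that candidate
#' family, keeps hits with q <= alpha, and partitions the hits into three
#' groups by average-linkage hierarchical clustering on distance 1 - rho of
#' their mutual correlation matrix. Groups are labelled by their mean
#' correlation with the focal phenotype: "focal_like" (mean rho >= 0.8),
#' "correlated" (>= 0) or "anti_correlated" (< 0).
#'
#' @param reg a [PhenotypeRegistry].
#' @param focal "study:pheno:sex" key or list(study, pheno, sex).
#' @param method "spearman" or "pearson".
#' @param alpha FDR level (default 0.05).
#' @param matchSex restrict candidates to the focal sex (default TRUE).
#' @param minOverlap minimum shared lines (default 10).
#' @param scope registry scope as in [correlateRegistry()].
#' @return list with \code{focal}, \code{method}, \code{alpha},
#'   \code{candidates} (all tested, with rho/p/q), \code{hits} (q <= alpha,
#'   with \code{group} labels) and \code{skipped} counts.
#' @export
focalAssociations <- function(reg, focal, method = c("spearman", "pearson"),
                              alpha = 0.05, matchSex = TRUE,
                              minOverlap = 10,
                              scope = c("curated_only", "all")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (is.character(focal) && length(focal) == 1L) {
    parts <- strsplit(focal, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("focal key must be 'study:pheno:sex'", call. = FALSE)
    focal <- list(study = parts[1], pheno = parts[2], sex = parts[3])
  }
  d <- .scopedDescriptors(reg, scope)
  keys <- descriptorKey(d)
  fkey <- paste(focal$study, focal$pheno, focal$sex, sep = ":")
  fi <- match(fkey, keys)
  if (is.na(fi))
    stop("focal phenotype not found in registry scope: ", fkey,
         call. = FALSE)
  fvals <- phenotypeValues(reg, focal$study, focal$pheno, focal$sex)
  cand <- d[-fi, , drop = FALSE]
  if (matchSex) cand <- cand[cand$sex == focal$sex, , drop = FALSE]
  skipped <- c(low_overlap = 0L, zero_variance = 0L)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    cvals <- phenotypeValues(reg, cand$study_id[i], cand$phenotype_id[i],
                             cand$sex[i])
    common <- intersect(names(fvals), names(cvals))
    res <- tryCatch(
      spearmanCor(fvals[common], cvals[common], minOverlap = minOverlap,
                  method = method),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      reason <- if (grepl("overlap", res)) "low_overlap" else "zero_variance"
      skipped[reason] <- skipped[reason] + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      study = cand$study_id[i], pheno = cand$phenotype_id[i],
      sex = cand$sex[i], rho = res$rho, n_shared = res$n_shared,
      p = res$p, stringsAsFactors = FALSE)
  }
  candidates <- if (length(rows)) do.call(rbind, rows)
                else data.frame(study = character(), pheno = character(),
                                sex = character(), rho = numeric(),
                                n_shared = integer(), p = numeric(),
                                stringsAsFactors = FALSE)
  candidates$q <- if (nrow(candidates)) bhAdjust(candidates$p) else numeric()
  hits <- candidates[candidates$q <= alpha, , drop = FALSE]
  hits$group <- .groupHits(reg, focal, fvals, hits, method)
  rownames(candidates) <- rownames(hits) <- NULL
  list(focal = fkey, method = method, alpha = alpha,
       candidates = candidates, hits = hits, skipped = skipped)
}

## Partition hits into up to 3 clusters of their mutual correlation matrix
## (average linkage on 1 - rho) and label each by mean correlation with the
## focal phenotype.
.groupHits <- function(reg, focal, fvals, hits, method) {
  nH <- nrow(hits)
  if (nH == 0L) return(character())
  vecs <- lapply(seq_len(nH), function(i)
    phenotypeValues(reg, hits$study[i], hits$pheno[i], hits$sex[i]))
  labelOf <- function(meanRho) {
    if (meanRho >= 0.8) "focal_like"
    else if (meanRho >= 0) "correlated"
    else "anti_correlated"
  }
  if (nH <= 2L)
    return(vapply(seq_len(nH), function(i) labelOf(hits$rho[i]),
                  character(1)))
  C <- diag(nH)
  for (i in seq_len(nH - 1L)) for (j in seq((i + 1L), nH)) {
    common <- intersect(names(vecs[[i]]), names(vecs[[j]]))
    r <- tryCatch(
      spearmanCor(vecs[[i]][common], vecs[[j]][common], minOverlap = 3,
                  method = method)$rho,
      error = function(e) 0)
    C[i, j] <- C[j, i] <- r
  }
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  cl <- stats::cutree(hc, k = min(3L, nH))
  grpLabel <- vapply(sort(unique(cl)), function(g)
    labelOf(mean(hits$rho[cl == g])), character(1))
  grpLabel[cl]
}
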