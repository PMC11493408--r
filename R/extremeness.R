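## Fraction-of-extremeness scoring: per-phenotype rank-based extremeness
## assignment (-1/0/+1), per-line FoE, adjusted per-phenotype values and
## cross-sex extreme/moderate line discovery.

#' Minimum-tie ranks
#'
#' Ascending ranks with tied values sharing the minimum rank of their tie
#' group; missing values stay unranked (NA).
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return integer ranks, same length and NA pattern as \code{values}.
#' @export
rankMinTies <- function(values) {
  if (sum(!is.na(values)) < 2L)
    stop("need at least 2 non-missing values to rank", call. = FALSE)
  rank(values, ties.method = "min", na.last = "keep")
}

#' Inclusive 15% rank cutoff
#'
#' The raw cutoff is 15% of the maximum assigned rank; it is rounded up
#' (ceiling) to be more inclusive at either end, so raw values 1.2 and 1.8
#' both become 2, and exact integers are unchanged.
#'
#' @param rMax maximum assigned rank (>= 1).
#' @return integer cutoff c = ceiling(0.15 * rMax).
#' @export
extremenessCutoff <- function(rMax) {
  stopifnot(rMax >= 1)
  as.integer(ceiling(0.15 * rMax))
}

#' Assign extremeness codes from ranks
#'
#' Ranks at or below the cutoff are assigned -1; ranks at or above the
#' maximum rank minus the cutoff are assigned +1; the rest 0. The rule is
#' applied verbatim, which makes the upper band one rank wider than the
#' lower one for dense distinct ranks (r >= rMax - c admits c + 1 ranks);
#' where the two bands overlap the lower band wins and the result carries a
#' \code{degenerate} attribute.
#'
#' @param ranks integer ranks (NA allowed, stays NA).
#' @param rMax maximum assigned rank.
#' @param cutoff the cutoff from [extremenessCutoff()].
#' @return integer vector over {-1, 0, 1, NA}; attribute
#'   \code{"degenerate"} TRUE when the bands overlap (c >= rMax - c).
#' @export
assignExtremeness <- function(ranks, rMax, cutoff) {
  out <- ifelse(is.na(ranks), NA_integer_,
         ifelse(ranks <= cutoff, -1L,
         ifelse(ranks >= rMax - cutoff, 1L, 0L)))
  attr(out, "degenerate") <- cutoff >= rMax - cutoff
  out
}

#' Fraction of extremeness for one line
#'
#' The count of -1/+1 assignments divided by the number of phenotypes with
#' a value for the line.
#'
#' @param assignments integer vector over {-1, 0, 1} (NAs excluded first).
#' @return fraction in [0, 1].
#' @export
fractionOfExtremeness <- function(assignments) {
  a <- assignments[!is.na(assignments)]
  if (!length(a))
    stop("no phenotypes with a value: fraction undefined", call. = FALSE)
  mean(a != 0L)
}

#' Adjusted per-phenotype extremeness value
#'
#' Rank divided by maximum rank, reflected about 0.5: values strictly above
#' 0.5 become 1 minus the value (0.91 -> 0.09), so both tails map below
#' 0.15 when extreme. A value of exactly 0.5 is not adjusted.
#'
#' @param r rank(s), 1 <= r <= rMax.
#' @param rMax maximum assigned rank.
#' @return value(s) in [0, 0.5].
#' @export
adjustedExtremeness <- function(r, rMax) {
  v <- r / rMax
  ifelse(v > 0.5, 1 - v, v)
}

#' Full extremeness pipeline over a registry
#'
#' For every quantitative phenotype descriptor in scope (curated studies,
#' optionally restricted to studies tagged with given categories,
#' case-insensitive), ranks the per-line values with minimum-tie ranks,
#' derives the inclusive 15% cutoff from the maximum assigned rank, assigns
#' -1/0/+1, and aggregates per (line, sex): phenotype count, fraction of
#' extremeness and adjusted values. Lines with fewer than \code{minPhenos}
#' phenotype values (per sex) are excluded from the line-level records but
#' never affect other lines. The violation report counts phenotype-level
#' cases where the rounded rank rule labels a value extreme (+-1) although
#' its adjusted value exceeds 0.15.
#'
#' @param reg a [PhenotypeRegistry].
#' @param categories optional character vector of study category tags;
#'   NULL = all studies in scope.
#' @param minPhenos minimum phenotype values per (line, sex) record
#'   (default 50).
#' @param scope "curated_only" (default) or "all".
#' @return list with \code{records} (data.frame line/sex/n_phenos/foe),
#'   \code{assignments} (long data.frame line/sex/study/pheno/rank/r_max/
#'   cutoff/assignment/adjusted/violation), \code{violations} (count and
#'   fraction) and \code{degenerate} (keys of phenotypes whose bands
#'   overlap).
#' @export
extremenessPipeline <- function(reg, categories = NULL, minPhenos = 50,
                                scope = c("curated_only", "all")) {
  scope <- match.arg(scope)
  d <- .scopedDescriptors(reg, scope)
  if (!is.null(categories)) {
    s <- studies(reg)
    want <- tolower(trimws(categories))
    tagged <- s$study_id[vapply(strsplit(s$categories, ",[ ]*"),
      function(tags) any(tolower(trimws(tags)) %in% want), logical(1))]
    d <- d[d$study_id %in% tagged, , drop = FALSE]
  }
  if (!nrow(d))
    stop("no phenotypes selected after category/scope filtering",
         call. = FALSE)
  longs <- vector("list", nrow(d))
  degenerate <- character()
  for (i in seq_len(nrow(d))) {
    vals <- phenotypeValues(reg, d$study_id[i], d$phenotype_id[i],
                            d$sex[i])
    if (sum(!is.na(vals)) < 2L) next
    r <- rankMinTies(vals)
    rMax <- max(r, na.rm = TRUE)
    cutoff <- extremenessCutoff(rMax)
    a <- assignExtremeness(r, rMax, cutoff)
    if (isTRUE(attr(a, "degenerate")))
      degenerate <- c(degenerate, descriptorKey(d[i, , drop = FALSE]))
    ok <- !is.na(vals)
    adj <- adjustedExtremeness(r[ok], rMax)
    longs[[i]] <- data.frame(
      line = names(vals)[ok], sex = d$sex[i], study = d$study_id[i],
      pheno = d$phenotype_id[i], rank = r[ok], r_max = rMax,
      cutoff = cutoff, assignment = as.integer(a[ok]), adjusted = adj,
      violation = a[ok] != 0L & adj > 0.15,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, longs[!vapply(longs, is.null, logical(1))])
  rownames(long) <- NULL
  key <- paste(long$line, long$sex, sep = "|")
  recs <- do.call(rbind, lapply(split(seq_len(nrow(long)), key),
    function(idx) {
      data.frame(line = long$line[idx[1L]], sex = long$sex[idx[1L]],
                 n_phenos = length(idx),
                 foe = mean(long$assignment[idx] != 0L),
                 stringsAsFactors = FALSE)
    }))
  recs <- recs[recs$n_phenos >= minPhenos, , drop = FALSE]
  recs <- recs[order(recs$line, recs$sex), , drop = FALSE]
  rownames(recs) <- NULL
  list(records = recs, assignments = long,
       violations = list(n = sum(long$violation),
                         fraction = mean(long$violation)),
       degenerate = degenerate)
}

#' Cross-sex extreme and moderate line pairings
#'
#' Among lines with records for both sexes whose female and male fractions
#' of extremeness differ by at most \code{tol}, returns the line with the
#' highest mean FoE across sexes (the extreme pick) and the lowest (the
#' moderate pick), with the full candidate ranking attached.
#'
#' @param records the \code{records} data.frame from
#'   [extremenessPipeline()].
#' @param tol maximum |FoE_F - FoE_M| for candidacy (default 0.05).
#' @return list with \code{extreme}, \code{moderate} (single-row
#'   data.frames or NULL) and \code{candidates} (line/foe_F/foe_M/mean_foe,
#'   sorted by mean_foe descending); a \code{notice} when no line has both
#'   sexes.
#' @export
crossSexPairings <- function(records, tol = 0.05) {
  fe <- records[records$sex == "F", c("line", "foe")]
  ma <- records[records$sex == "M", c("line", "foe")]
  both <- merge(fe, ma, by = "line", suffixes = c("_F", "_M"))
  if (!nrow(both))
    return(list(extreme = NULL, moderate = NULL,
                candidates = data.frame(),
                notice = "no line has records for both sexes"))
  cand <- both[abs(both$foe_F - both$foe_M) <= tol, , drop = FALSE]
  if (!nrow(cand))
    return(list(extreme = NULL, moderate = NULL,
                candidates = data.frame(),
                notice = "no line within the cross-sex tolerance"))
  cand$mean_foe <- (cand$foe_F + cand$foe_M) / 2
  cand <- cand[order(-cand$mean_foe, cand$line), , drop = FALSE]
  rownames(cand) <- NULL
  list(extreme = cand[1L, , drop = FALSE],
       moderate = cand[nrow(cand), , drop = FALSE],
       candidates = cand)
}
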