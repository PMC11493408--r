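#' Normalize line identifiers to the canonical DGRP_XXX form
#'
#' Community guidelines ask for one identifier format across all studies:
#' \code{DGRP_} followed by a zero-padded three-digit line number. Published
#' submissions use many spellings (\code{DGRP-42}, \code{ral_757},
#' \code{line 21}, bare numbers); this function strips any alphabetic
#' prefix/separator, parses the line number and re-emits the canonical form.
#' Normalization is idempotent and injective on distinct line numbers.
#'
#' @param raw character vector of raw line labels.
#' @return character vector of canonical ids matching \code{DGRP_[0-9]{3}},
#'   with the raw labels preserved as names.
#' @examples
#' normalizeLineId(c("DGRP-42", "ral_757", "DGRP_852"))
#' @export
normalizeLineId <- function(raw) {
  raw <- as.character(raw)
  digits <- regmatches(raw, regexpr("[0-9]+", raw))
  has <- regexpr("[0-9]+", raw) > 0L
  if (any(!has))
    stop("malformed line identifier (no line number found): ",
         paste(sQuote(raw[!has]), collapse = ", "), call. = FALSE)
  num <- suppressWarnings(as.integer(regmatches(
    raw, regexpr("[0-9]+", raw))))
  if (any(num > 999L))
    stop("line number out of range (> 999): ",
         paste(sQuote(raw[num > 999L]), collapse = ", "), call. = FALSE)
  out <- sprintf("DGRP_%03d", num)
  names(out) <- raw
  out
}

#' Check whether identifiers are already canonical
#'
#' @param id character vector.
#' @return logical vector, TRUE where the id matches \code{DGRP_[0-9]{3}}.
#' @export
isCanonicalLineId <- function(id) {
  grepl("^DGRP_[0-9]{3}$", as.character(id))
}

#' Normalize a sex code column
#'
#' Accepts upper- or lowercase m/f/na; anything else is an error. The "NA"
#' code (sex-mixed or population-level measurements) is kept as the literal
#' string \code{"NA"}, distinct from a missing value.
#'
#' @param sex character vector.
#' @return character vector over {"M", "F", "NA"}.
#' @export
normalizeSexCode <- function(sex) {
  up <- toupper(trimws(as.character(sex)))
  up[is.na(up)] <- "NA"
  bad <- !(up %in% c("M", "F", "NA"))
  if (any(bad))
    stop("invalid sex code(s): ", paste(sQuote(unique(sex[bad])),
         collapse = ", "), "; expected M, F or NA", call. = FALSE)
  up
}
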