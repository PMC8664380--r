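#' Target and sentinel action-unit classes
#'
#' The classifier operates separately on the upper and lower face. In each
#' region it distinguishes three target classes; everything else is collapsed
#' onto a non-target sentinel that is never used as a classification target
#' but is kept for behavioural reporting:
#'
#' * upper face: `UpperNone` (no coded upper action), `AU1+2` (brow raiser),
#'   `AU43_5` (eye closure / blink, merged since the two differ only in
#'   movement duration), sentinel `OtherUpper`;
#' * lower face: `AU25+26` (lips part + jaw drop), `AU25+26+16` (plus lower
#'   lip depressor), `AU25+26+18i` (plus true pucker), plus the neutral
#'   `LowerNone` and sentinel `OtherLower`.
#'
#' @param region `"upper"` or `"lower"`.
#' @return `au_target_classes()`: the three classifier target classes of a
#'   region, in the fixed order used for tie-breaking and confusion matrices.
#'   `au_all_classes()`: targets plus the region's neutral/sentinel classes.
#' @export
au_target_classes <- function(region) {
  region <- match_region(region)
  if (region == "upper") c("UpperNone", "AU1+2", "AU43_5")
  else c("AU25+26", "AU25+26+16", "AU25+26+18i")
}

#' @rdname au_target_classes
#' @export
au_all_classes <- function(region) {
  region <- match_region(region)
  if (region == "upper") c(au_target_classes("upper"), "OtherUpper")
  else c("LowerNone", au_target_classes("lower"), "OtherLower")
}

match_region <- function(region) {
  if (length(region) != 1L || !region %in% c("upper", "lower"))
    stop("region must be \"upper\" or \"lower\"", call. = FALSE)
  region
}

#' Parse a "+"-joined action-unit code string
#'
#' Codes are stored in label tables as `"+"`-joined raw MaqFACS codes, e.g.
#' `"AU25+AU26+AU18i"`. A fragment that does not start with `"AU"` is merged
#' into the preceding token, so the single unit `"AU1+2"` (brow raiser, one
#' code in the MaqFACS lexicon) parses as one element.
#'
#' @param codes character scalar (may be `""` or `NA` for a neutral frame).
#' @return character vector of raw codes (possibly empty).
#' @export
parse_au_codes <- function(codes) {
  if (length(codes) != 1L) stop("codes must be a single string", call. = FALSE)
  if (is.na(codes) || !nzchar(trimws(codes))) return(character(0))
  frags <- strsplit(trimws(codes), "+", fixed = TRUE)[[1]]
  out <- character(0)
  for (f in frags) {
    f <- trimws(f)
    if (!nzchar(f)) next
    if (length(out) && !startsWith(f, "AU")) {
      out[length(out)] <- paste0(out[length(out)], "+", f)
    } else {
      out <- c(out, f)
    }
  }
  out
}

#' Harmonize raw action-unit codes into a single per-region class
#'
#' Maps the set of raw codes coded on one frame (for one facial region) onto
#' the region's class. The mapping is total and deterministic:
#'
#' * upper: empty set -> `UpperNone`; any non-empty subset of
#'   \{`AU43`, `AU45`, `AU43_5`\} -> `AU43_5` (eye closure and blink are
#'   merged); exactly \{`AU1+2`\} -> `AU1+2`; anything else (including
#'   combinations of `AU1+2` with eye closure, which are rare and flagged
#'   via a message when `verbose = TRUE`) -> `OtherUpper`.
#' * lower: `AU12` is deleted from the set before matching (too infrequent in
#'   the training corpus to model); empty set -> `LowerNone`; exactly
#'   \{`AU25`, `AU26`\} -> `AU25+26`; with `AU16` -> `AU25+26+16`; with
#'   `AU18i` -> `AU25+26+18i`; any other residual combination -> `OtherLower`.
#'
#' @param raw_codes character vector of raw codes (a set; duplicates ignored).
#' @param region `"upper"` or `"lower"`.
#' @param verbose emit a message for multi-unit upper-face frames.
#' @return a single class name (see [au_all_classes()]).
#' @export
harmonize_labels <- function(raw_codes, region, verbose = FALSE) {
  region <- match_region(region)
  codes <- unique(raw_codes[nzchar(raw_codes)])
  if (region == "upper") {
    if (length(codes) == 0L) return("UpperNone")
    eye <- c("AU43", "AU45", "AU43_5")
    if (all(codes %in% eye)) return("AU43_5")
    if (length(codes) == 1L && codes == "AU1+2") return("AU1+2")
    if (verbose && "AU1+2" %in% codes && any(codes %in% eye))
      message("multi-unit upper-face frame mapped to OtherUpper: ",
              paste(sort(codes), collapse = "+"))
    return("OtherUpper")
  }
  codes <- setdiff(codes, "AU12")
  if (length(codes) == 0L) return("LowerNone")
  s <- sort(codes)
  if (identical(s, sort(c("AU25", "AU26")))) return("AU25+26")
  if (identical(s, sort(c("AU25", "AU26", "AU16")))) return("AU25+26+16")
  if (identical(s, sort(c("AU25", "AU26", "AU18i")))) return("AU25+26+18i")
  "OtherLower"
}

region_neutral_class <- function(region) {
  if (match_region(region) == "upper") "UpperNone" else "LowerNone"
}
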