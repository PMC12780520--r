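# Plausibility screening and the nine-way nutritional-status taxonomy.

#' Nutritional-status category levels
#'
#' The nine mutually exclusive categories: `normal`, the four standalone forms
#' of malnutrition (SFM: `stunting`, `wasting`, `underweight`,
#' `overweight_obese`) and the four coexisting forms (CFM: `CUW`, `CUS`,
#' `CUWS`, `CSO`).
#' @export
CFM_CATEGORIES <- c("normal", "stunting", "wasting", "underweight",
                    "overweight_obese", "CUW", "CUS", "CUWS", "CSO")

#' @rdname CFM_CATEGORIES
#' @export
CFM_TYPES <- c("CUW", "CUS", "CUWS", "CSO")

#' @rdname CFM_CATEGORIES
#' @export
SFM_TYPES <- c("stunting", "wasting", "underweight", "overweight_obese")

.conflict_flags <- c("none", "stunted_wasted_not_underweight",
                     "underweight_with_overfeeding_pattern",
                     "multiple_standalone")

#' Biological-plausibility filter for anthropometric z-scores
#'
#' Flags z-score triples with implausible values for exclusion. A record is
#' retained iff `|haz| <= 6`, `|whz| <= 5` and `-6 <= waz <= +5`; exclusion is
#' strictly beyond each bound (a value exactly at the bound is retained).
#' Missing components impose no constraint.
#'
#' @param haz,waz,whz numeric z-score vectors (recycled to a common length).
#' @return data.frame with `retained` (logical) and `violated` (comma-separated
#'   names of the violated bounds, `""` when retained).
#' @export
plausibility_filter <- function(haz, waz, whz) {
  n <- max(length(haz), length(waz), length(whz))
  haz <- rep_len(haz, n); waz <- rep_len(waz, n); whz <- rep_len(whz, n)
  v_haz <- !is.na(haz) & abs(haz) > 6
  v_whz <- !is.na(whz) & abs(whz) > 5
  v_waz <- !is.na(waz) & (waz < -6 | waz > 5)
  violated <- character(n)
  for (i in which(v_haz | v_whz | v_waz)) {
    violated[i] <- paste(c(
      if (v_haz[i]) sprintf("haz=%g beyond +/-6", haz[i]),
      if (v_waz[i]) sprintf("waz=%g beyond [-6,+5]", waz[i]),
      if (v_whz[i]) sprintf("whz=%g beyond +/-5", whz[i])), collapse = ", ")
  }
  data.frame(retained = !(v_haz | v_whz | v_waz), violated = violated,
             stringsAsFactors = FALSE)
}

#' Classify z-score triples into the nine-way nutritional-status taxonomy
#'
#' Deficit predicates use inclusive -2 SD cut-offs: stunted `haz <= -2`,
#' wasted `whz <= -2`, underweight `waz <= -2`; the excess predicate is
#' `whz >= +2` or `waz >= +2`. Categories are resolved in priority order:
#' CUWS (underweight, stunted and wasted), CUS (underweight and stunted),
#' CUW (underweight and wasted), CSO (stunted with excess, not underweight),
#' then the standalone forms, then normal. Predicate combinations outside the
#' taxonomy (e.g. stunted and wasted but not underweight) are assigned one
#' category by fixed precedence (stunting > wasting > underweight >
#' overweight_obese) and conflict-flagged so they can be tabulated.
#'
#' Records with any missing component are not classified (`category` is `NA`,
#' `incomplete` is `TRUE`), mirroring a complete-anthropometry eligibility
#' rule.
#'
#' @param haz,waz,whz numeric z-score vectors (recycled to a common length).
#' @return data.frame with columns `category` (factor over the nine levels),
#'   `malnourished`, `sfm`, `cfm` (logical), `conflict_flag` (factor) and
#'   `incomplete` (logical).
#' @export
classify_nutrition <- function(haz, waz, whz) {
  n <- max(length(haz), length(waz), length(whz))
  haz <- rep_len(haz, n); waz <- rep_len(waz, n); whz <- rep_len(whz, n)
  incomplete <- is.na(haz) | is.na(waz) | is.na(whz)

  st <- !incomplete & haz <= -2
  wa <- !incomplete & whz <= -2
  uw <- !incomplete & waz <= -2
  ov <- !incomplete & (whz >= 2 | waz >= 2)
  npred <- st + wa + uw + ov

  cat <- rep(NA_character_, n)
  flag <- rep("none", n)

  idx <- !incomplete
  # CFM types, most specific first
  i <- idx & uw & st & wa;            cat[i] <- "CUWS"
  i <- idx & is.na(cat) & uw & st;    cat[i] <- "CUS"
  i <- idx & is.na(cat) & uw & wa;    cat[i] <- "CUW"
  i <- idx & is.na(cat) & st & ov & !uw; cat[i] <- "CSO"
  # exactly one predicate -> standalone
  one <- idx & is.na(cat) & npred == 1
  cat[one & st] <- "stunting"
  cat[one & wa] <- "wasting"
  cat[one & uw] <- "underweight"
  cat[one & ov] <- "overweight_obese"
  # no predicate -> normal
  cat[idx & is.na(cat) & npred == 0] <- "normal"
  # residual multi-predicate combinations: fixed precedence
  res <- idx & is.na(cat)
  cat[res & st] <- "stunting"
  cat[res & !st & wa] <- "wasting"
  cat[res & !st & !wa & uw] <- "underweight"
  cat[res & !st & !wa & !uw] <- "overweight_obese"

  # conflict flags for combinations outside the taxonomy
  flag[idx & uw & ov] <- "underweight_with_overfeeding_pattern"
  flag[idx & st & wa & !uw] <- "stunted_wasted_not_underweight"
  extra <- idx & flag == "none" & cat %in% SFM_TYPES & npred > 1
  flag[extra] <- "multiple_standalone"

  category <- factor(cat, levels = CFM_CATEGORIES)
  cfm <- !is.na(category) & category %in% CFM_TYPES
  maln <- !is.na(category) & category != "normal"
  data.frame(
    category = category,
    malnourished = maln,
    sfm = maln & !cfm,
    cfm = cfm,
    conflict_flag = factor(flag, levels = .conflict_flags),
    incomplete = incomplete
  )
}

#' Tabulate category counts and group totals
#'
#' @param categories factor or character vector of categories (levels as in
#'   [CFM_CATEGORIES]); `NA` entries (unclassified records) are ignored.
#' @return named numeric vector: one count per category, plus `sfm_total`
#'   (standalone forms), `cfm_total` (coexisting forms), `malnourished_total`
#'   and `n` (classified records). `malnourished_total = sfm_total + cfm_total`
#'   and all nine categories sum to `n`.
#' @export
derive_group_counts <- function(categories) {
  categories <- factor(as.character(categories), levels = CFM_CATEGORIES)
  cnt <- table(categories)
  out <- as.numeric(cnt)
  names(out) <- names(cnt)
  sfm <- sum(out[SFM_TYPES])
  cfm <- sum(out[CFM_TYPES])
  c(out, sfm_total = sfm, cfm_total = cfm,
    malnourished_total = sfm + cfm, n = sum(out))
}

.region_lookup_env <- new.env(parent = emptyenv())

#' Country to global-region lookup
#'
#' Maps each of the 62 study countries to one of six global regions: `CA`
#' (Central Asia), `LAC` (Latin America & the Caribbean), `NAWAE` (North
#' Africa, West Asia & Europe), `Oceania`, `SASEA` (South Asia & Southeast
#' Asia) and `SSA` (Sub-Saharan Africa). The lookup ships as
#' `inst/extdata/country_regions.csv` and can be replaced via `lookup`.
#'
#' @param country character vector of country names.
#' @param lookup optional data.frame with columns `country`, `region`
#'   overriding the bundled table.
#' @return character vector of region codes.
#' @export
map_country_region <- function(country, lookup = NULL) {
  if (is.null(lookup)) {
    if (is.null(.region_lookup_env$tab)) {
      path <- system.file("extdata", "country_regions.csv",
                          package = "cfmtools", mustWork = TRUE)
      .region_lookup_env$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    lookup <- .region_lookup_env$tab
  }
  idx <- match(as.character(country), lookup$country)
  if (any(is.na(idx) & !is.na(country))) {
    bad <- unique(country[is.na(idx) & !is.na(country)])
    stop("unknown country: ", paste(bad, collapse = ", "),
         ". Valid names: ", paste(lookup$country, collapse = ", "))
  }
  lookup$region[idx]
}
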