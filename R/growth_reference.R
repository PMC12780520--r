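# Growth-reference tables and the LMS z-score engine.

DAYS_PER_MONTH <- 30.4375

.indicators <- c("length_height_for_age", "weight_for_age", "weight_for_length_height")
.axis_kinds <- c("age_days", "age_months", "length_cm", "height_cm")
.sexes <- c("male", "female")

#' Construct a growth-reference table
#'
#' A growth reference holds the LMS parameters (Box-Cox power `L`, median `M`,
#' coefficient of variation `S`) of a measurement distribution tabulated along
#' an axis `t` (age in months, or length/height in cm). Z-scores are obtained
#' by interpolating `L`, `M`, `S` at the child's axis value and applying the
#' LMS transform.
#'
#' @param t numeric axis values (strictly increasing after sorting).
#' @param L,M,S numeric LMS parameters, one per axis value. `M` and `S` must be
#'   strictly positive.
#' @param indicator one of `"length_height_for_age"`, `"weight_for_age"`,
#'   `"weight_for_length_height"`.
#' @param sex `"male"` or `"female"`.
#' @param axis_kind one of `"age_days"`, `"age_months"`, `"length_cm"`,
#'   `"height_cm"`. Tables keyed in days are converted to months
#'   (1 month = 30.4375 days) so all age lookups use decimal months.
#' @return an object of class `growth_reference`.
#' @export
growth_reference <- function(t, L, M, S, indicator, sex, axis_kind) {
  indicator <- match.arg(indicator, .indicators)
  sex <- match.arg(sex, .sexes)
  axis_kind <- match.arg(axis_kind, .axis_kinds)
  tab <- data.frame(t = as.numeric(t), L = as.numeric(L),
                    M = as.numeric(M), S = as.numeric(S))
  if (nrow(tab) < 2L) {
    stop("growth reference needs at least 2 rows, got ", nrow(tab))
  }
  bad <- which(!is.finite(tab$t) | !is.finite(tab$L) |
                 !is.finite(tab$M) | !is.finite(tab$S))
  if (length(bad)) {
    stop("non-finite LMS values at row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(tab$M <= 0)
  if (length(bad)) {
    stop("non-positive M at row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(tab$S <= 0)
  if (length(bad)) {
    stop("non-positive S at row(s) ", paste(bad, collapse = ", "))
  }
  if (is.unsorted(tab$t, strictly = TRUE)) {
    if (anyDuplicated(tab$t)) {
      stop("duplicated axis value t = ",
           tab$t[anyDuplicated(tab$t)], " in growth reference")
    }
    warning("growth-reference rows not sorted by t; sorting ascending")
    tab <- tab[order(tab$t), , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (axis_kind == "age_days") {
    tab$t <- tab$t / DAYS_PER_MONTH
    axis_kind <- "age_months"
  }
  structure(list(indicator = indicator, sex = sex, axis_kind = axis_kind,
                 table = tab),
            class = "growth_reference")
}

#' @export
print.growth_reference <- function(x, ...) {
  cat(sprintf("<growth_reference> %s / %s on %s: %d rows, t in [%g, %g]\n",
              x$indicator, x$sex, x$axis_kind, nrow(x$table),
              min(x$table$t), max(x$table$t)))
  invisible(x)
}

#' Load a growth-reference table from a CSV file
#'
#' The file must contain columns `t`, `L`, `M`, `S`. Metadata (indicator, sex,
#' axis kind) is taken from the arguments when given, otherwise parsed from a
#' file name of the form `<indicator>_<sex>_<axis_kind>.csv`, e.g.
#' `weight_for_age_male_age_months.csv`.
#'
#' @param path path to a delimited text file with header `t,L,M,S`.
#' @param indicator,sex,axis_kind optional metadata overriding the filename
#'   convention.
#' @return a [growth_reference()] object.
#' @export
load_reference <- function(path, indicator = NULL, sex = NULL, axis_kind = NULL) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "L", "M", "S")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("reference file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(indicator) || is.null(sex) || is.null(axis_kind)) {
    stem <- sub("\\.[^.]+$", "", basename(path))
    for (ind in .indicators) {
      if (startsWith(stem, ind)) {
        rest <- sub(paste0("^", ind, "_"), "", stem)
        for (sx in .sexes) {
          if (startsWith(rest, sx)) {
            ax <- sub(paste0("^", sx, "_"), "", rest)
            if (is.null(indicator)) indicator <- ind
            if (is.null(sex)) sex <- sx
            if (is.null(axis_kind)) axis_kind <- ax
          }
        }
      }
    }
    if (is.null(indicator) || is.null(sex) || is.null(axis_kind)) {
      stop("cannot infer indicator/sex/axis_kind from file name '",
           basename(path), "'; pass them explicitly")
    }
  }
  growth_reference(tab$t, tab$L, tab$M, tab$S, indicator, sex, axis_kind)
}

#' Interpolate LMS parameters at axis values
#'
#' Piecewise-linear interpolation of `L`, `M` and `S` separately between the
#' bracketing table rows; knot values are reproduced exactly. No extrapolation:
#' values outside the table range are an error.
#'
#' @param ref a [growth_reference()].
#' @param t numeric vector of axis values.
#' @return a data.frame with columns `L`, `M`, `S`, one row per `t`.
#' @export
interpolate_lms <- function(ref, t) {
  stopifnot(inherits(ref, "growth_reference"))
  tab <- ref$table
  out_of_range <- !is.na(t) & (t < tab$t[1L] | t > tab$t[nrow(tab)])
  if (any(out_of_range)) {
    stop(sprintf("axis value %g outside reference range [%g, %g]",
                 t[which(out_of_range)[1L]], tab$t[1L], tab$t[nrow(tab)]))
  }
  data.frame(
    L = stats::approx(tab$t, tab$L, xout = t)$y,
    M = stats::approx(tab$t, tab$M, xout = t)$y,
    S = stats::approx(tab$t, tab$S, xout = t)$y
  )
}

# Interpolation that yields NA outside the table support instead of erroring;
# used by compute_indices so an out-of-range child gets a missing component.
.interp_lms_soft <- function(ref, t) {
  tab <- ref$table
  data.frame(
    L = stats::approx(tab$t, tab$L, xout = t, rule = 1)$y,
    M = stats::approx(tab$t, tab$M, xout = t, rule = 1)$y,
    S = stats::approx(tab$t, tab$S, xout = t, rule = 1)$y
  )
}

#' LMS z-score transform
#'
#' Converts a measurement `y` to a z-score given LMS parameters:
#' `z = ((y/M)^L - 1) / (L * S)`, with the continuous log-limit
#' `z = log(y/M) / S` when `|L| < 1e-8`.
#'
#' @param y positive measurement value(s).
#' @param L,M,S LMS parameters (recycled); `M > 0`, `S > 0`.
#' @return z-score(s) in SD units.
#' @export
lms_zscore <- function(y, L, M, S) {
  n <- max(length(y), length(L), length(M), length(S))
  y <- rep_len(y, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ok <- is.na(y) | is.na(M) | (y > 0 & M > 0 & S > 0)
  if (!all(ok)) {
    stop("lms_zscore requires y > 0, M > 0, S > 0 (violated at position ",
         which(!ok)[1L], ")")
  }
  z <- ifelse(abs(L) < 1e-8,
              log(y / M) / S,
              ((y / M)^L - 1) / (L * S))
  z
}

#' Inverse LMS transform
#'
#' Recovers the measurement at a given z-score:
#' `y = M * (1 + L*S*z)^(1/L)` (`M * exp(S*z)` in the log-limit). Round-trips
#' with [lms_zscore()] to better than 1e-10 SD.
#'
#' @param z z-score(s) in SD units.
#' @param L,M,S LMS parameters (recycled).
#' @return measurement value(s).
#' @export
invert_lms_zscore <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  base <- 1 + L * S * z
  bad <- !is.na(z) & abs(L) >= 1e-8 & base <= 0
  if (any(bad)) {
    stop("invert_lms_zscore: 1 + L*S*z <= 0 at z = ", z[which(bad)[1L]])
  }
  ifelse(abs(L) < 1e-8, M * exp(S * z), M * base^(1 / L))
}

#' Restricted adjustment of weight-based z-scores
#'
#' WHO convention for weight-for-age and weight-for-length/height: z-scores in
#' `[-3, 3]` pass through unchanged; beyond 3 SD the score is linearized on the
#' measurement scale using the local width of the 2-to-3 SD band,
#' `z = 3 + (y - SD3pos) / (SD3pos - SD2pos)` above and
#' `z = -3 + (y - SD3neg) / (SD2neg - SD3neg)` below, where `SDk` are the
#' measurements at z = k from the inverse LMS transform. Height-based
#' indicators are never adjusted.
#'
#' @param z unadjusted z-score(s).
#' @param y measurement value(s).
#' @param L,M,S LMS parameters (recycled).
#' @param indicator indicator name; only the weight-based indicators are
#'   adjusted, `"length_height_for_age"` passes through.
#' @return adjusted z-score(s); identity on `[-3, 3]`, continuous at the join.
#' @export
restricted_adjust <- function(z, y, L, M, S,
                              indicator = "weight_for_age") {
  indicator <- match.arg(indicator, .indicators)
  if (indicator == "length_height_for_age") return(z)
  n <- max(length(z), length(y), length(L), length(M), length(S))
  z <- rep_len(z, n); y <- rep_len(y, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  out <- z
  hi <- which(!is.na(z) & z > 3)
  if (length(hi)) {
    sd3 <- invert_lms_zscore(3, L[hi], M[hi], S[hi])
    sd2 <- invert_lms_zscore(2, L[hi], M[hi], S[hi])
    if (any(sd3 - sd2 <= 0)) stop("degenerate SD band: SD3pos <= SD2pos")
    out[hi] <- 3 + (y[hi] - sd3) / (sd3 - sd2)
  }
  lo <- which(!is.na(z) & z < -3)
  if (length(lo)) {
    sd3 <- invert_lms_zscore(-3, L[lo], M[lo], S[lo])
    sd2 <- invert_lms_zscore(-2, L[lo], M[lo], S[lo])
    if (any(sd2 - sd3 <= 0)) stop("degenerate SD band: SD2neg <= SD3neg")
    out[lo] <- -3 + (y[lo] - sd3) / (sd2 - sd3)
  }
  out
}

#' Bundle growth references into an indexed set
#'
#' @param ... [growth_reference()] objects (or a single list of them) covering
#'   the indicator/sex/axis combinations needed by [compute_indices()].
#' @return an object of class `reference_set`, a list keyed by
#'   `indicator.sex.axis_kind`.
#' @export
reference_set <- function(...) {
  refs <- list(...)
  if (length(refs) == 1L && !inherits(refs[[1L]], "growth_reference")) {
    refs <- refs[[1L]]
  }
  ok <- vapply(refs, inherits, logical(1), "growth_reference")
  if (!all(ok)) stop("all elements must be growth_reference objects")
  keys <- vapply(refs, function(r) {
    paste(r$indicator, r$sex, r$axis_kind, sep = ".")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate reference for ", keys[anyDuplicated(keys)])
  }
  structure(stats::setNames(refs, keys), class = "reference_set")
}

#' Load a directory of reference CSVs as a reference set
#'
#' @param dir directory containing files named
#'   `<indicator>_<sex>_<axis_kind>.csv`.
#' @return a [reference_set()].
#' @export
load_reference_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no reference CSV files found in ", dir)
  reference_set(lapply(files, load_reference))
}

.get_ref <- function(refs, indicator, sex, axis_kind) {
  refs[[paste(indicator, sex, axis_kind, sep = ".")]]
}

#' Compute HAZ, WAZ and WHZ for child records
#'
#' Applies the LMS engine to raw measurements. Height-for-age (HAZ) and
#' weight-for-age (WAZ) use the age axis; weight-for-length/height (WHZ) uses
#' the length axis below 24 months (recumbent convention) and the height axis
#' at 24 months and above. When the measurement position is known and
#' mismatches the age convention, 0.7 cm is added to a standing measurement
#' below 24 months and subtracted from a recumbent measurement at 24 months or
#' above before any length/height lookup. WAZ and WHZ receive the restricted
#' adjustment beyond 3 SD; HAZ never does. Missing or out-of-range inputs give
#' missing components without failing the record; a record with all three
#' indices missing is flagged, not an error.
#'
#' @param children data.frame with columns `age_months`, `sex`
#'   (`"male"`/`"female"`), `weight_kg`, `lenhei_cm`, and optionally
#'   `measured_recumbent` (logical, `NA` = unknown).
#' @param refs a [reference_set()] covering the needed tables.
#' @param position_correction apply the 0.7 cm recumbent/standing correction
#'   when position is known (default `TRUE`).
#' @return data.frame with columns `haz`, `waz`, `whz`, `no_index` (logical:
#'   all three indices missing).
#' @export
compute_indices <- function(children, refs, position_correction = TRUE) {
  stopifnot(is.data.frame(children), inherits(refs, "reference_set"))
  n <- nrow(children)
  age <- children$age_months
  sex <- as.character(children$sex)
  wt <- children$weight_kg
  ht <- children$lenhei_cm
  pos <- if ("measured_recumbent" %in% names(children)) {
    children$measured_recumbent
  } else {
    rep(NA, n)
  }
  bad_sex <- !is.na(sex) & !sex %in% .sexes
  if (any(bad_sex)) {
    stop("unknown sex value '", sex[which(bad_sex)[1L]],
         "'; expected 'male' or 'female'")
  }
  young <- !is.na(age) & age < 24

  # position-corrected length/height on the age-appropriate scale
  ht_corr <- ht
  if (position_correction) {
    add <- which(young & !is.na(pos) & pos == FALSE)   # standing, < 24 mo
    sub <- which(!young & !is.na(age) & !is.na(pos) & pos == TRUE)
    ht_corr[add] <- ht_corr[add] + 0.7
    ht_corr[sub] <- ht_corr[sub] - 0.7
  }

  haz <- rep(NA_real_, n)
  waz <- rep(NA_real_, n)
  whz <- rep(NA_real_, n)

  for (sx in .sexes) {
    i_sex <- which(!is.na(sex) & sex == sx)
    if (!length(i_sex)) next

    lhfa <- .get_ref(refs, "length_height_for_age", sx, "age_months")
    wfa <- .get_ref(refs, "weight_for_age", sx, "age_months")
    wfl <- .get_ref(refs, "weight_for_length_height", sx, "length_cm")
    wfh <- .get_ref(refs, "weight_for_length_height", sx, "height_cm")

    i <- i_sex[!is.na(age[i_sex]) & !is.na(ht_corr[i_sex])]
    if (length(i) && !is.null(lhfa)) {
      p <- .interp_lms_soft(lhfa, age[i])
      ok <- !is.na(p$M) & ht_corr[i] > 0
      haz[i[ok]] <- lms_zscore(ht_corr[i][ok], p$L[ok], p$M[ok], p$S[ok])
    }

    i <- i_sex[!is.na(age[i_sex]) & !is.na(wt[i_sex])]
    if (length(i) && !is.null(wfa)) {
      p <- .interp_lms_soft(wfa, age[i])
      ok <- !is.na(p$M) & wt[i] > 0
      z <- lms_zscore(wt[i][ok], p$L[ok], p$M[ok], p$S[ok])
      waz[i[ok]] <- restricted_adjust(z, wt[i][ok], p$L[ok], p$M[ok], p$S[ok],
                                      "weight_for_age")
    }

    for (band in c("length", "height")) {
      ref <- if (band == "length") wfl else wfh
      if (is.null(ref)) next
      in_band <- if (band == "length") young[i_sex] else
        (!is.na(age[i_sex]) & age[i_sex] >= 24)
      i <- i_sex[in_band & !is.na(wt[i_sex]) & !is.na(ht_corr[i_sex])]
      if (!length(i)) next
      p <- .interp_lms_soft(ref, ht_corr[i])
      ok <- !is.na(p$M) & wt[i] > 0
      z <- lms_zscore(wt[i][ok], p$L[ok], p$M[ok], p$S[ok])
      whz[i[ok]] <- restricted_adjust(z, wt[i][ok], p$L[ok], p$M[ok], p$S[ok],
                                      "weight_for_length_height")
    }
  }

  data.frame(haz = haz, waz = waz, whz = whz,
             no_index = is.na(haz) & is.na(waz) & is.na(whz))
}
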