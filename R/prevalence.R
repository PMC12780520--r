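# Survey-weighted prevalence estimation at national, regional and global levels.

#' Kish effective sample size
#'
#' `n_eff = (sum w)^2 / sum(w^2)`: the equal-weight sample size with the same
#' variance as the weighted sample. Equal weights give `n_eff = n`.
#'
#' @param weights positive sampling weights.
#' @return effective sample size (numeric scalar).
#' @export
effective_sample_size <- function(weights) {
  if (!length(weights)) stop("effective_sample_size: empty weight vector")
  if (any(is.na(weights)) || any(weights <= 0)) {
    stop("effective_sample_size: weights must be positive and non-missing")
  }
  sum(weights)^2 / sum(weights^2)
}

#' Confidence interval for a proportion
#'
#' Wilson score interval (default) or Wald interval on an effective sample
#' size, clamped to `[0, 1]`.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param n_eff (effective) sample size(s), `> 0`.
#' @param method `"wilson"` or `"wald"`.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `low`, `high`.
#' @export
proportion_ci <- function(p, n_eff, method = c("wilson", "wald"), conf = 0.95) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), all(n_eff > 0, na.rm = TRUE))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / n_eff
    centre <- (p + z^2 / (2 * n_eff)) / denom
    half <- z * sqrt(p * (1 - p) / n_eff + z^2 / (4 * n_eff^2)) / denom
    low <- centre - half
    high <- centre + half
  } else {
    half <- z * sqrt(p * (1 - p) / n_eff)
    low <- p - half
    high <- p + half
  }
  data.frame(low = pmin(pmax(low, 0), 1), high = pmin(pmax(high, 0), 1))
}

#' Survey-weighted prevalence of a binary outcome
#'
#' Horvitz-Thompson ratio estimator `100 * sum(w * x) / sum(w)` with a
#' confidence interval computed on the Kish effective sample size. With equal
#' weights this is exactly the unweighted proportion.
#'
#' @param x logical (or 0/1) outcome membership per record.
#' @param weights positive sampling weights.
#' @param ci_method `"wilson"` or `"wald"`.
#' @param conf confidence level.
#' @return one-row data.frame: `point_pct`, `ci_low_pct`, `ci_high_pct`,
#'   `n_unweighted`, `n_weighted`, `n_eff`.
#' @export
weighted_prevalence <- function(x, weights = rep(1, length(x)),
                                ci_method = "wilson", conf = 0.95) {
  if (!length(x)) stop("weighted_prevalence: empty group")
  if (length(weights) != length(x)) stop("weights must match x in length")
  keep <- !is.na(x)
  x <- as.numeric(x[keep]); w <- weights[keep]
  if (!length(x)) stop("weighted_prevalence: no non-missing records in group")
  if (any(is.na(w)) || any(w <= 0)) stop("weights must be positive")
  tw <- sum(w)
  if (tw <= 0) stop("zero total weight in group")
  p <- sum(w * x) / tw
  n_eff <- effective_sample_size(w)
  ci <- proportion_ci(p, n_eff, method = ci_method, conf = conf)
  data.frame(point_pct = 100 * p,
             ci_low_pct = 100 * ci$low, ci_high_pct = 100 * ci$high,
             n_unweighted = length(x), n_weighted = tw, n_eff = n_eff)
}

# Outcome columns of the standard prevalence report, in report order.
.report_outcomes <- c("malnourished", "SFM", "CFM", "CUW", "CUS", "CUWS", "CSO")

.outcome_flags <- function(category) {
  category <- factor(as.character(category), levels = CFM_CATEGORIES)
  cfm <- category %in% CFM_TYPES
  sfm <- category %in% SFM_TYPES
  data.frame(malnourished = sfm | cfm, SFM = sfm, CFM = cfm,
             CUW = category == "CUW", CUS = category == "CUS",
             CUWS = category == "CUWS", CSO = category == "CSO")
}

#' Weighted prevalence report at national, regional and global levels
#'
#' Emits one row per (unit, outcome) over the outcome set malnourished, SFM,
#' CFM, CUW, CUS, CUWS, CSO. National estimates use the within-country weights
#' as given. For regional and global estimates, survey weights are only
#' relatively scaled within a survey, so each country's weights are first
#' rescaled according to `pooling`:
#' \describe{
#'   \item{`"sample_size"`}{weights rescaled to sum to the country's
#'     unweighted n, so each country contributes its sample size (default).}
#'   \item{`"population"`}{weights rescaled to user-supplied country shares
#'     (`pop_shares`, a named vector of positive masses).}
#' }
#'
#' @param data data.frame with columns `category`, `weight`, `country` (and
#'   any others, which are ignored).
#' @param levels subset of `c("national", "regional", "global")`.
#' @param pooling `"sample_size"` or `"population"`.
#' @param pop_shares named positive vector of country population shares,
#'   required for `pooling = "population"`.
#' @param ci_method,conf passed to [weighted_prevalence()].
#' @param region_lookup optional lookup passed to [map_country_region()].
#' @return data.frame with columns `level`, `unit`, `category`, `point_pct`,
#'   `ci_low_pct`, `ci_high_pct`, `n_unweighted`, `n_weighted`.
#' @export
aggregate_prevalence <- function(data,
                                 levels = c("national", "regional", "global"),
                                 pooling = c("sample_size", "population"),
                                 pop_shares = NULL,
                                 ci_method = "wilson", conf = 0.95,
                                 region_lookup = NULL) {
  levels <- match.arg(levels, several.ok = TRUE)
  pooling <- match.arg(pooling)
  stopifnot(all(c("category", "weight", "country") %in% names(data)))
  data <- data[!is.na(data$category), , drop = FALSE]
  if (!nrow(data)) stop("no classified records to aggregate")
  data$region <- map_country_region(data$country, lookup = region_lookup)

  # country-rescaled weights for pooled (regional/global) estimates
  ctab <- split(seq_len(nrow(data)), data$country)
  w_pooled <- data$weight
  for (cc in names(ctab)) {
    i <- ctab[[cc]]
    mass <- if (pooling == "sample_size") {
      length(i)
    } else {
      if (is.null(pop_shares) || is.null(pop_shares[[cc]])) {
        stop("population pooling requires pop_shares for country ", cc)
      }
      pop_shares[[cc]]
    }
    w_pooled[i] <- data$weight[i] * mass / sum(data$weight[i])
  }

  flags <- .outcome_flags(data$category)
  one_unit <- function(idx, w, level, unit) {
    do.call(rbind, lapply(.report_outcomes, function(oc) {
      est <- weighted_prevalence(flags[[oc]][idx], w[idx],
                                 ci_method = ci_method, conf = conf)
      cbind(data.frame(level = level, unit = unit, category = oc,
                       stringsAsFactors = FALSE),
            est[c("point_pct", "ci_low_pct", "ci_high_pct",
                  "n_unweighted", "n_weighted")])
    }))
  }

  out <- list()
  if ("national" %in% levels) {
    out <- c(out, lapply(names(ctab), function(cc) {
      one_unit(ctab[[cc]], data$weight, "national", cc)
    }))
  }
  if ("regional" %in% levels) {
    rtab <- split(seq_len(nrow(data)), data$region)
    out <- c(out, lapply(names(rtab), function(rr) {
      one_unit(rtab[[rr]], w_pooled, "regional", rr)
    }))
  }
  if ("global" %in% levels) {
    out <- c(out, list(one_unit(seq_len(nrow(data)), w_pooled,
                                "global", "global")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Check internal additivity of a prevalence report
#'
#' For every unit, the malnourished prevalence must equal SFM + CFM and the
#' CFM prevalence must equal CUW + CUS + CUWS + CSO, up to `tol_pct`
#' percentage points (use a small tolerance for internally generated reports
#' and a rounding allowance for transcribed published tables).
#'
#' @param report long-format report as returned by [aggregate_prevalence()]
#'   (columns `unit`, `category`, `point_pct`; extra columns ignored).
#' @param tol_pct tolerance in percentage points.
#' @return data.frame of violations (`unit`, `check`, `discrepancy_pct`);
#'   zero rows when the report is internally consistent.
#' @export
validate_report <- function(report, tol_pct = 1e-9) {
  stopifnot(all(c("unit", "category", "point_pct") %in% names(report)))
  out <- list()
  for (u in unique(report$unit)) {
    r <- report[report$unit == u, , drop = FALSE]
    val <- function(oc) {
      v <- r$point_pct[match(oc, r$category)]
      if (anyNA(v)) stop("report for unit '", u, "' is missing category ",
                         paste(oc[is.na(match(oc, r$category))], collapse = ", "))
      v
    }
    d1 <- abs(val("malnourished") - (val("SFM") + val("CFM")))
    d2 <- abs(val("CFM") - sum(val(c("CUW", "CUS", "CUWS", "CSO"))))
    if (d1 > tol_pct) {
      out[[length(out) + 1L]] <- data.frame(
        unit = u, check = "malnourished = SFM + CFM", discrepancy_pct = d1)
    }
    if (d2 > tol_pct) {
      out[[length(out) + 1L]] <- data.frame(
        unit = u, check = "CFM = CUW + CUS + CUWS + CSO", discrepancy_pct = d2)
    }
  }
  if (!length(out)) {
    return(data.frame(unit = character(), check = character(),
                      discrepancy_pct = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
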