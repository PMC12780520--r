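# Independent oracles used across the suite.

# Brute-force classifier oracle: a hand-written lookup over the 16 predicate
# combinations (stunted, wasted, underweight, over), derived directly from the
# taxonomy definitions. Independent of the package's precedence-ladder code.
.oracle_table <- local({
  tab <- data.frame(
    st = rep(c(FALSE, TRUE), times = 8),
    wa = rep(rep(c(FALSE, TRUE), each = 2), times = 4),
    uw = rep(rep(c(FALSE, TRUE), each = 4), times = 2),
    ov = rep(c(FALSE, TRUE), each = 8)
  )
  key <- function(st, wa, uw, ov) 1 + st + 2 * wa + 4 * uw + 8 * ov
  cat <- character(16); flag <- character(16)
  set <- function(st, wa, uw, ov, category, fl = "none") {
    i <- key(st, wa, uw, ov)
    cat[i] <<- category; flag[i] <<- fl
  }
  set(F, F, F, F, "normal")
  set(T, F, F, F, "stunting")
  set(F, T, F, F, "wasting")
  set(F, F, T, F, "underweight")
  set(F, F, F, T, "overweight_obese")
  set(T, T, F, F, "stunting", "stunted_wasted_not_underweight")
  set(T, F, T, F, "CUS")
  set(T, F, F, T, "CSO")
  set(F, T, T, F, "CUW")
  set(F, T, F, T, "wasting", "multiple_standalone")
  set(F, F, T, T, "underweight", "underweight_with_overfeeding_pattern")
  set(T, T, T, F, "CUWS")
  set(T, T, F, T, "CSO", "stunted_wasted_not_underweight")
  set(T, F, T, T, "CUS", "underweight_with_overfeeding_pattern")
  # wa & uw & ov combinations are logically impossible (whz <= -2 excludes
  # whz >= +2 and waz <= -2 excludes waz >= +2); left unlabelled on purpose.
  set(F, T, T, T, "impossible")
  set(T, T, T, T, "impossible")
  tab$category <- cat; tab$flag <- flag
  tab$key <- key(tab$st, tab$wa, tab$uw, tab$ov)
  tab[order(tab$key), ]
})

oracle_classify <- function(haz, waz, whz) {
  st <- haz <= -2
  wa <- whz <= -2
  uw <- waz <= -2
  ov <- whz >= 2 | waz >= 2
  i <- 1 + st + 2 * wa + 4 * uw + 8 * ov
  data.frame(category = .oracle_table$category[i],
             flag = .oracle_table$flag[i],
             cfm = .oracle_table$category[i] %in% c("CUW", "CUS", "CUWS", "CSO"),
             stringsAsFactors = FALSE)
}

# Hand-rolled Horvitz-Thompson weighted proportion.
oracle_weighted_prop <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * as.numeric(x[i])
    den <- den + w[i]
  }
  num / den
}

# Tiny all-purpose toy reference: L = 1 linear tables, used where the exact
# fixture geometry is irrelevant.
toy_linear_ref <- function(indicator = "weight_for_age", sex = "male",
                           axis_kind = "age_months") {
  growth_reference(t = c(0, 30, 60), L = 1, M = c(10, 12, 14), S = 0.1,
                   indicator = indicator, sex = sex, axis_kind = axis_kind)
}
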