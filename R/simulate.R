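# Synthetic DHS-like microdata with known ground truth: correlated z-scores,
# planted covariate effects, sampling weights, clusters and country labels.

# Latent model. Two latent components (the height-for-age and
# weight-for-height axes) are drawn from a bivariate normal; the weight-for-age
# score is coupled to them. On the z-score output pathway the coupling is
# stochastic (waz = a*haz + b*whz + noise). On the raw-measurement pathway
# only two degrees of freedom exist (given age, weight and height determine
# all three indices), so the toy references are built log-linear, which makes
# the engine-implied coupling exactly waz = whz + k*haz with k fixed by the
# table slopes.

#' Generate the toy growth-reference fixture
#'
#' Builds smooth log-normal (Box-Cox power L = 0) LMS tables for both sexes
#' and all three indicators: length/height-for-age and weight-for-age on an
#' age axis of 0-60 months, and weight-for-length/height on a length/height
#' axis wide enough to cover |HAZ| <= 6 at every age. Median curves are
#' log-linear in age, so the three indices computed from a child's raw
#' measurements satisfy an exact linear consistency relation
#' `waz = whz + k * haz` (k is returned as an attribute). The seed perturbs
#' the median intercepts slightly; output is deterministic per seed.
#'
#' @param seed integer seed.
#' @return a [reference_set()] with attribute `consistency` (list with the
#'   coupling constant `k` and the S parameters used).
#' @export
generate_reference_fixture <- function(seed = 1) {
  set.seed(seed)
  jit <- stats::runif(4, -0.005, 0.005)
  S_h <- 0.05          # length/height coefficient of variation
  S_w <- 0.18          # weight coefficient of variation (both weight tables)
  Mh0 <- c(male = 49.9 * (1 + jit[1]), female = 49.1 * (1 + jit[2]))
  Mw0 <- c(male = 3.3 * (1 + jit[3]), female = 3.2 * (1 + jit[4]))
  c1 <- log(110 / 49.9) / 60   # log-slope of median height vs age
  d1 <- log(16.0 / 3.3) / 60   # log-slope of median weight vs age
  k <- d1 * S_h / (c1 * S_w)

  ages <- seq(0, 60, by = 0.5)
  lens <- seq(36, 152, by = 0.5)
  refs <- list()
  for (sx in c("male", "female")) {
    M_h <- Mh0[[sx]] * exp(c1 * ages)
    M_w <- Mw0[[sx]] * exp(d1 * ages)
    # median weight at a given length: weight of the median child whose
    # median height equals that length (log-linear inversion of the age axis)
    M_wl <- Mw0[[sx]] * exp(d1 * (log(lens) - log(Mh0[[sx]])) / c1)
    refs <- c(refs, list(
      growth_reference(ages, 0, M_h, S_h, "length_height_for_age", sx,
                       "age_months"),
      growth_reference(ages, 0, M_w, S_w, "weight_for_age", sx, "age_months"),
      growth_reference(lens, 0, M_wl, S_w, "weight_for_length_height", sx,
                       "length_cm"),
      growth_reference(lens, 0, M_wl, S_w, "weight_for_length_height", sx,
                       "height_cm")
    ))
  }
  out <- reference_set(refs)
  attr(out, "consistency") <- list(k = k, S_h = S_h, S_w = S_w,
                                   c1 = c1, d1 = d1)
  out
}

#' Simulation configuration for synthetic survey microdata
#'
#' Defaults describe a plausible pooled under-five population: mean HAZ well
#' below zero with unit-ish spread, milder WHZ deficit, a weak positive
#' HAZ-WHZ correlation, and WAZ coupled to both. Countries contribute additive
#' latent mean shifts; categorical covariates contribute additive shifts per
#' level (zero by default). Sampling weights are i.i.d. gamma.
#'
#' @param countries data.frame with columns `country`, `n_clusters`,
#'   `cluster_size`, `shift_haz`, `shift_whz`.
#' @param mean_haz,sd_haz,mean_whz,sd_whz,cor_haz_whz latent bivariate-normal
#'   parameters (SD units).
#' @param waz_loading_haz,waz_loading_whz,waz_noise_sd coupling of WAZ to the
#'   two latent components on the z-score output pathway.
#' @param covariates named list; each element a list with `levels` (character),
#'   `probs` (marginal probabilities summing to 1), and optional `shift_haz`,
#'   `shift_whz` (numeric per level, default zero).
#' @param weight_shape,weight_scale gamma parameters of the sampling weights.
#' @param output `"measurements"` (invert latent scores to raw weight and
#'   length/height, then recompute all indices with the LMS engine) or
#'   `"zscores"` (emit the latent triple directly).
#' @param seed integer seed; all randomness in [generate_population()] derives
#'   from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(countries,
                       mean_haz = -0.9, sd_haz = 1.25,
                       mean_whz = -0.35, sd_whz = 1.05,
                       cor_haz_whz = 0.05,
                       waz_loading_haz = 0.55, waz_loading_whz = 0.55,
                       waz_noise_sd = 0.4,
                       covariates = list(),
                       weight_shape = 4, weight_scale = 0.25,
                       output = c("measurements", "zscores"),
                       seed = 1) {
  output <- match.arg(output)
  stopifnot(is.data.frame(countries),
            all(c("country", "n_clusters", "cluster_size",
                  "shift_haz", "shift_whz") %in% names(countries)),
            sd_haz > 0, sd_whz > 0, abs(cor_haz_whz) < 1,
            waz_noise_sd >= 0, weight_shape > 0, weight_scale > 0)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    stopifnot(length(cv$levels) >= 2L, length(cv$probs) == length(cv$levels))
    if (abs(sum(cv$probs) - 1) > 1e-8) {
      stop("marginal probabilities of covariate '", nm, "' must sum to 1")
    }
    for (fld in c("shift_haz", "shift_whz")) {
      if (is.null(cv[[fld]])) {
        covariates[[nm]][[fld]] <- rep(0, length(cv$levels))
      } else stopifnot(length(cv[[fld]]) == length(cv$levels))
    }
  }
  n <- sum(countries$n_clusters * countries$cluster_size)
  structure(list(countries = countries, mean_haz = mean_haz, sd_haz = sd_haz,
                 mean_whz = mean_whz, sd_whz = sd_whz,
                 cor_haz_whz = cor_haz_whz,
                 waz_loading_haz = waz_loading_haz,
                 waz_loading_whz = waz_loading_whz,
                 waz_noise_sd = waz_noise_sd,
                 covariates = covariates,
                 weight_shape = weight_shape, weight_scale = weight_scale,
                 output = output, n_children = n, seed = seed),
            class = "sim_config")
}

# 2x2 covariance of the latent (haz, whz) pair
.latent_cov2 <- function(config) {
  v <- config$cor_haz_whz * config$sd_haz * config$sd_whz
  matrix(c(config$sd_haz^2, v, v, config$sd_whz^2), 2, 2)
}

# map from latent (haz, whz) to the emitted (haz, waz, whz) triple:
# list(B = 3x2 loading matrix, noise_var = extra WAZ variance)
.triple_map <- function(config, k = NULL) {
  if (config$output == "measurements") {
    if (is.null(k)) stop("measurement pathway needs the fixture constant k")
    list(B = rbind(c(1, 0), c(k, 1), c(0, 1)), noise_var = 0)
  } else {
    list(B = rbind(c(1, 0),
                   c(config$waz_loading_haz, config$waz_loading_whz),
                   c(0, 1)),
         noise_var = config$waz_noise_sd^2)
  }
}

#' Moments of the emitted z-score triple for one mean-shift cell
#'
#' @param config a [sim_config()].
#' @param shift_haz,shift_whz additive latent mean shifts of the cell.
#' @param k coupling constant of the reference fixture (required for the
#'   measurement pathway; see [generate_reference_fixture()]).
#' @return list with `mean` (length 3: haz, waz, whz) and `cov` (3x3).
#' @export
triple_moments <- function(config, shift_haz = 0, shift_whz = 0, k = NULL) {
  map <- .triple_map(config, k)
  mu2 <- c(config$mean_haz + shift_haz, config$mean_whz + shift_whz)
  mean3 <- as.numeric(map$B %*% mu2)
  cov3 <- map$B %*% .latent_cov2(config) %*% t(map$B)
  cov3[2, 2] <- cov3[2, 2] + map$noise_var
  names(mean3) <- rownames(cov3) <- colnames(cov3) <- c("haz", "waz", "whz")
  list(mean = mean3, cov = cov3)
}

#' Generate a synthetic child population
#'
#' Draws covariates from their marginals, draws the latent z pair from the
#' bivariate normal with country and covariate mean shifts, couples WAZ, and
#' either emits the z triple directly or inverts to raw weight and
#' length/height and recomputes all indices through the LMS engine (so the
#' full pipeline is exercisable end-to-end). Assigns gamma sampling weights
#' and cluster/stratum labels, applies the plausibility filter and stores the
#' true classification of every record. Deterministic per `config$seed`.
#'
#' @param config a [sim_config()].
#' @param refs a [reference_set()]; defaults to
#'   `generate_reference_fixture(config$seed)` on the measurement pathway.
#' @return object of class `cfm_population`: list with `records` (data.frame)
#'   and `truth` (realized category counts and prevalences among plausible
#'   classified records, recomputable from `records`).
#' @export
generate_population <- function(config, refs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$output == "measurements" && is.null(refs)) {
    refs <- generate_reference_fixture(config$seed)
  }
  set.seed(config$seed)
  ctry <- config$countries
  country <- rep(ctry$country, ctry$n_clusters * ctry$cluster_size)
  cluster <- unlist(lapply(seq_len(nrow(ctry)), function(i) {
    rep(paste0(ctry$country[i], ":c", seq_len(ctry$n_clusters[i])),
        each = ctry$cluster_size[i])
  }))
  n <- length(country)
  stratum <- paste0(country, ":s",
                    1L + (as.integer(factor(cluster)) %% 2L))

  mu_haz <- config$mean_haz +
    rep(ctry$shift_haz, ctry$n_clusters * ctry$cluster_size)
  mu_whz <- config$mean_whz +
    rep(ctry$shift_whz, ctry$n_clusters * ctry$cluster_size)

  covs <- list()
  for (nm in names(config$covariates)) {
    cv <- config$covariates[[nm]]
    idx <- sample.int(length(cv$levels), n, replace = TRUE, prob = cv$probs)
    covs[[nm]] <- factor(cv$levels[idx], levels = cv$levels)
    mu_haz <- mu_haz + cv$shift_haz[idx]
    mu_whz <- mu_whz + cv$shift_whz[idx]
  }

  sig <- .latent_cov2(config)
  ch <- chol(sig)
  zlat <- matrix(stats::rnorm(2 * n), n, 2) %*% ch
  haz_l <- mu_haz + zlat[, 1]
  whz_l <- mu_whz + zlat[, 2]

  age <- stats::runif(n, 0, 60)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  recumbent <- age < 24

  rec <- data.frame(id = seq_len(n), country = country, cluster = cluster,
                    stratum = stratum,
                    weight = stats::rgamma(n, shape = config$weight_shape,
                                           scale = config$weight_scale),
                    age_months = age, sex = sex,
                    measured_recumbent = recumbent,
                    stringsAsFactors = FALSE)
  for (nm in names(covs)) rec[[nm]] <- covs[[nm]]

  if (config$output == "measurements") {
    wt <- ht <- rep(NA_real_, n)
    for (sx in c("male", "female")) {
      i <- which(sex == sx)
      lhfa <- .get_ref(refs, "length_height_for_age", sx, "age_months")
      p <- interpolate_lms(lhfa, age[i])
      ht[i] <- invert_lms_zscore(haz_l[i], p$L, p$M, p$S)
      for (band in c("length", "height")) {
        ref <- .get_ref(refs, "weight_for_length_height", sx,
                        paste0(if (band == "length") "length" else "height",
                               "_cm"))
        j <- i[if (band == "length") recumbent[i] else !recumbent[i]]
        if (!length(j)) next
        pw <- .interp_lms_soft(ref, ht[j])
        ok <- !is.na(pw$M)
        wt[j[ok]] <- invert_lms_zscore(whz_l[j][ok], pw$L[ok], pw$M[ok],
                                       pw$S[ok])
      }
    }
    rec$weight_kg <- wt
    rec$lenhei_cm <- ht
    zz <- compute_indices(rec, refs)
    rec$haz <- zz$haz; rec$waz <- zz$waz; rec$whz <- zz$whz
  } else {
    rec$haz <- haz_l
    rec$waz <- config$waz_loading_haz * haz_l +
      config$waz_loading_whz * whz_l +
      stats::rnorm(n, 0, config$waz_noise_sd)
    rec$whz <- whz_l
  }

  pl <- plausibility_filter(rec$haz, rec$waz, rec$whz)
  rec$retained <- pl$retained
  cls <- classify_nutrition(rec$haz, rec$waz, rec$whz)
  rec$category <- cls$category
  rec$category[!rec$retained] <- NA
  rec$conflict_flag <- cls$conflict_flag
  rec$incomplete <- cls$incomplete

  counts <- derive_group_counts(rec$category)
  prev <- 100 * counts / counts[["n"]]
  structure(list(records = rec,
                 truth = list(counts = counts,
                              prevalence_pct = prev[setdiff(names(prev), "n")],
                              n_classified = counts[["n"]],
                              config = config)),
            class = "cfm_population")
}

#' @export
print.cfm_population <- function(x, ...) {
  cat(sprintf("<cfm_population> %d records (%d classified)\n",
              nrow(x$records), x$truth$n_classified))
  invisible(x)
}

# All 27 boxes of z-space induced by cutpoints {-2, +2} per axis, each labeled
# with its (conflict-resolved) category via a representative interior point.
.category_boxes <- function() {
  cuts <- c(-Inf, -2, 2, Inf)
  reps <- c(-3, 0, 3)
  g <- expand.grid(i1 = 1:3, i2 = 1:3, i3 = 1:3)
  boxes <- data.frame(
    haz_lo = cuts[g$i1], haz_hi = cuts[g$i1 + 1L],
    waz_lo = cuts[g$i2], waz_hi = cuts[g$i2 + 1L],
    whz_lo = cuts[g$i3], whz_hi = cuts[g$i3 + 1L])
  lab <- classify_nutrition(reps[g$i1], reps[g$i2], reps[g$i3])
  boxes$category <- as.character(lab$category)
  boxes
}

# P(x1 in [a1,b1], x3 in [a3,b3], x2 in [a2,b2]) for a trivariate normal over
# (haz, waz, whz): 2D Gauss-Legendre over the (haz, whz) marginal, closed-form
# conditional normal CDF for waz. Tolerates zero conditional variance (the
# degenerate measurement-pathway covariance) via an indicator.
.box_prob_integrate <- function(mean3, cov3, box, n_nodes = 32) {
  m2 <- mean3[c(1, 3)]
  S2 <- cov3[c(1, 3), c(1, 3)]
  det2 <- S2[1, 1] * S2[2, 2] - S2[1, 2]^2
  if (det2 <= 1e-12 * S2[1, 1] * S2[2, 2]) {
    stop("(haz, whz) marginal is singular; use method = 'mc'")
  }
  b <- cov3[2, c(1, 3)]                       # cov(waz, (haz, whz))
  Sinv <- solve(S2)
  beta <- as.numeric(Sinv %*% b)
  cvar <- cov3[2, 2] - sum(b * beta)
  csd <- sqrt(max(cvar, 0))

  gl <- .gauss_legendre(n_nodes)
  lim <- function(lo, hi, mu, sd) {
    c(max(lo, mu - 8.5 * sd), min(hi, mu + 8.5 * sd))
  }
  l1 <- lim(box$haz_lo, box$haz_hi, m2[1], sqrt(S2[1, 1]))
  l2 <- lim(box$whz_lo, box$whz_hi, m2[2], sqrt(S2[2, 2]))
  if (l1[1] >= l1[2] || l2[1] >= l2[2]) return(0)
  x1 <- (l1[2] - l1[1]) / 2 * gl$x + (l1[1] + l1[2]) / 2
  w1 <- (l1[2] - l1[1]) / 2 * gl$w
  x2 <- (l2[2] - l2[1]) / 2 * gl$x + (l2[1] + l2[2]) / 2
  w2 <- (l2[2] - l2[1]) / 2 * gl$w

  X1 <- matrix(x1 - m2[1], n_nodes, n_nodes)
  X2 <- matrix(x2 - m2[2], n_nodes, n_nodes, byrow = TRUE)
  quad <- Sinv[1, 1] * X1^2 + 2 * Sinv[1, 2] * X1 * X2 + Sinv[2, 2] * X2^2
  dens <- exp(-quad / 2) / (2 * pi * sqrt(det2))
  cmu <- mean3[2] + beta[1] * X1 + beta[2] * X2
  inner <- if (csd > 1e-10) {
    stats::pnorm(box$waz_hi, cmu, csd) - stats::pnorm(box$waz_lo, cmu, csd)
  } else {
    (cmu >= box$waz_lo & cmu <= box$waz_hi) * 1
  }
  sum((w1 %o% w2) * dens * inner)
}

.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  # Golub-Welsch: nodes/weights from the Jacobi matrix eigendecomposition
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  ord <- order(res$x)
  res <- list(x = res$x[ord], w = res$w[ord])
  .gl_cache[[key]] <- res
  res
}

#' Expected category probabilities under a trivariate-normal z model
#'
#' Probability mass of each of the nine (conflict-resolved) category regions
#' of (HAZ, WAZ, WHZ) space under a trivariate normal. `"integration"`
#' (default) uses deterministic 2D Gauss-Legendre quadrature over the
#' (HAZ, WHZ) marginal with the closed-form conditional normal CDF in the WAZ
#' direction, and tolerates a rank-2 covariance in which WAZ is an exact
#' linear function of the other two. `"mc"` uses plain Monte Carlo with an
#' eigendecomposition sampler (valid for any positive semi-definite
#' covariance) and reports the per-category standard error as an attribute.
#'
#' @param z_means length-3 mean vector (haz, waz, whz).
#' @param z_cov 3x3 positive semi-definite covariance.
#' @param method `"integration"` or `"mc"`.
#' @param n_mc Monte-Carlo draws (default 1e6).
#' @param n_nodes quadrature nodes per dimension.
#' @param seed optional seed for the MC method.
#' @return named probability vector over [CFM_CATEGORIES]; for `"mc"`, the
#'   standard errors are in `attr(, "se")`.
#' @export
expected_category_probabilities <- function(z_means, z_cov,
                                            method = c("integration", "mc"),
                                            n_mc = 1e6, n_nodes = 32,
                                            seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(z_means) == 3, all(dim(z_cov) == c(3, 3)))
  ev <- eigen(z_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) stop("z_cov is not positive semi-definite")
  boxes <- .category_boxes()
  if (method == "integration") {
    p <- vapply(seq_len(nrow(boxes)), function(i) {
      .box_prob_integrate(z_means, z_cov, boxes[i, ], n_nodes)
    }, numeric(1))
    out <- vapply(CFM_CATEGORIES, function(cc) sum(p[boxes$category == cc]),
                  numeric(1))
    return(out / sum(out))   # renormalize the tiny quadrature truncation
  }
  if (!is.null(seed)) set.seed(seed)
  e <- eigen(z_cov, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  draws <- matrix(stats::rnorm(3 * n_mc), n_mc, 3) %*% t(A)
  draws <- sweep(draws, 2, z_means, "+")
  cl <- classify_nutrition(draws[, 1], draws[, 2], draws[, 3])
  tab <- table(cl$category) / n_mc
  out <- as.numeric(tab)[match(CFM_CATEGORIES, names(tab))]
  names(out) <- CFM_CATEGORIES
  attr(out, "se") <- sqrt(out * (1 - out) / n_mc)
  out
}

# Enumerate the distinct latent mean-shift cells of a config (countries
# convolved with covariate shift distributions), with their probabilities.
.shift_cells <- function(config) {
  ctry <- config$countries
  n_c <- ctry$n_clusters * ctry$cluster_size
  cells <- data.frame(p = n_c / sum(n_c),
                      sh = ctry$shift_haz, sw = ctry$shift_whz)
  for (nm in names(config$covariates)) {
    cv <- config$covariates[[nm]]
    if (all(cv$shift_haz == 0) && all(cv$shift_whz == 0)) next
    new <- do.call(rbind, lapply(seq_along(cv$levels), function(l) {
      data.frame(p = cells$p * cv$probs[l],
                 sh = cells$sh + cv$shift_haz[l],
                 sw = cells$sw + cv$shift_whz[l])
    }))
    # collapse numerically identical cells to keep the enumeration small
    key <- paste(round(new$sh, 10), round(new$sw, 10))
    cells <- do.call(rbind, lapply(split(new, key), function(d) {
      data.frame(p = sum(d$p), sh = d$sh[1], sw = d$sw[1])
    }))
  }
  cells
}

#' Expected category prevalences for a whole simulation scenario
#'
#' Mixture of [expected_category_probabilities()] over all distinct mean-shift
#' cells of the config (countries convolved with covariate effects), weighted
#' by their population shares. This is the deterministic oracle against which
#' realized prevalences of [generate_population()] converge.
#'
#' @param config a [sim_config()].
#' @param k coupling constant of the reference fixture (measurement pathway).
#' @param n_nodes quadrature nodes per dimension.
#' @return named probability vector over [CFM_CATEGORIES].
#' @export
expected_population_prevalence <- function(config, k = NULL, n_nodes = 32) {
  cells <- .shift_cells(config)
  acc <- stats::setNames(numeric(length(CFM_CATEGORIES)), CFM_CATEGORIES)
  for (i in seq_len(nrow(cells))) {
    mom <- triple_moments(config, cells$sh[i], cells$sw[i], k = k)
    acc <- acc + cells$p[i] *
      expected_category_probabilities(mom$mean, mom$cov,
                                      method = "integration",
                                      n_nodes = n_nodes)
  }
  acc
}

#' Calibrate a latent mean shift to a target category odds ratio
#'
#' Solves by bisection (tolerance `tol` in log-OR) for the latent mean shift
#' `delta` applied along `direction` to the exposed group such that the
#' induced odds ratio of `category` versus `reference`,
#' `[P_A(delta)/P_B(delta)] / [P_A(0)/P_B(0)]`, equals `target_or` under the
#' deterministic integration oracle.
#'
#' @param target_or target odds ratio (> 0).
#' @param z_means,z_cov baseline triple moments (see [triple_moments()]).
#' @param direction length-3 shift direction in (haz, waz, whz) space for one
#'   unit of `delta`; e.g. `c(1, k, 0)` for a pure latent height shift on the
#'   measurement pathway.
#' @param category,reference the two categories whose odds are compared.
#' @param interval search interval for `delta` (default `[-5, 5]`).
#' @param tol bisection tolerance in log-OR.
#' @param n_nodes quadrature nodes.
#' @return the calibrated shift `delta`, with the achieved OR as attribute
#'   `or`.
#' @export
planted_effect_calibration <- function(target_or, z_means, z_cov, direction,
                                       category = "CUS",
                                       reference = "underweight",
                                       interval = c(-5, 5), tol = 1e-6,
                                       n_nodes = 32) {
  stopifnot(target_or > 0, length(direction) == 3)
  base <- expected_category_probabilities(z_means, z_cov, n_nodes = n_nodes)
  odds0 <- base[[category]] / base[[reference]]
  f <- function(delta) {
    p <- expected_category_probabilities(z_means + delta * direction, z_cov,
                                         n_nodes = n_nodes)
    log(p[[category]] / p[[reference]]) - log(odds0) - log(target_or)
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("no root for target OR ", target_or, " with shift in [",
         lo, ", ", hi, "]")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = min(tol, 1e-10))$root
  achieved <- target_or * exp(f(root))
  structure(root, or = achieved)
}

#' Canonical synthetic global scenario
#'
#' Six countries, one per global region, with latent mean shifts chosen so
#' the regional ordering qualitatively echoes the global epidemiology of
#' coexisting malnutrition (South/Southeast Asia worst; Latin America and
#' Central Asia best). Covariates: child sex and age band, maternal education,
#' wealth quintile and residence, with mild planted protective/adverse
#' effects. Illustrative only: no real survey is reproduced.
#'
#' @param n_per_country children per country (split over 25 clusters).
#' @param covariate_effects include the planted covariate effects
#'   (`FALSE` gives a covariate-null scenario useful for oracle comparisons).
#' @param output,seed passed to [sim_config()].
#' @return a [sim_config()].
#' @export
default_scenario <- function(n_per_country = 600, covariate_effects = TRUE,
                             output = "measurements", seed = 1) {
  n_cl <- 25L
  size <- max(1L, as.integer(ceiling(n_per_country / n_cl)))
  countries <- data.frame(
    country = c("India", "Papua New Guinea", "Nigeria",
                "Egypt", "Tajikistan", "Peru"),
    n_clusters = n_cl, cluster_size = size,
    shift_haz = c(-0.45, -0.35, -0.25, -0.10, 0.25, 0.35),
    shift_whz = c(-0.35, -0.20, -0.10, 0.05, 0.15, 0.20))
  covs <- list(
    sex_child = list(levels = c("male", "female"), probs = c(0.51, 0.49)),
    age_band = list(levels = c("0-11", "12-23", "24-35", "36-47", "48-59"),
                    probs = rep(0.2, 5)),
    maternal_education = list(levels = c("none", "primary", "secondary+"),
                              probs = c(0.3, 0.4, 0.3)),
    wealth_quintile = list(levels = paste0("Q", 1:5), probs = rep(0.2, 5)),
    residence = list(levels = c("rural", "urban"), probs = c(0.65, 0.35)))
  if (covariate_effects) {
    covs$sex_child$shift_haz <- c(0, 0.08)
    covs$sex_child$shift_whz <- c(0, 0.05)
    covs$age_band$shift_haz <- c(0.30, -0.20, -0.25, -0.05, 0.05)
    covs$age_band$shift_whz <- c(0.10, -0.15, -0.10, 0.00, 0.05)
    covs$maternal_education$shift_haz <- c(-0.15, 0, 0.20)
    covs$maternal_education$shift_whz <- c(-0.10, 0, 0.10)
    covs$wealth_quintile$shift_haz <- c(-0.20, -0.10, 0, 0.10, 0.20)
    covs$wealth_quintile$shift_whz <- c(-0.10, -0.05, 0, 0.05, 0.10)
    covs$residence$shift_haz <- c(0, 0.10)
    covs$residence$shift_whz <- c(0, 0.05)
  }
  sim_config(countries = countries, covariates = covs,
             output = output, seed = seed)
}
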