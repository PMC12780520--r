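# Chi-square screening, multinomial logistic regression, backward elimination
# and collinearity diagnostics for the CFM determinant models.

#' Pearson chi-square screening of a covariate against an outcome
#'
#' Bivariate screen on the contingency table of non-missing pairs;
#' a covariate passes the screen when `p <= alpha` (default 0.05) and is then
#' eligible for the multivariable model.
#'
#' @param data data.frame.
#' @param covariate,outcome column names of categorical variables.
#' @param alpha screening significance level.
#' @return list with `statistic`, `df`, `p_value`, `pass`, `table`.
#' @export
chisq_screen <- function(data, covariate, outcome, alpha = 0.05) {
  x <- factor(data[[covariate]])
  y <- factor(data[[outcome]])
  keep <- !is.na(x) & !is.na(y)
  tab <- table(droplevels(x[keep]), droplevels(y[keep]))
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("degenerate contingency table for ", covariate, " x ", outcome,
         " (need at least 2 rows and 2 columns)")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), pass = unname(ct$p.value) <= alpha,
       table = tab)
}

#' Build a dummy-coded design matrix with declared reference levels
#'
#' @param data data.frame holding the covariates.
#' @param covariates character vector of covariate column names (treated as
#'   factors).
#' @param refs named list/vector giving the reference level per covariate
#'   (default: first factor level).
#' @return list of class `cfm_design`: `X` (matrix with intercept), `blocks`
#'   (named list mapping covariate to its column indices in `X`), `levels`
#'   (per-covariate level sets), `refs`, `rows` (row indices of `data` kept
#'   after complete-case filtering), `n_dropped`.
#' @export
build_design <- function(data, covariates, refs = list()) {
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("covariates not in data: ", paste(miss, collapse = ", "))
  df <- data[covariates]
  for (nm in covariates) {
    f <- factor(df[[nm]])
    if (!is.null(refs[[nm]])) {
      if (!as.character(refs[[nm]]) %in% levels(f)) {
        stop("reference level '", refs[[nm]], "' not a level of ", nm)
      }
      f <- stats::relevel(f, ref = as.character(refs[[nm]]))
    }
    df[[nm]] <- f
  }
  keep <- stats::complete.cases(df)
  dfc <- droplevels(df[keep, , drop = FALSE])
  X <- stats::model.matrix(~., dfc)
  asgn <- attr(X, "assign")
  blocks <- lapply(seq_along(covariates), function(i) which(asgn == i))
  names(blocks) <- covariates
  empty <- covariates[vapply(blocks, length, 1L) == 0L]
  if (length(empty)) {
    stop("covariate(s) with a single observed level: ",
         paste(empty, collapse = ", "))
  }
  structure(list(
    X = X, blocks = blocks,
    levels = lapply(dfc, levels),
    refs = vapply(dfc, function(f) levels(f)[1L], character(1)),
    rows = which(keep), n_dropped = sum(!keep)
  ), class = "cfm_design")
}

# Multinomial log-likelihood machinery. B is p x (K-1); the reference outcome
# level carries all-zero coefficients.
.mlogit_probs <- function(X, B) {
  eta <- X %*% B
  eta <- pmin(eta, 500)           # overflow guard; probabilities saturate
  expeta <- exp(eta)
  denom <- 1 + rowSums(expeta)
  list(P = expeta / denom, denom = denom, eta = eta)
}

.mlogit_loglik <- function(X, Y, B, w, ridge = 0) {
  pr <- .mlogit_probs(X, B)
  ll <- sum(w * (rowSums(Y * pr$eta) - log(pr$denom)))
  if (ridge > 0) ll <- ll - 0.5 * ridge * sum(B^2)
  ll
}

#' Fit a multinomial logistic regression by Newton-Raphson
#'
#' Maximizes the multinomial log-likelihood over coefficients for each
#' non-reference outcome level, with step-halving whenever a Newton step would
#' decrease the log-likelihood. A two-level outcome reduces exactly to binary
#' logistic regression. Convergence when the maximum absolute score falls
#' below `tol_score` or the relative log-likelihood change falls below
#' `tol_ll`, up to `max_iter` iterations. Quasi-complete separation (any
#' coefficient diverging beyond `sep_threshold` in absolute value) triggers a
#' flagged ridge-penalized refit (penalty `1e-6`) with a warning.
#'
#' @param X design matrix including an intercept column (see
#'   [build_design()]), or a `cfm_design` object.
#' @param y outcome labels (factor or character).
#' @param ref_outcome reference outcome level (all-zero coefficients).
#' @param weights optional positive case weights (default unweighted).
#' @param blocks optional named list mapping covariate names to columns of
#'   `X`; filled automatically from a `cfm_design`.
#' @param tol_score,tol_ll,max_iter convergence controls.
#' @param sep_threshold absolute-coefficient threshold for separation.
#' @param ridge ridge penalty (0 = plain maximum likelihood).
#' @return object of class `cfm_multinom`: `coefficients` (p x K-1 matrix),
#'   `se`, `vcov`, `loglik`, `converged`, `n_iter`, `outcome_levels`,
#'   `ref_outcome`, `separation`, `blocks`, `n`.
#' @export
fit_multinomial <- function(X, y, ref_outcome = NULL, weights = NULL,
                            blocks = NULL, tol_score = 1e-8, tol_ll = 1e-10,
                            max_iter = 100, sep_threshold = 15, ridge = 0) {
  if (inherits(X, "cfm_design")) {
    if (is.null(blocks)) blocks <- X$blocks
    y <- y[X$rows]
    if (!is.null(weights)) weights <- weights[X$rows]
    X <- X$X
  }
  y <- factor(y)
  if (nlevels(y) < 2L) stop("outcome needs at least 2 levels")
  if (is.null(ref_outcome)) ref_outcome <- levels(y)[1L]
  if (!ref_outcome %in% levels(y)) {
    stop("reference outcome '", ref_outcome, "' not an outcome level")
  }
  y <- stats::relevel(y, ref = ref_outcome)
  if (any(table(y) == 0L)) stop("every outcome level needs >= 1 observation")
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights > 0))
    as.numeric(weights)
  }
  Y <- matrix(0, n, K - 1L)
  for (k in 2:K) Y[, k - 1L] <- as.numeric(y == levels(y)[k])

  B <- matrix(0, p, K - 1L,
              dimnames = list(colnames(X), levels(y)[-1L]))
  ll <- .mlogit_loglik(X, Y, B, w, ridge)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  repeat {
    iter <- iter + 1L
    pr <- .mlogit_probs(X, B)
    G <- crossprod(X, w * (Y - pr$P))
    if (ridge > 0) G <- G - ridge * B
    # stacked Hessian: block (j,l) = -X' diag(w * P_j (d_jl - P_l)) X
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (j in seq_len(K - 1L)) {
      for (l in j:(K - 1L)) {
        wjl <- w * pr$P[, j] * ((j == l) - pr$P[, l])
        blk <- crossprod(X, X * wjl)
        rj <- (j - 1L) * p + seq_len(p)
        rl <- (l - 1L) * p + seq_len(p)
        H[rj, rl] <- blk
        if (l != j) H[rl, rj] <- blk
      }
    }
    if (ridge > 0) H <- H + ridge * diag(p * (K - 1L))
    if (max(abs(G)) < tol_score) { converged <- TRUE; break }
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) {
      solve(H + 1e-10 * diag(nrow(H)), as.vector(G))
    })
    # step-halving: never accept a decrease in the (penalized) log-likelihood
    lambda <- 1
    repeat {
      Bnew <- B + lambda * matrix(step, p, K - 1L)
      llnew <- .mlogit_loglik(X, Y, Bnew, w, ridge)
      if (llnew >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    rel <- abs(llnew - ll) / (abs(ll) + 1e-300)
    B <- Bnew
    ll <- llnew
    if (rel < tol_ll) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  separation <- any(abs(B) > sep_threshold)
  if (separation && ridge == 0) {
    warning("possible complete separation (|coefficient| > ", sep_threshold,
            "); refitting with ridge penalty 1e-6")
    fit <- fit_multinomial(X, y, ref_outcome = ref_outcome, weights = weights,
                           blocks = blocks, tol_score = tol_score,
                           tol_ll = tol_ll, max_iter = max_iter,
                           sep_threshold = Inf, ridge = 1e-6)
    fit$separation <- TRUE
    return(fit)
  }

  V <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, nrow(H), ncol(H))
  })
  SE <- matrix(sqrt(pmax(diag(V), 0)), p, K - 1L,
               dimnames = dimnames(B))
  structure(list(coefficients = B, se = SE, vcov = V, loglik = ll,
                 converged = converged, n_iter = iter,
                 outcome_levels = levels(y), ref_outcome = ref_outcome,
                 separation = separation, blocks = blocks, n = n,
                 ridge = ridge),
            class = "cfm_multinom")
}

#' @export
print.cfm_multinom <- function(x, ...) {
  cat(sprintf("<cfm_multinom> %d obs, outcome levels: %s (ref %s)\n",
              x$n, paste(x$outcome_levels, collapse = ", "), x$ref_outcome))
  cat(sprintf("  logLik %.4f, %s in %d iterations%s\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' @export
logLik.cfm_multinom <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
coef.cfm_multinom <- function(object, ...) object$coefficients

# likelihood-ratio p-value for dropping one covariate block
.block_lrt <- function(data, outcome, covariates, drop, ref_outcome, refs,
                       weights, full_fit = NULL, ...) {
  fit1 <- if (is.null(full_fit)) {
    d <- build_design(data, covariates, refs)
    fit_multinomial(d, data[[outcome]], ref_outcome, weights = weights, ...)
  } else full_fit
  reduced <- setdiff(covariates, drop)
  d0 <- if (length(reduced)) build_design(data, reduced, refs) else NULL
  # align risk sets: complete cases of the FULL covariate set
  dfull <- build_design(data, covariates, refs)
  if (length(reduced)) {
    Xr <- d0$X[match(dfull$rows, d0$rows), , drop = FALSE]
    fit0 <- fit_multinomial(Xr, data[[outcome]][dfull$rows], ref_outcome,
                            weights = if (is.null(weights)) NULL else
                              weights[dfull$rows], ...)
  } else {
    Xr <- matrix(1, length(dfull$rows), 1, dimnames = list(NULL, "(Intercept)"))
    fit0 <- fit_multinomial(Xr, data[[outcome]][dfull$rows], ref_outcome,
                            weights = if (is.null(weights)) NULL else
                              weights[dfull$rows], ...)
  }
  df <- length(fit1$coefficients) - length(fit0$coefficients)
  stat <- 2 * (fit1$loglik - fit0$loglik)
  stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
}

#' Backward elimination of covariate blocks by likelihood-ratio test
#'
#' Starting from the screen-passing covariates, iteratively refits the
#' multinomial model, removing at each step the covariate block (all dummy
#' levels together, jointly across outcome equations) with the largest
#' likelihood-ratio p-value above `alpha`, until every remaining block is
#' significant at `alpha`. The elimination order and p-values are recorded.
#'
#' @param data data.frame with outcome and covariate columns.
#' @param outcome outcome column name.
#' @param covariates initial covariate set (column names).
#' @param ref_outcome reference outcome level.
#' @param alpha retention threshold (default 0.05).
#' @param refs named list of covariate reference levels.
#' @param weights optional case weights.
#' @param ... further arguments for [fit_multinomial()].
#' @return the final `cfm_multinom` fit, with extra fields `retained`,
#'   `eliminated` (data.frame of dropped covariates and their p-values, in
#'   order) and `design` (the final `cfm_design`).
#' @export
backward_eliminate <- function(data, outcome, covariates, ref_outcome = NULL,
                               alpha = 0.05, refs = list(), weights = NULL,
                               ...) {
  current <- covariates
  eliminated <- data.frame(covariate = character(), p_value = numeric())
  repeat {
    if (!length(current)) {
      warning("all covariates eliminated; returning intercept-only model")
      X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
      keep <- !is.na(data[[outcome]])
      fit <- fit_multinomial(X[keep, , drop = FALSE], data[[outcome]][keep],
                             ref_outcome,
                             weights = if (is.null(weights)) NULL else
                               weights[keep], ...)
      fit$retained <- character()
      fit$eliminated <- eliminated
      return(fit)
    }
    pvals <- vapply(current, function(cv) {
      .block_lrt(data, outcome, current, cv, ref_outcome, refs, weights, ...)
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] > alpha) {
      eliminated <- rbind(eliminated, data.frame(
        covariate = current[worst], p_value = unname(pvals[worst])))
      current <- current[-worst]
    } else {
      d <- build_design(data, current, refs)
      fit <- fit_multinomial(d, data[[outcome]], ref_outcome,
                             weights = weights, ...)
      fit$retained <- current
      fit$eliminated <- eliminated
      fit$block_p <- pvals
      fit$design <- d
      return(fit)
    }
  }
}

#' Variance inflation factors of a dummy-coded design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of column j on all other non-intercept columns plus an
#' intercept. Exactly collinear columns are reported as `Inf` and flagged,
#' not raised as an error.
#'
#' @param X design matrix (intercept column, if present, is excluded from the
#'   VIF set), or a `cfm_design`.
#' @return data.frame with columns `column`, `vif`, `aliased` (logical flag
#'   for exact collinearity).
#' @export
vif_diagnostics <- function(X) {
  if (inherits(X, "cfm_design")) X <- X$X
  cols <- setdiff(colnames(X), "(Intercept)")
  if (length(cols) < 2L) stop("VIF needs at least 2 non-intercept columns")
  if (nrow(X) <= ncol(X)) stop("VIF needs more rows than columns")
  out <- data.frame(column = cols, vif = NA_real_, aliased = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    yj <- X[, cols[i]]
    Z <- cbind(1, X[, setdiff(cols, cols[i]), drop = FALSE])
    fit <- stats::lm.fit(Z, yj)
    tss <- sum((yj - mean(yj))^2)
    rss <- sum(fit$residuals^2)
    if (tss <= 0 || rss / tss < 1e-12) {
      out$vif[i] <- Inf
      out$aliased[i] <- TRUE
    } else {
      out$vif[i] <- tss / rss
    }
  }
  out
}

#' Odds-ratio table from fitted models
#'
#' Renders one row per (outcome level, covariate level): the odds ratio
#' `exp(beta)` with a Wald 95% CI `exp(beta +/- 1.96 se)`, a significance
#' star when the CI excludes 1, and explicit reference rows (`OR = 1`, no CI)
#' for each covariate's reference level.
#'
#' @param models a single `cfm_multinom` fit from [backward_eliminate()] (or
#'   [fit_multinomial()] on a `cfm_design`), or a named list of them; names
#'   become the `model` tag.
#' @param conf confidence level.
#' @return data.frame with columns `model`, `outcome`, `covariate`, `level`,
#'   `or`, `ci_low`, `ci_high`, `significant`, `reference`.
#' @export
or_table <- function(models, conf = 0.95) {
  if (inherits(models, "cfm_multinom")) models <- list(model = models)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- list()
  for (tag in names(models)) {
    fit <- models[[tag]]
    des <- fit$design
    if (is.null(fit$blocks)) next
    for (oc in setdiff(fit$outcome_levels, fit$ref_outcome)) {
      for (cv in names(fit$blocks)) {
        cols <- fit$blocks[[cv]]
        if (!length(cols)) next
        lv <- if (!is.null(des)) des$levels[[cv]] else NULL
        ref_lv <- if (!is.null(lv)) lv[1L] else "(ref)"
        rows[[length(rows) + 1L]] <- data.frame(
          model = tag, outcome = oc, covariate = cv, level = ref_lv,
          or = 1, ci_low = NA_real_, ci_high = NA_real_,
          significant = FALSE, reference = TRUE, stringsAsFactors = FALSE)
        for (j in seq_along(cols)) {
          b <- fit$coefficients[cols[j], oc]
          s <- fit$se[cols[j], oc]
          lvl <- if (!is.null(lv)) lv[j + 1L] else
            colnames(fit$coefficients)[cols[j]]
          lo <- exp(b - z * s); hi <- exp(b + z * s)
          rows[[length(rows) + 1L]] <- data.frame(
            model = tag, outcome = oc, covariate = cv, level = lvl,
            or = exp(b), ci_low = lo, ci_high = hi,
            significant = is.finite(lo) && is.finite(hi) && (lo > 1 | hi < 1),
            reference = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
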