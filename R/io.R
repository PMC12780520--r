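# Readers/writers for the pipeline's tabular formats, the DHS child-recode
# dialect, and the end-to-end pipeline driver.

#' Column mapping from a source table to canonical field names
#'
#' Canonical fields: `id`, `age_months`, `sex`, `weight_kg`, `lenhei_cm`,
#' `measured_recumbent`, `haz`, `waz`, `whz`, `weight` (sampling weight),
#' `cluster`, `stratum`, `country`, plus any number of covariate columns
#' (passed through unchanged). Two dialects are supported:
#' \describe{
#'   \item{`generic`}{values taken as-is (z-scores in SD units, sampling
#'     weight on its own scale, sex as `male`/`female` or `1`/`2`).}
#'   \item{`dhs_kr`}{the DHS child-recode storage conventions: z-scores are
#'     integers times 100 with flag codes `>= 9990` meaning missing, the
#'     sampling weight is stored times 1,000,000, and sex is coded 1 = male,
#'     2 = female. The default mapping uses the standard recode variables
#'     (`hw1`, `b4`, `hw70`-`hw72`, `v005`, `v001`, `v022`).}
#' }
#'
#' @param ... named canonical-field = source-column pairs.
#' @param dialect `"generic"` or `"dhs_kr"`.
#' @param covariates character vector of source covariate columns to carry.
#' @return object of class `column_map`.
#' @export
column_map <- function(..., dialect = c("generic", "dhs_kr"),
                       covariates = character()) {
  dialect <- match.arg(dialect)
  map <- list(...)
  if (dialect == "dhs_kr") {
    defaults <- list(age_months = "hw1", sex = "b4", haz = "hw70",
                     waz = "hw71", whz = "hw72", weight = "v005",
                     cluster = "v001", stratum = "v022", country = "country")
    for (nm in names(defaults)) {
      if (is.null(map[[nm]])) map[[nm]] <- defaults[[nm]]
    }
  }
  known <- c("id", "age_months", "sex", "weight_kg", "lenhei_cm",
             "measured_recumbent", "haz", "waz", "whz", "weight",
             "cluster", "stratum", "country")
  bad <- setdiff(names(map), known)
  if (length(bad)) stop("unknown canonical field(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(names(map))) stop("duplicate canonical field names")
  structure(list(map = map, dialect = dialect, covariates = covariates),
            class = "column_map")
}

.decode_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  out
}

.num_soft <- function(x) suppressWarnings(as.numeric(x))

#' Read child records from a delimited file
#'
#' Applies the column mapping and dialect decoding, keeps children aged 0-59
#' completed months, and emits one disposition per input row:
#' `analyzed`, `excluded_age` (age missing or outside 0-59 months), or
#' `excluded_incomplete` (no anthropometric information usable for any
#' index). Unparseable numeric cells become missing values and feed the
#' incompleteness rule; they never abort the read.
#'
#' @param path CSV file with a header row.
#' @param colmap a [column_map()].
#' @return list with `records` (canonical data.frame, all rows) and
#'   `dispositions` (data.frame `id`, `status`, `detail`). Downstream stages
#'   only analyze rows whose status is `analyzed`; the plausibility filter
#'   later refines some of them to `excluded_outlier`.
#' @export
read_children <- function(path, colmap) {
  stopifnot(inherits(colmap, "column_map"))
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- unlist(colmap$map, use.names = FALSE)
  miss <- setdiff(c(need, colmap$covariates), names(raw))
  if (length(miss)) {
    stop("mapped column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  }
  n <- nrow(raw)
  rec <- data.frame(id = if (!is.null(colmap$map$id)) raw[[colmap$map$id]]
                    else seq_len(n))
  getcol <- function(field) {
    src <- colmap$map[[field]]
    if (is.null(src)) NULL else raw[[src]]
  }
  num_fields <- c("age_months", "weight_kg", "lenhei_cm", "haz", "waz",
                  "whz", "weight")
  for (f in num_fields) {
    v <- getcol(f)
    if (!is.null(v)) rec[[f]] <- .num_soft(v)
  }
  if (!is.null(getcol("sex"))) rec$sex <- .decode_sex(getcol("sex"))
  if (!is.null(getcol("measured_recumbent"))) {
    rec$measured_recumbent <- as.logical(getcol("measured_recumbent"))
  }
  for (f in c("cluster", "stratum", "country")) {
    v <- getcol(f)
    if (!is.null(v)) rec[[f]] <- as.character(v)
  }
  for (cv in colmap$covariates) rec[[cv]] <- raw[[cv]]

  if (colmap$dialect == "dhs_kr") {
    for (f in c("haz", "waz", "whz")) {
      if (!is.null(rec[[f]])) {
        rec[[f]][!is.na(rec[[f]]) & rec[[f]] >= 9990] <- NA
        rec[[f]] <- rec[[f]] / 100
      }
    }
    if (!is.null(rec$weight)) rec$weight <- rec$weight / 1e6
  }

  has_z <- Reduce(`|`, lapply(c("haz", "waz", "whz"), function(f) {
    if (is.null(rec[[f]])) rep(FALSE, n) else !is.na(rec[[f]])
  }))
  has_raw <- (!is.null(rec$age_months) & !is.null(rec$sex)) &&
    (!is.null(rec$weight_kg) || !is.null(rec$lenhei_cm))
  has_meas <- if (isTRUE(has_raw)) {
    !is.na(rec$age_months) & !is.na(rec$sex) &
      ((if (is.null(rec$weight_kg)) FALSE else !is.na(rec$weight_kg)) |
         (if (is.null(rec$lenhei_cm)) FALSE else !is.na(rec$lenhei_cm)))
  } else rep(FALSE, n)

  age_ok <- if (is.null(rec$age_months)) rep(TRUE, n) else
    !is.na(rec$age_months) & rec$age_months >= 0 & rec$age_months < 60
  status <- rep("analyzed", n)
  detail <- rep("", n)
  i <- !age_ok
  status[i] <- "excluded_age"
  detail[i] <- "age missing or outside 0-59 months"
  i <- age_ok & !(has_z | has_meas)
  status[i] <- "excluded_incomplete"
  detail[i] <- "no usable anthropometry"
  list(records = rec,
       dispositions = data.frame(id = rec$id, status = status,
                                 detail = detail, stringsAsFactors = FALSE))
}

#' Fit the standard pair of CFM determinant models
#'
#' The composite undernutrition types are modeled against an underweight
#' reference in one multinomial regression (outcome levels underweight, CUW,
#' CUS, CUWS; risk set = children in those categories), and CSO against a
#' stunted reference in a binary regression (risk set = stunting and CSO
#' categories). Covariates are first screened by Pearson chi-square
#' (`p <= alpha`), then reduced by [backward_eliminate()].
#'
#' @param data classified data.frame (column `category` plus covariates).
#' @param covariates covariate column names.
#' @param alpha significance level for screening and elimination.
#' @param refs named list of covariate reference levels.
#' @param weights optional case weights (aligned to `data` rows).
#' @return list with elements `undernutrition` and `cso` (each a
#'   `cfm_multinom` fit with elimination records, or `NULL` when its risk set
#'   is degenerate), `screen` (screening p-values per model), and `table`
#'   (combined [or_table()]).
#' @export
cfm_models <- function(data, covariates, alpha = 0.05, refs = list(),
                       weights = NULL) {
  fits <- list()
  screen <- list()
  specs <- list(
    undernutrition = list(levels = c("underweight", "CUW", "CUS", "CUWS"),
                          ref = "underweight"),
    cso = list(levels = c("stunting", "CSO"), ref = "stunting"))
  for (tag in names(specs)) {
    sp <- specs[[tag]]
    idx <- which(!is.na(data$category) & data$category %in% sp$levels)
    d <- data[idx, , drop = FALSE]
    d$category <- factor(as.character(d$category), levels = sp$levels)
    if (length(unique(d$category[!is.na(d$category)])) < 2L) {
      fits[[tag]] <- NULL
      screen[[tag]] <- NULL
      next
    }
    scr <- vapply(covariates, function(cv) {
      tryCatch(chisq_screen(d, cv, "category", alpha)$p_value,
               error = function(e) NA_real_)
    }, numeric(1))
    screen[[tag]] <- scr
    keep <- names(scr)[!is.na(scr) & scr <= alpha]
    if (!length(keep)) {
      warning("no covariate passed screening for model '", tag, "'")
      fits[[tag]] <- NULL
      next
    }
    w <- if (is.null(weights)) NULL else weights[idx]
    fits[[tag]] <- backward_eliminate(d, "category", keep,
                                      ref_outcome = sp$ref, alpha = alpha,
                                      refs = refs, weights = w)
  }
  tab <- if (length(fits)) or_table(Filter(Negate(is.null), fits)) else NULL
  list(undernutrition = fits$undernutrition, cso = fits$cso,
       screen = screen, table = tab)
}

#' Write pipeline reports to a directory
#'
#' Writes the prevalence report, the odds-ratio table and the disposition
#' table as CSV with stable column order, plus a JSON run summary (counts per
#' disposition, seed, package version, config echo) and a plain-text log.
#' Output is deterministic for identical inputs.
#'
#' @param prevalence prevalence report data.frame (or `NULL`).
#' @param ors odds-ratio table data.frame (or `NULL`; an empty table yields a
#'   header-only CSV).
#' @param dispositions disposition data.frame (or `NULL`).
#' @param out_dir output directory (created if absent).
#' @param summary named list merged into the JSON run summary.
#' @return invisibly, the vector of files written.
#' @export
write_reports <- function(prevalence = NULL, ors = NULL, dispositions = NULL,
                          out_dir, summary = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  files <- character()
  log_lines <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    log_lines <<- c(log_lines, sprintf("wrote %s (%d rows)", name, nrow(df)))
  }
  if (!is.null(prevalence)) wr(prevalence, "prevalence.csv")
  if (!is.null(ors)) wr(ors, "or_table.csv")
  if (!is.null(dispositions)) wr(dispositions, "dispositions.csv")
  sm <- c(list(package_version = as.character(utils::packageVersion("cfmtools"))),
          summary)
  if (!is.null(dispositions)) {
    sm$disposition_counts <- as.list(table(dispositions$status))
    sm$n_records <- nrow(dispositions)
  }
  p <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(sm, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, p)
  p <- file.path(out_dir, "run.log")
  writeLines(log_lines, p)
  files <- c(files, p)
  invisible(files)
}

#' Run the full analysis pipeline
#'
#' Chains read (or in-memory input) -> z-score computation (when raw
#' measurements and references are available) -> plausibility filtering ->
#' nine-way classification -> weighted prevalence aggregation -> optional
#' determinant models, and optionally writes reports. Any stage failure is an
#' error carrying the stage name.
#'
#' @param config a named list, or the path of a YAML file with the same
#'   structure. Recognized fields: `input` (CSV path) or `data` (data.frame),
#'   `colmap` (a [column_map()] or list of arguments for it), `refs_dir`
#'   (directory of reference CSVs for [load_reference_set()]) or `refs` (a
#'   `reference_set`), `stages` (subset of `zscore`, `classify`, `prevalence`,
#'   `model`; default all applicable), `levels`, `ci_method`, `pooling`,
#'   `model` (list: `covariates`, `alpha`, `refs`), `out_dir`, `seed`.
#' @return invisibly, a list with `records`, `dispositions`, `prevalence`,
#'   `models`, `or_table`, and the files written (if any).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(config$seed)) set.seed(config$seed)

  stages <- config$stages %||% c("zscore", "classify", "prevalence", "model")

  # --- read ---------------------------------------------------------------
  if (!is.null(config$data)) {
    rec <- config$data
    disp <- data.frame(id = rec$id %||% seq_len(nrow(rec)),
                       status = "analyzed", detail = "",
                       stringsAsFactors = FALSE)
  } else if (!is.null(config$input)) {
    cm <- config$colmap
    if (!inherits(cm, "column_map")) cm <- do.call(column_map, as.list(cm))
    rd <- read_children(config$input, cm)
    rec <- rd$records
    disp <- rd$dispositions
  } else {
    stop("pipeline config must name an 'input' file or provide 'data'")
  }
  live <- disp$status == "analyzed"

  # --- zscore -------------------------------------------------------------
  refs <- config$refs
  if (is.null(refs) && !is.null(config$refs_dir)) {
    refs <- load_reference_set(config$refs_dir)
  }
  need_z <- is.null(rec$haz) || is.null(rec$waz) || is.null(rec$whz) ||
    any(live & is.na(rec$haz) & is.na(rec$waz) & is.na(rec$whz))
  if ("zscore" %in% stages && !is.null(refs) &&
      !is.null(rec$weight_kg) && !is.null(rec$lenhei_cm) && need_z) {
    zz <- compute_indices(rec[live, , drop = FALSE], refs)
    for (f in c("haz", "waz", "whz")) {
      if (is.null(rec[[f]])) rec[[f]] <- NA_real_
      rec[[f]][live] <- zz[[f]]
    }
  }
  for (f in c("haz", "waz", "whz")) {
    if (is.null(rec[[f]])) rec[[f]] <- NA_real_
  }

  # --- plausibility + classify --------------------------------------------
  pl <- plausibility_filter(rec$haz, rec$waz, rec$whz)
  out_i <- live & !pl$retained
  disp$status[out_i] <- "excluded_outlier"
  disp$detail[out_i] <- pl$violated[out_i]
  live <- disp$status == "analyzed"

  cls <- classify_nutrition(rec$haz, rec$waz, rec$whz)
  inc_i <- live & cls$incomplete
  disp$status[inc_i] <- "excluded_incomplete"
  disp$detail[inc_i] <- "incomplete anthropometry"
  live <- disp$status == "analyzed"
  rec$category <- cls$category
  rec$category[!live] <- NA
  rec$conflict_flag <- cls$conflict_flag

  prevalence <- NULL
  if ("prevalence" %in% stages) {
    if (is.null(rec$country)) stop("prevalence stage requires a country column")
    if (is.null(rec$weight)) rec$weight <- 1
    prevalence <- aggregate_prevalence(
      rec[live, , drop = FALSE],
      levels = config$levels %||% c("national", "regional", "global"),
      pooling = config$pooling %||% "sample_size",
      pop_shares = config$pop_shares,
      ci_method = config$ci_method %||% "wilson",
      region_lookup = config$region_lookup)
  }

  models <- NULL
  ortab <- NULL
  if ("model" %in% stages && !is.null(config$model)) {
    mc <- config$model
    models <- cfm_models(rec[live, , drop = FALSE],
                         covariates = mc$covariates,
                         alpha = mc$alpha %||% 0.05,
                         refs = mc$refs %||% list(),
                         weights = if (isTRUE(mc$weighted)) rec$weight[live]
                         else NULL)
    ortab <- models$table
  }

  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- write_reports(prevalence, ortab, disp, config$out_dir,
                           summary = list(seed = config$seed,
                                          stages = stages))
  }
  invisible(list(records = rec, dispositions = disp, prevalence = prevalence,
                 models = models, or_table = ortab, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
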