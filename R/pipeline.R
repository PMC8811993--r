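#' Classify anti-VEGF treatment response
#'
#' An eye is *refractory* when it required at least 5 anti-VEGF injections
#' in the first treatment year, or when macular edema persisted after the 3
#' monthly loading injections (either clause suffices); otherwise it is
#' *responsive*. Only treated eyes (>= 1 injection) are classifiable.
#'
#' @param injections_year1 integer count of injections in year one (>= 1).
#' @param persistent_after_3_monthly logical flag.
#' @return character vector, `"responsive"` or `"refractory"`.
#' @examples
#' classify_response(4, FALSE)  # responsive
#' classify_response(5, FALSE)  # refractory
#' classify_response(3, TRUE)   # refractory
#' @export
classify_response <- function(injections_year1,
                              persistent_after_3_monthly = FALSE) {
  if (any(injections_year1 < 1)) {
    stop("classification requires a treated eye (injections_year1 >= 1)")
  }
  ifelse(injections_year1 >= 5 | persistent_after_3_monthly,
         "refractory", "responsive")
}

#' Convert a Snellen fraction to logMAR
#'
#' @param snellen_fraction visual acuity as a decimal fraction (e.g. 20/40
#'   = 0.5); must be positive.
#' @return logMAR, `-log10(fraction)`.
#' @export
snellen_to_logmar <- function(snellen_fraction) {
  if (any(snellen_fraction <= 0)) stop("Snellen fraction must be positive")
  -log10(snellen_fraction)
}

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` draws a cohort from [cohort_params()];
#'   `"images"` quantifies frame pairs listed in a manifest CSV and joins a
#'   clinical table.
#' @param cohort a [cohort_params()] (synthetic mode).
#' @param quantify a [quantify_config()] (image mode).
#' @param manifest_csv CSV with columns `eye_id, path_1min, path_5min,
#'   fovea_row, fovea_col` (image mode).
#' @param clinical_csv CSV of clinical covariates keyed by `eye_id` (image
#'   mode), with at least `injections_year1` and
#'   `persistent_after_3_monthly`.
#' @param p_stay Wald stay threshold for the stepwise model.
#' @param seed integer seed for all randomness in the run.
#' @param out_dir run directory for the emitted tables.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "images"),
                       cohort = cohort_params(),
                       quantify = quantify_config(),
                       manifest_csv = NULL, clinical_csv = NULL,
                       p_stay = 0.05, seed = 1L, out_dir = tempfile("faleak-run-")) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, cohort = cohort, quantify = quantify,
              manifest_csv = manifest_csv, clinical_csv = clinical_csv,
              p_stay = p_stay, seed = as.integer(seed), out_dir = out_dir)
  if (mode == "synthetic" && !inherits(cohort, "cohort_params")) {
    stop("synthetic mode needs a cohort_params() object")
  }
  if (mode == "images" &&
      (is.null(manifest_csv) || is.null(clinical_csv))) {
    stop("image mode needs manifest_csv and clinical_csv")
  }
  if (p_stay <= 0 || p_stay >= 1) stop("p_stay must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Assembles per-eye records (synthetic cohort, or image quantification
#' joined to a clinical table), classifies each eye with
#' [classify_response()], and writes to the run directory: `cohort.csv`
#' (all records), `table1.csv` (group comparisons), `table2.csv` (ROC/AUC
#' with DeLong contrasts against pre-treatment CRT), `stepwise.csv` (the
#' backward-selection trace and final odds ratios), `run_summary.json` and
#' `provenance.json`. In image mode, eyes whose quantification fails are
#' logged and skipped; the run aborts when more than 20% of eyes fail.
#'
#' Output formatting is fixed (p-values to 3 decimals with `<0.001` below
#' that, scores to 1 decimal, AUCs to 3), so a given config + seed yields
#' byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `cohort`, `table1`, `table2`, `stepwise`,
#'   `summary` and the output `dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  failures <- character()
  if (config$mode == "synthetic") {
    cp <- config$cohort
    cp$seed <- config$seed
    cohort <- generate_cohort(cp)
  } else {
    cohort <- quantify_manifest(config, function(id, msg) {
      failures <<- c(failures, paste0(id, ": ", msg))
    })
  }
  if (nrow(cohort) == 0L) stop("empty input: no eyes to analyze")

  cohort$group <- classify_response(cohort$injections_year1,
                                    cohort$persistent_after_3_monthly)
  n <- nrow(cohort)
  n_resp <- sum(cohort$group == "responsive")
  if (n_resp < 2L || n - n_resp < 2L) {
    stop("degenerate grouping: need >= 2 eyes per response group")
  }

  rep_tabs <- make_report(cohort, p_stay = config$p_stay)

  summary <- list(
    n_eyes = n,
    n_responsive = n_resp,
    n_refractory = n - n_resp,
    pct_responsive = round(100 * n_resp / n),
    n_failed = length(failures),
    failed_eyes = failures
  )

  write_fixed_csv(format_cohort(cohort), file.path(config$out_dir, "cohort.csv"))
  write_fixed_csv(rep_tabs$table1, file.path(config$out_dir, "table1.csv"))
  write_fixed_csv(rep_tabs$table2, file.path(config$out_dir, "table2.csv"))
  write_fixed_csv(format_stepwise(rep_tabs$stepwise),
                  file.path(config$out_dir, "stepwise.csv"))
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(
    package = "faleak",
    version = as.character(utils::packageVersion("faleak")),
    seed = config$seed,
    config_hash = config_hash(config),
    mode = config$mode,
    timepoints_min = c(1, 5),
    threshold_dialect = if (isTRUE(config$quantify$shared_threshold))
      "intermeans-default/per-stack" else "intermeans-default/per-frame",
    rolling_ball = "shrink-smooth-roll-expand, light-background off",
    delong_ci_scale = "normal (clipped)",
    mm_note = "parafoveal 120 px ~ 3.0 mm, perifoveal 240 px ~ 6.0 mm (nominal study equivalence, metadata only)"
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, table1 = rep_tabs$table1,
                 table2 = rep_tabs$table2, stepwise = rep_tabs$stepwise,
                 summary = summary, dir = config$out_dir))
}

quantify_manifest <- function(config, on_fail) {
  manifest <- utils::read.csv(config$manifest_csv, stringsAsFactors = FALSE)
  clinical <- utils::read.csv(config$clinical_csv, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L) stop("empty input: manifest lists no eyes")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    tryCatch({
      pair <- structure(list(
        frame_1min = read_gray(m$path_1min),
        frame_5min = read_gray(m$path_5min),
        fovea = c(m$fovea_row, m$fovea_col),
        eye_id = m$eye_id
      ), class = "fa_pair")
      res <- quantify_eye(pair, config$quantify, grader_id = "averaged")
      data.frame(eye_id = m$eye_id,
                 parafoveal_mgv = res$parafoveal_mgv,
                 perifoveal_mgv = res$perifoveal_mgv,
                 threshold_1min = res$threshold_1min,
                 threshold_5min = res$threshold_5min,
                 alignment_rotation = res$alignment$rotation,
                 alignment_dy = res$alignment$translation[1],
                 alignment_dx = res$alignment$translation[2],
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      on_fail(m$eye_id, conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (mean(!ok) > 0.2) {
    stop("more than 20% of eyes failed quantification (",
         sum(!ok), " of ", length(ok), ")")
  }
  scores <- do.call(rbind, rows[ok])
  merge(scores, clinical, by = "eye_id", sort = TRUE)
}

#' Build the group-comparison and ROC report tables
#'
#' `table1` compares every demographic, clinical and leakage variable
#' between response groups with the matched test — pooled t-test for
#' continuous variables, uncorrected chi-square for categorical ones —
#' displaying `mean +/- sd` or `a : b` counts per group. `table2` gives
#' each quantitative predictor's AUC with DeLong 95% CI and the paired
#' DeLong p against the pre-treatment CRT reference. `stepwise` is the
#' backward logistic selection over the baseline predictors that differ at
#' `p_stay` in table 1.
#'
#' @param cohort data.frame of eye records with a `group` column.
#' @param p_stay screening/stay threshold for the multivariate model.
#' @return list with `table1`, `table2` (data.frames) and `stepwise` (a
#'   `selection_trace`).
#' @export
make_report <- function(cohort, p_stay = 0.05) {
  g <- cohort$group
  if (sum(g == "responsive") < 2L || sum(g == "refractory") < 2L) {
    stop("degenerate group: need >= 2 eyes per group")
  }
  resp <- cohort[g == "responsive", ]
  refr <- cohort[g == "refractory", ]

  cont_vars <- c(age = "Age",
                 followup_months = "Follow-up duration (months)",
                 injections_year1 = "Anti-VEGF injections in first year",
                 logmar_baseline = "Baseline logMAR BCVA",
                 logmar_1yr = "logMAR BCVA at 1 year",
                 crt_pre = "Pre-treatment CRT (um)",
                 crt_best_post = "Post-treatment best CRT (um)",
                 crt_1yr = "CRT at 1 year (um)",
                 parafoveal_mgv = "Mean gray value, parafoveal region",
                 perifoveal_mgv = "Mean gray value, perifoveal region")
  cat_vars <- list(
    laterality = list(label = "Eye (OD : OS)", level = "OD"),
    sex = list(label = "Sex (male : female)", level = "M"),
    brvo_type = list(label = "BRVO type (major : macular)", level = "major"),
    edema_cystoid = list(label = "Cystoid macular edema (yes : no)", level = TRUE),
    edema_diffuse = list(label = "Diffuse retinal thickening (yes : no)", level = TRUE),
    edema_serous = list(label = "Serous retinal detachment (yes : no)", level = TRUE)
  )

  rows <- list()
  for (v in names(cont_vars)) {
    if (!v %in% names(cohort)) next
    tt <- two_sample_t(resp[[v]], refr[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = cont_vars[[v]],
      all = msd(cohort[[v]]), responsive = msd(resp[[v]]),
      refractory = msd(refr[[v]]),
      test = "t", p = format_p(tt$p), stringsAsFactors = FALSE
    )
  }
  for (v in names(cat_vars)) {
    if (!v %in% names(cohort)) next
    lv <- cat_vars[[v]]$level
    tab <- rbind(
      c(sum(resp[[v]] == lv), sum(resp[[v]] != lv)),
      c(sum(refr[[v]] == lv), sum(refr[[v]] != lv))
    )
    p <- tryCatch(chi_square_2x2(t(tab))$p, error = function(e) NA_real_)
    cnt <- function(d) paste0(sum(d[[v]] == lv), " : ", sum(d[[v]] != lv))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = cat_vars[[v]]$label,
      all = cnt(cohort), responsive = cnt(resp), refractory = cnt(refr),
      test = "chi-square", p = format_p(p), stringsAsFactors = FALSE
    )
  }
  table1 <- do.call(rbind, rows)

  predictors <- c(crt_pre = "Pre-treatment CRT (um)",
                  crt_best_post = "Post-treatment best CRT (um)",
                  parafoveal_mgv = "Mean gray value, parafoveal region",
                  perifoveal_mgv = "Mean gray value, perifoveal region")
  predictors <- predictors[names(predictors) %in% names(cohort)]
  y <- as.integer(g == "refractory")
  ref_scores <- cohort[["crt_pre"]]
  t2 <- lapply(names(predictors), function(v) {
    dl <- delong_variance_and_ci(cohort[[v]], y)
    p_ref <- if (v == "crt_pre") {
      "reference"
    } else {
      format_p(delong_paired_test(cohort[[v]], ref_scores, y)$p)
    }
    data.frame(predictor = predictors[[v]],
               auc = sprintf("%.3f", dl$auc),
               ci95 = sprintf("%.3f - %.3f", dl$ci95[1], dl$ci95[2]),
               p_vs_crt_pre = p_ref, stringsAsFactors = FALSE)
  })
  table2 <- do.call(rbind, t2)

  base_pred <- setdiff(names(predictors), "crt_best_post")
  screened <- base_pred[vapply(base_pred, function(v) {
    two_sample_t(resp[[v]], refr[[v]])$p < p_stay
  }, logical(1))]
  stepwise <- if (length(screened)) {
    backward_stepwise_logistic(cohort[screened], y, p_stay = p_stay)
  } else {
    structure(list(trace = data.frame(step = integer(),
                                      variable_removed = character(),
                                      p_at_removal = numeric()),
                   final = data.frame(variable = character(), coef = numeric(),
                                      or = numeric(), or_lo = numeric(),
                                      or_hi = numeric(), p = numeric()),
                   separated = FALSE, model = NULL),
              class = "selection_trace")
  }
  list(table1 = table1, table2 = table2, stepwise = stepwise)
}

msd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))

format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}

format_cohort <- function(cohort) {
  out <- cohort
  num <- vapply(out, is.numeric, logical(1))
  for (v in names(out)[num]) {
    out[[v]] <- ifelse(abs(out[[v]] - round(out[[v]])) < 1e-9,
                       sprintf("%d", as.integer(round(out[[v]]))),
                       sprintf("%.1f", out[[v]]))
  }
  out
}

format_stepwise <- function(sw) {
  fin <- sw$final
  data.frame(
    section = c(rep("removed", nrow(sw$trace)), rep("final", nrow(fin))),
    step = c(sw$trace$step, rep(NA_integer_, nrow(fin))),
    variable = c(sw$trace$variable_removed, fin$variable),
    p = vapply(c(sw$trace$p_at_removal, fin$p), format_p, character(1)),
    odds_ratio = c(rep("", nrow(sw$trace)),
                   sprintf("%.3f", fin$or)),
    or_ci95 = c(rep("", nrow(sw$trace)),
                ifelse(is.na(fin$or_lo), "",
                       sprintf("%.3f - %.3f", fin$or_lo, fin$or_hi))),
    stringsAsFactors = FALSE
  )
}

write_fixed_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Stable FNV-1a hash of the JSON-serialized config, for provenance records.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_all(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}
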