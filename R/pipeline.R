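#' Pipeline run configuration
#'
#' A run consumes exactly one of: real inputs (a directory of
#' `<id>_volume.nii.gz` / `<id>_mask.nii.gz` pairs plus a survival CSV) or a
#' synthetic [cohort_spec]. Everything downstream -- scales, screening rule,
#' endpoints, output location, seed -- lives here so a run is fully
#' reproducible from its config.
#'
#' @param input_dir directory of NIfTI volume/mask pairs (real-input mode).
#' @param survival_csv survival table CSV (real-input mode).
#' @param cohort a [cohort_spec] (synthetic mode).
#' @param ssf_list spatial scales in mm.
#' @param screen_p ROC-screen p-value threshold feeding stage 2
#'   (default 0.05).
#' @param endpoints survival endpoints for stage 2, subset of
#'   `c("os", "pfs")`.
#' @param pooling observation pooling for feature extraction; see
#'   [extract_feature_table].
#' @param min_group_frac group-size floor for the cut-off search.
#' @param out_dir output directory (default a tempdir).
#' @param seed integer seed overriding the cohort spec's.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, survival_csv = NULL, cohort = NULL,
                       ssf_list = c(0, 2, 3, 4, 5, 6), screen_p = 0.05,
                       endpoints = c("os", "pfs"),
                       pooling = c("volumetric", "slice_mean"),
                       min_group_frac = 0.1,
                       out_dir = tempfile("filtrad_run_"), seed = NULL) {
  real_mode <- !is.null(input_dir) || !is.null(survival_csv)
  if (real_mode && !is.null(cohort)) {
    stop("config must name real inputs OR a cohort spec, not both",
         call. = FALSE)
  }
  if (!real_mode && is.null(cohort)) {
    stop("config names neither real inputs nor a cohort spec", call. = FALSE)
  }
  if (real_mode && (is.null(input_dir) || is.null(survival_csv))) {
    stop("real-input mode needs both input_dir and survival_csv", call. = FALSE)
  }
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_spec"))
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
  }
  endpoints <- match.arg(endpoints, c("os", "pfs"), several.ok = TRUE)
  pooling <- match.arg(pooling)
  structure(
    list(
      input_dir = input_dir, survival_csv = survival_csv, cohort = cohort,
      ssf_list = as.numeric(ssf_list), screen_p = screen_p,
      endpoints = endpoints, pooling = pooling,
      min_group_frac = min_group_frac,
      out_dir = out_dir, seed = seed
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Top-level keys mirror [run_config]; a `cohort` mapping is passed to
#' [cohort_spec] and its optional `phantom` sub-mapping to [phantom_spec].
#'
#' @param path YAML or JSON config file.
#' @param seed optional seed overriding the file.
#' @param out_dir optional output directory overriding the file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, seed = NULL, out_dir = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    cargs <- raw$cohort
    if (!is.null(cargs$phantom)) {
      cargs$phantom <- do.call(phantom_spec, cargs$phantom)
    }
    cohort <- do.call(cohort_spec, cargs)
  }
  args <- raw[setdiff(names(raw), "cohort")]
  args$cohort <- cohort
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(run_config, args)
}

pipeline_log <- function(level, fmt, ..., log_file = NULL) {
  line <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
}

resolve_inputs <- function(config) {
  if (!is.null(config$cohort)) {
    coh <- generate_cohort(config$cohort)
    ids <- vapply(coh$volumes, `[[`, character(1L), "patient_id")
    return(list(
      ids = ids,
      get_volume = function(i) coh$volumes[[i]],
      get_mask = function(i, vol) coh$masks[[i]],
      survival = coh$survival,
      cohort = coh
    ))
  }
  vols <- list.files(config$input_dir, pattern = "_volume\\.nii(\\.gz)?$",
                     full.names = TRUE)
  if (!length(vols)) {
    stop("no *_volume.nii[.gz] files under ", config$input_dir, call. = FALSE)
  }
  ids <- sub("_volume\\.nii(\\.gz)?$", "", basename(vols))
  masks <- file.path(config$input_dir,
                     sub("_volume\\.", "_mask.", basename(vols)))
  list(
    ids = ids,
    get_volume = function(i) read_volume(vols[i], patient_id = ids[i]),
    get_mask = function(i, vol) read_mask(masks[i], vol),
    survival = read_survival_table(config$survival_csv),
    cohort = NULL
  )
}

#' Extract the feature table for every patient in a run
#'
#' One row per (patient, SSF). A failure for one patient (corrupt file,
#' incongruent mask, ...) is logged with its reason and that patient is
#' dropped; it never aborts the whole extraction.
#'
#' @param config a [run_config].
#' @param log_file optional path appended with progress lines.
#' @return a `feature_table`; attribute `failures` is a named character
#'   vector of per-patient failure reasons.
#' @export
run_extract <- function(config, log_file = NULL) {
  stopifnot(inherits(config, "run_config"))
  inputs <- resolve_inputs(config)
  extract_many(inputs, config$ssf_list, config$pooling, log_file = log_file)
}

extract_many <- function(inputs, ssf_list, pooling = "volumetric",
                         log_file = NULL) {
  rows <- list()
  failures <- character(0L)
  for (i in seq_along(inputs$ids)) {
    id <- inputs$ids[i]
    res <- tryCatch({
      vol <- inputs$get_volume(i)
      msk <- inputs$get_mask(i, vol)
      extract_feature_table(vol, msk, ssf_list, pooling = pooling)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      pipeline_log("WARN", "patient %s failed: %s", id, failures[id],
                   log_file = log_file)
    } else {
      rows[[id]] <- res
      pipeline_log("INFO", "extracted %d scales for patient %s",
                   nrow(res), id, log_file = log_file)
    }
  }
  if (!length(rows)) stop("no patients could be extracted", call. = FALSE)
  tab <- as_feature_table(do.call(rbind, rows))
  rownames(tab) <- NULL
  attr(tab, "failures") <- failures
  tab
}

#' Two-stage prognostic analysis of a feature table
#'
#' Stage 1 screens every (feature, SSF) pair with a ROC analysis against the
#' binary progression label. Stage 2 takes the pairs whose ROC p-value
#' passes `screen_p` and, for each requested endpoint, finds the
#' optimal-threshold Kaplan-Meier split with its log-rank test, and fits the
#' univariate Cox model on overall survival with the feature as a continuous
#' covariate. Every cut-point p-value is flagged exploratory: the threshold
#' is searched to minimise it and no multiple-testing adjustment is applied.
#'
#' @param features a `feature_table`.
#' @param survival a `survival_table`.
#' @param config a [run_config] (used for `screen_p`, `endpoints`,
#'   `min_group_frac`).
#' @return object of class `analysis_report`: `roc_table` (one row per
#'   feature x SSF with either results or an exclusion reason), `survival_results`
#'   (per screened-in pair: KM/log-rank per endpoint and the OS Cox fit),
#'   `screen` settings and `provenance`.
#' @export
run_analysis <- function(features, survival, config) {
  stopifnot(inherits(config, "run_config"))
  features <- as_feature_table(features)
  survival <- as_survival_table(survival)

  ids <- unique(features$patient_id)
  orphans <- setdiff(ids, survival$patient_id)
  if (length(orphans)) {
    stop("feature-table patients missing from survival table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (length(ids) < 4L) {
    stop("need at least 4 patients with joined features and survival",
         call. = FALSE)
  }
  surv <- survival[match(ids, survival$patient_id), ]

  roc_rows <- list()
  surv_results <- list()
  for (f in FEATURE_NAMES) {
    for (s in sort(unique(features$ssf))) {
      sub <- features[features$ssf == s, ]
      x <- sub[[f]][match(ids, sub$patient_id)]
      key <- sprintf("%s_ssf%g", f, s)
      row <- data.frame(
        feature = f, ssf = s, n = sum(is.finite(x)),
        auc = NA_real_, direction = NA_character_, cutoff = NA_real_,
        sensitivity_pct = NA_real_, specificity_pct = NA_real_,
        p_value = NA_real_, screened_in = FALSE,
        excluded_reason = NA_character_, stringsAsFactors = FALSE
      )
      keep <- is.finite(x)
      res <- tryCatch(
        roc_analysis(x[keep], surv$progressor[keep]),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        row$excluded_reason <- conditionMessage(res)
      } else if (length(unique(x[keep])) < 2L) {
        row$excluded_reason <- "feature is constant across patients"
      } else {
        row$auc <- res$auc
        row$direction <- res$direction
        row$cutoff <- res$cutoff
        row$sensitivity_pct <- res$sensitivity_pct
        row$specificity_pct <- res$specificity_pct
        row$p_value <- res$p_value
        row$screened_in <- is.finite(res$p_value) && res$p_value < config$screen_p
      }
      roc_rows[[key]] <- row

      if (isTRUE(row$screened_in)) {
        per <- list(feature = f, ssf = s)
        for (ep in config$endpoints) {
          tt <- if (ep == "os") surv$os_days else surv$pfs_days
          ee <- if (ep == "os") surv$os_event else surv$pfs_event
          cut <- tryCatch(
            optimal_cutoff_km(x[keep], tt[keep], ee[keep],
                              min_group_frac = config$min_group_frac),
            error = function(e) e
          )
          per[[paste0("km_", ep)]] <- if (inherits(cut, "error")) {
            list(error = conditionMessage(cut))
          } else {
            list(
              threshold = cut$threshold,
              chi_square = cut$logrank$chi_square,
              p_value = cut$logrank$p_value,
              p_value_is_exploratory = TRUE,
              group_sizes = as.list(cut$logrank$group_sizes)
            )
          }
        }
        cox <- tryCatch(
          cox_univariate(x[keep], surv$os_days[keep], surv$os_event[keep]),
          error = function(e) e
        )
        per$cox_os <- if (inherits(cox, "error")) {
          list(error = conditionMessage(cox))
        } else {
          list(
            coefficient = cox$coefficient, hr = cox$hr,
            ci95_lower = cox$ci95[1L], ci95_upper = cox$ci95[2L],
            p_value = cox$p_value, converged = cox$converged,
            n_events = cox$n_events
          )
        }
        surv_results[[key]] <- per
      }
    }
  }
  roc_table <- do.call(rbind, roc_rows)
  rownames(roc_table) <- NULL

  structure(
    list(
      roc_table = roc_table,
      survival_results = surv_results,
      screen = list(p_threshold = config$screen_p,
                    endpoints = config$endpoints,
                    note = paste("cut-point p-values are exploratory:",
                                 "threshold searched, no multiplicity",
                                 "adjustment")),
      provenance = list(
        # hash over the scientific settings only; the output location must
        # not change what a rerun produces
        config_hash = digest::digest(
          unclass(config)[setdiff(names(config), "out_dir")]
        ),
        seed = if (!is.null(config$cohort)) config$cohort$seed else config$seed,
        ssf_list = config$ssf_list,
        package_version = as.character(utils::packageVersion("filtrad")),
        n_patients = length(ids)
      )
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  n_in <- sum(x$roc_table$screened_in, na.rm = TRUE)
  cat(sprintf(
    "<analysis_report> %d feature x SSF pairs screened, %d passed (p < %g) to KM/Cox; %d patients\n",
    nrow(x$roc_table), n_in, x$screen$p_threshold, x$provenance$n_patients
  ))
  if (n_in > 0) {
    top <- x$roc_table[x$roc_table$screened_in %in% TRUE, ]
    top <- top[order(-top$auc), c("feature", "ssf", "auc", "p_value")]
    print(utils::head(top, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Run the full pipeline: simulate (if synthetic), extract, analyse, write
#'
#' Writes `features.csv`, `report.json` and `run.log` under the config's
#' output directory. Identical configs produce byte-identical feature tables
#' and reports.
#'
#' @param config a [run_config].
#' @return the `analysis_report`, invisibly; attribute `paths` holds the
#'   output file locations.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  cat("", file = log_file) # truncate
  t0 <- proc.time()[["elapsed"]]

  inputs <- resolve_inputs(config)
  pipeline_log("INFO", "stage simulate/load: %d patients (%.1fs)",
               length(inputs$ids), proc.time()[["elapsed"]] - t0,
               log_file = log_file)

  t1 <- proc.time()[["elapsed"]]
  features <- extract_many(inputs, config$ssf_list, config$pooling,
                           log_file = log_file)
  feat_path <- file.path(config$out_dir, "features.csv")
  write_feature_table(features, feat_path)
  pipeline_log("INFO", "stage extract: %d rows -> %s (%.1fs)",
               nrow(features), feat_path, proc.time()[["elapsed"]] - t1,
               log_file = log_file)

  t2 <- proc.time()[["elapsed"]]
  report <- run_analysis(features, inputs$survival, config)
  report_path <- file.path(config$out_dir, "report.json")
  write_report(report, report_path)
  pipeline_log("INFO", "stage analyse: %d screened in -> %s (%.1fs)",
               sum(report$roc_table$screened_in, na.rm = TRUE), report_path,
               proc.time()[["elapsed"]] - t2, log_file = log_file)

  attr(report, "paths") <- list(features = feat_path, report = report_path,
                                log = log_file)
  invisible(report)
}

#' Write an analysis report as JSON
#' @param report an `analysis_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
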