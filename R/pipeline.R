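#' Configure an end-to-end trajectory-analysis run
#'
#' Either point `troughs`/`patients`/`outcomes` at CSV files (schemas of
#' [read_troughs()] and friends) or set `synth` to a [synth_config()] to
#' run on a generated cohort. Every stochastic stage derives its seed from
#' `seed`, so identical configurations reproduce identical reports.
#'
#' @param troughs,patients,outcomes CSV paths (ignored when `synth` given).
#' @param synth Optional [synth_config()]; when supplied the cohort is
#'   generated in memory.
#' @param cadence Panel cadence for the analysis (the mixture model
#'   consumes the yearly panel).
#' @param n_occasions Panel length (years).
#' @param min_years Minimum observed MLVI years for inclusion.
#' @param k_max Largest class count enumerated.
#' @param order Polynomial growth order.
#' @param n_starts,n_final Random-start counts for each fit.
#' @param blrt_B Bootstrap-LRT replicates (0 = skip).
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, all stage outputs and the
#'   run report (markdown + JSON) are written there.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(troughs = NULL, patients = NULL, outcomes = NULL,
                       synth = NULL, cadence = "yearly", n_occasions = 10L,
                       min_years = 4L, k_max = 3L, order = 1L,
                       n_starts = 60L, n_final = 10L, blrt_B = 0L,
                       seed = 1L, out_dir = NULL) {
  if (is.null(synth)) {
    for (p in c(troughs, patients, outcomes)) {
      if (!is.null(p) && !file.exists(p)) {
        abort(sprintf("Input file does not exist: '%s'", p),
              class = "adheretraj_schema_error")
      }
    }
    if (is.null(troughs) || is.null(patients)) {
      abort("Provide either `synth` or both `troughs` and `patients` paths.",
            class = "adheretraj_config_error")
    }
  } else {
    stopifnot(inherits(synth, "synth_config"))
  }
  structure(
    list(troughs = troughs, patients = patients, outcomes = outcomes,
         synth = synth, cadence = cadence,
         n_occasions = as.integer(n_occasions),
         min_years = as.integer(min_years), k_max = as.integer(k_max),
         order = as.integer(order), n_starts = as.integer(n_starts),
         n_final = as.integer(n_final), blrt_B = as.integer(blrt_B),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "adheretraj_pipeline_error", parent = e)
  })
}

#' Run the full adherence-trajectory pipeline
#'
#' Ingest (or synthesize) → eligibility and minimum-years filters → MLVI
#' panel and missingness profile → class enumeration → classification,
#' separation, outcome and demographic comparisons. Stage outputs and a run
#' report (markdown + JSON) are written to `config$out_dir` when set; a
#' stage failure aborts with the stage name, leaving earlier outputs on
#' disk for inspection.
#'
#' @param config A [run_config()].
#' @return List of class `"trajectory_report"` with elements `cohort_counts`,
#'   `exclusions`, `missingness`, `selection` (enumeration table),
#'   `recommended_K`, `rules`, `classification`, `separation`,
#'   `comparisons`, `outcome_rates`, `seeds`, plus the fitted
#'   `enumeration` object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  hdr <- c(seed = config$seed)

  if (!is.null(config$synth)) {
    cohort <- pipeline_stage("synth", synth_cohort(config$synth))
    troughs <- cohort$troughs; patients <- cohort$patients
    outcomes <- cohort$outcomes
  } else {
    troughs <- pipeline_stage("ingest", read_troughs(config$troughs))
    patients <- pipeline_stage("ingest", read_patients(config$patients))
    outcomes <- if (!is.null(config$outcomes)) {
      pipeline_stage("ingest", read_outcomes(config$outcomes))
    } else NULL
  }

  elig <- pipeline_stage("eligibility",
                         eligibility_filter(patients, troughs))
  troughs_e <- semi_join(troughs, elig$patients, by = "patient_id")

  panel <- pipeline_stage("mlvi", {
    p <- mlvi_panel(troughs_e, elig$patients, cadence = config$cadence,
                    n_occasions = config$n_occasions)
    minimum_years_filter(p, config$min_years)
  })
  miss <- pipeline_stage("mlvi", missingness_profile(panel))
  if (!is.null(out_dir)) {
    write_csv_with_header(as_tibble(panel),
                          file.path(out_dir, "mlvi_panel.csv"), hdr)
    write_csv_with_header(miss, file.path(out_dir, "missingness.csv"), hdr)
  }

  enum <- pipeline_stage("enumerate", enumerate_classes(
    panel, k_max = config$k_max,
    base_spec = growth_spec(1L, config$n_occasions, config$order),
    n_starts = config$n_starts, n_final = config$n_final,
    seed = config$seed, blrt_B = config$blrt_B))
  if (!is.null(out_dir)) {
    write_csv_with_header(enum$table, file.path(out_dir, "selection.csv"),
                          hdr)
    for (K in seq_along(enum$fits)) {
      f <- enum$fits[[K]]
      if (is.null(f)) next
      writeLines(jsonlite::toJSON(list(
        K = K, loglik = f$loglik, converged = f$converged,
        flags = f$flags, pi = f$params$pi, mu = f$params$mu,
        psi = f$params$psi, theta = f$params$theta,
        starts = f$starts_report[c("seed", "n_starts", "n_final",
                                   "n_replicated", "replicated")]),
        auto_unbox = TRUE, digits = NA),
        file.path(out_dir, sprintf("fit_K%d.json", K)))
      resp <- as_tibble(f$responsibilities, .name_repair = ~
                          paste0("class_", seq_len(ncol(f$responsibilities))))
      resp <- dplyr::bind_cols(
        tibble(patient_id = rownames(f$responsibilities)), resp)
      write_csv_with_header(resp,
                            file.path(out_dir,
                                      sprintf("responsibilities_K%d.csv", K)),
                            hdr)
    }
  }

  best_fit <- enum$fits[[enum$recommended_K]]
  cls <- pipeline_stage("profile", classify(best_fit))
  sep <- pipeline_stage("profile", separation_analysis(panel, cls))
  comparisons <- NULL
  rates <- NULL
  if (enum$recommended_K == 2) {
    comparisons <- pipeline_stage(
      "profile", compare_classes(patients, cls, outcomes))
  }
  if (!is.null(outcomes)) {
    rates <- pipeline_stage("profile", {
      oc <- semi_join(outcomes, cls$assignment, by = "patient_id")
      outcome_rates(oc, cls)
    })
  }

  report <- structure(
    list(
      cohort_counts = list(
        registry = nrow(patients), eligible = nrow(elig$patients),
        analyzed = length(attr(panel, "patient_ids")),
        troughs = nrow(troughs)),
      exclusions = elig$exclusions,
      missingness = miss,
      selection = enum$table,
      recommended_K = enum$recommended_K,
      rules = enum$rules,
      classification = cls,
      separation = sep,
      comparisons = comparisons,
      outcome_rates = rates,
      seeds = list(master = config$seed),
      enumeration = enum
    ),
    class = "trajectory_report"
  )
  if (!is.null(out_dir)) {
    write_report(report, out_dir, hdr)
  }
  report
}

report_json <- function(report) {
  jsonlite::toJSON(list(
    cohort_counts = report$cohort_counts,
    exclusions = report$exclusions,
    missingness = report$missingness,
    selection = report$selection,
    recommended_K = report$recommended_K,
    rules = report$rules,
    class_counts = report$classification$counts,
    avepp = report$classification$avepp,
    separation = list(ranges = report$separation$ranges,
                      overlap = report$separation$overlap,
                      threshold = report$separation$threshold),
    comparisons = report$comparisons,
    outcome_rates = report$outcome_rates,
    seeds = report$seeds
  ), dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
  na = "null")
}

write_report <- function(report, out_dir, hdr) {
  writeLines(report_json(report), file.path(out_dir, "report.json"))
  if (!is.null(report$comparisons)) {
    write_csv_with_header(report$comparisons,
                          file.path(out_dir, "table1.csv"), hdr)
  }
  write_csv_with_header(report$classification$assignment,
                        file.path(out_dir, "classification.csv"), hdr)
  writeLines(jsonlite::toJSON(
    list(ranges = report$separation$ranges,
         overlap = report$separation$overlap,
         gap_lower = report$separation$gap_lower,
         gap_upper = report$separation$gap_upper,
         threshold = report$separation$threshold),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"),
    file.path(out_dir, "separation.json"))
  md <- c(
    "# Adherence trajectory run report",
    "",
    sprintf("- master seed: %d", report$seeds$master),
    sprintf("- registry patients: %d; eligible: %d; analyzed: %d",
            report$cohort_counts$registry, report$cohort_counts$eligible,
            report$cohort_counts$analyzed),
    sprintf("- exclusions: %s",
            paste(sprintf("%s (%d)", report$exclusions$reason,
                          report$exclusions$n), collapse = ", ")),
    sprintf("- recommended K: %d", report$recommended_K),
    sprintf("- rules: %s", paste(report$rules, collapse = "; ")),
    sprintf("- class counts: %s",
            paste(report$classification$counts, collapse = " / ")),
    sprintf("- separation: %s",
            if (report$separation$overlap) "ranges overlap"
            else sprintf("disjoint, gap (%.3f, %.3f), midpoint %.3f",
                         report$separation$gap_lower,
                         report$separation$gap_upper,
                         report$separation$threshold))
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("Adherence trajectory report\n")
  cat(sprintf("  patients: %d registry, %d eligible, %d analyzed\n",
              x$cohort_counts$registry, x$cohort_counts$eligible,
              x$cohort_counts$analyzed))
  cat("  recommended K:", x$recommended_K, "\n")
  cat("  class counts:", paste(x$classification$counts, collapse = " / "),
      "\n")
  if (!x$separation$overlap && !is.na(x$separation$threshold)) {
    cat(sprintf("  separation: disjoint, midpoint threshold %.3f\n",
                x$separation$threshold))
  }
  invisible(x)
}
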