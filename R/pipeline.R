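#' Pipeline run configuration
#'
#' @param records Individual records: a data frame or a CSV/TSV path for
#'   [read_records()].
#' @param growth_ref Growth reference (data frame or CSV path); required
#'   only when child rows lack `bmi_percentile`.
#' @param strata Either `NULL` (one pooled stratum) or a data frame of
#'   `sex`/`group` combinations to fit separately; `"auto"` derives all
#'   combinations present in the records.
#' @param cycle_mode `"pooled"` or `"per_cycle"` weight handling across
#'   survey cycles.
#' @param spec A [prevalence_spec()].
#' @param cost A [cost_matrix()].
#' @param bootstrap A [bootstrap_config()], or `NULL` to skip CIs.
#' @param pop Optional population counts (data frame or CSV path) enabling
#'   the extrapolation stage.
#' @param seed Master seed; mandatory, feeds every stochastic stage.
#' @param output_dir Optional directory; when given, prevalence, net
#'   transition and extrapolation CSVs plus a JSON run log are written.
#' @return List of class `run_config`.
#' @export
run_config <- function(records, growth_ref = NULL, strata = NULL,
                       cycle_mode = "pooled", spec = prevalence_spec(),
                       cost = cost_matrix(), bootstrap = bootstrap_config(),
                       pop = NULL, seed = 1, output_dir = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  structure(list(records = records, growth_ref = growth_ref, strata = strata,
                 cycle_mode = cycle_mode, spec = spec, cost = cost,
                 bootstrap = bootstrap, pop = pop, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full net-transition estimation pipeline
#'
#' Stages: eligibility exclusions, weight classification, cycle pooling,
#' per-stratum prevalence smoothing, net transition estimation, parametric
#' bootstrap, and (when population counts are supplied) extrapolation to
#' net numbers of people transitioning. Any stage error is re-raised with
#' the stage name.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_result`: `exclusion_log`, per-stratum
#'   `curves`, `nets` (one table with stratum columns and CIs),
#'   `extrapolation` (or `NULL`) and the `log` written alongside any output.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  records <- stage("input", {
    if (is.character(cfg$records)) read_records(cfg$records) else
      as.data.frame(cfg$records)
  })
  growth_ref <- stage("input", {
    if (is.character(cfg$growth_ref)) read_growth_reference(cfg$growth_ref)
    else cfg$growth_ref
  })
  pop <- stage("input", {
    if (is.character(cfg$pop)) read_population_counts(cfg$pop) else cfg$pop
  })

  excl <- stage("exclusions", apply_exclusions(records))
  classified <- stage("classification",
                      assign_categories(excl$eligible, growth_ref))
  classified <- stage("cycles", combine_cycles(classified, cfg$cycle_mode))

  strata <- cfg$strata
  if (identical(strata, "auto")) {
    strata <- unique(classified[intersect(c("sex", "group"), names(classified))])
  }
  if (is.null(strata)) strata <- data.frame(row.names = 1)

  curves <- list(); nets <- list(); extrap <- list()
  for (si in seq_len(nrow(strata))) {
    sdef <- as.list(strata[si, , drop = FALSE])
    label <- if (length(sdef)) paste(unlist(sdef), collapse = ":") else "all"
    curve <- stage("prevalence",
                   fit_prevalence(classified, stratum = sdef, spec = cfg$spec))
    tab <- if (is.null(cfg$bootstrap)) {
      stage("nets", net_transition_table(curve))
    } else {
      bc <- cfg$bootstrap
      bc$seed <- cfg$seed + 104729L * si  # independent stream per stratum
      stage("bootstrap", bootstrap_nets(curve, cfg$cost, bc))
    }
    tab <- cbind(stratum = label, tab)
    curves[[label]] <- curve
    nets[[label]] <- tab
    if (!is.null(pop)) {
      ex <- stage("extrapolation",
                  extrapolate_counts(tab[, setdiff(names(tab), "stratum")],
                                     curve, pop))
      extrap[[label]] <- cbind(stratum = label, ex)
    }
  }
  nets <- do.call(rbind, nets)
  rownames(nets) <- NULL
  extrap <- if (length(extrap)) { e <- do.call(rbind, extrap); rownames(e) <- NULL; e }

  log <- list(seed = cfg$seed, cycle_mode = cfg$cycle_mode,
              cost_constants = cfg$cost$constants,
              lambda = lapply(curves, function(cv) cv$lambda),
              n_input = excl$log$n_input, n_eligible = excl$log$n_eligible,
              exclusions = excl$log,
              bootstrap = if (!is.null(cfg$bootstrap)) {
                cfg$bootstrap[c("replicates", "ci_level")]
              },
              r_version = R.version.string)
  res <- structure(list(exclusion_log = excl$log, curves = curves,
                        nets = nets, extrapolation = extrap, log = log),
                   class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(res, cfg$output_dir)
  res
}

#' Write pipeline outputs as CSV + JSON
#'
#' Emits `prevalence.csv` (stratum, age, p_normal, p_overweight, p_obese),
#' `net_transitions.csv` (the machine-readable per-age net transition table
#' with CIs), `extrapolation.csv` when available, and `run_log.json`.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prev <- do.call(rbind, lapply(names(res$curves), function(lab) {
    cv <- res$curves[[lab]]
    data.frame(stratum = lab, age = cv$ages,
               p_normal = cv$P[, 1], p_overweight = cv$P[, 2],
               p_obese = cv$P[, 3])
  }))
  paths <- c(prevalence = file.path(dir, "prevalence.csv"),
             nets = file.path(dir, "net_transitions.csv"),
             log = file.path(dir, "run_log.json"))
  utils::write.csv(prev, paths["prevalence"], row.names = FALSE)
  utils::write.csv(res$nets, paths["nets"], row.names = FALSE)
  if (!is.null(res$extrapolation)) {
    paths["extrapolation"] <- file.path(dir, "extrapolation.csv")
    utils::write.csv(res$extrapolation, paths["extrapolation"], row.names = FALSE)
  }
  jsonlite::write_json(res$log, paths["log"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Net-transition pipeline result\n")
  cat(sprintf("  %d / %d records eligible; %d stratum curve(s)\n",
              x$exclusion_log$n_eligible, x$exclusion_log$n_input,
              length(x$curves)))
  cat(sprintf("  net table: %d rows%s\n", nrow(x$nets),
              if ("ci_low" %in% names(x$nets)) " (with bootstrap CIs)" else ""))
  invisible(x)
}
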