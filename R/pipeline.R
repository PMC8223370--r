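# deterministic 32-bit rolling hash; used to stamp reports with a config
# fingerprint and to derive per-stage RNG substreams from one master seed
string_hash32 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

config_hash <- function(config) {
  # fingerprint the analysis-relevant settings; where outputs land is not
  # part of the analysis identity
  config$out_dir <- NULL
  sprintf("%08x", string_hash32(paste(deparse(unclass(config)),
                                      collapse = "\n")))
}

stage_seed <- function(seed, stage) {
  as.integer((seed + string_hash32(stage)) %% 2147483647)
}

#' Assemble a pipeline run configuration
#'
#' @param cohort Path to a cohort CSV, or `NULL` to simulate.
#' @param design A [dyna_design()] used when `cohort` is `NULL`; default the
#'   [scenario_paperlike()] design.
#' @param threshold,alpha Network-construction parameters.
#' @param intervals Interval matrix (default [default_intervals()]).
#' @param windows List of correlation windows (default 0-12 h and 12-48 h).
#' @param pairs List of mediator pairs for windowed correlations.
#' @param correlation_compartments Compartments the windowed correlations
#'   are computed in.
#' @param B Bootstrap replicates.
#' @param seed Master seed; every stage derives its own substream from it.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = NULL, design = NULL, threshold = 0.7,
                       alpha = 0.05, intervals = default_intervals(),
                       windows = list(c(0, 12), c(12, 48)),
                       pairs = list(c("IL-17A", "GM-CSF"),
                                    c("IL-17A", "TNF")),
                       correlation_compartments = c("plasma", "spleen"),
                       B = 1000, seed = 1L, out_dir = "dyna-run") {
  if (!is.null(cohort) && !file.exists(cohort))
    stop("cohort file does not exist: ", cohort, call. = FALSE)
  structure(
    list(cohort = cohort, design = design, threshold = threshold,
         alpha = alpha, intervals = validate_intervals(intervals),
         windows = windows, pairs = pairs,
         correlation_compartments = correlation_compartments,
         B = B, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors [run_config()] fields; `intervals` and `windows` are
#' lists of two-number arrays.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("cohort", "threshold", "alpha", "B", "seed", "out_dir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$intervals))
    args$intervals <- do.call(rbind, lapply(y$intervals, as.numeric))
  if (!is.null(y$windows))
    args$windows <- lapply(y$windows, as.numeric)
  if (!is.null(y$pairs))
    args$pairs <- lapply(y$pairs, as.character)
  if (!is.null(y$correlation_compartments))
    args$correlation_compartments <- as.character(y$correlation_compartments)
  if (identical(y$design, "paperlike"))
    args$design <- scenario_paperlike(seed = if (is.null(y$seed)) 1L
                                      else as.integer(y$seed))
  do.call(run_config, args)
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

ratio_or_marker <- function(r) {
  if (is.nan(r)) "undefined" else if (is.infinite(r)) "Inf" else r
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> interval networks -> complexity and
#' connection totals -> AUC summaries -> windowed Spearman correlations, and
#' writes every artifact under `config$out_dir`:
#'
#' * `cohort.csv` — the analysed cohort (when simulated);
#' * `networks/` — one edge list (`.tsv`) and one GraphML per
#'   (strain, compartment, interval);
#' * `complexity.json` — per-interval complexity and totals per group;
#' * `auc.json` — per-mediator AUCs, compartment sums, strain ratios;
#' * `spearman.json` — windowed correlations with bootstrap CIs;
#' * `report.json`, `report.md` — consolidated report ranking compartments
#'   by connection ratio and by AUC ratio, stamped with seed and config
#'   hash, including per-stage skip/warning logs.
#'
#' The run is deterministic for a given configuration and seed; every stage
#' draws from its own substream derived from the master seed, so stage order
#' cannot silently change results.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the in-memory results (`cohort`, `fits`,
#'   `auc`, `correlations`, `report`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stamp <- list(seed = config$seed, config_hash = config_hash(config))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- cohort stage (validate everything before writing any output) ------
  sim <- NULL
  cohort <- run_stage("cohort", {
    if (!is.null(config$cohort)) {
      read_cohort(config$cohort)
    } else {
      design <- if (is.null(config$design))
        scenario_paperlike(seed = config$seed) else config$design
      sim <- simulate_cohort(design, seed = stage_seed(config$seed,
                                                       "simulate"))
      sim$cohort
    }
  })
  if (!nrow(cohort))
    stop("pipeline stage 'cohort' failed: cohort is empty", call. = FALSE)
  strains <- unique(cohort$strain)
  compartments <- unique(cohort$compartment)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "networks"), showWarnings = FALSE)
  if (is.null(config$cohort))
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  # --- network stage ------------------------------------------------------
  skip_log <- list()
  fits <- run_stage("dyna", {
    out <- list()
    for (s in strains) for (cp in compartments) {
      fit <- dyna(cohort, s, cp, intervals = config$intervals,
                  threshold = config$threshold, alpha = config$alpha)
      out[[paste(s, cp, sep = "|")]] <- fit
      for (nm in names(fit$networks)) {
        nw <- fit$networks[[nm]]
        stem <- file.path(config$out_dir, "networks",
                          safe_name(paste(s, cp, nm, sep = "_")))
        write_network(nw, paste0(stem, ".tsv"), "edgelist")
        write_network(nw, paste0(stem, ".graphml"), "graphml")
        if (nrow(nw$skipped))
          skip_log[[length(skip_log) + 1L]] <- list(
            stage = "dyna", strain = s, compartment = cp, interval = nm,
            skipped_pairs = nrow(nw$skipped))
      }
    }
    out
  })

  complexity <- lapply(fits, function(fit) list(
    strain = fit$strain, compartment = fit$compartment,
    per_interval = as.list(fit$complexity),
    total_connections = fit$total_connections))
  jsonlite::write_json(c(stamp, list(groups = unname(complexity))),
                       file.path(config$out_dir, "complexity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- connection / AUC ratio stage --------------------------------------
  two_strains <- length(strains) == 2
  ratios <- NULL
  aucs <- run_stage("auc", {
    lapply(compartments, function(cp)
      if (two_strains) compartment_auc_summary(cohort, cp, strains)
      else NULL)
  })
  names(aucs) <- compartments
  if (two_strains) {
    conn <- vapply(compartments, function(cp) {
      ta <- fits[[paste(strains[1], cp, sep = "|")]]$total_connections
      tb <- fits[[paste(strains[2], cp, sep = "|")]]$total_connections
      connection_ratio(ta, tb)
    }, 0)
    aucr <- vapply(compartments, function(cp) aucs[[cp]]$strain_ratio, 0)
    ratios <- data.frame(compartment = compartments,
                         connection_ratio = conn, auc_ratio = aucr)
  }
  auc_json <- lapply(compartments, function(cp) {
    a <- aucs[[cp]]
    if (is.null(a)) return(NULL)
    list(compartment = cp,
         per_mediator = stats::setNames(
           lapply(seq_along(a$strains), function(i)
             as.list(a$per_mediator[, i])), a$strains),
         compartment_sum = as.list(a$compartment_sum),
         strain_ratio = ratio_or_marker(a$strain_ratio))
  })
  jsonlite::write_json(c(stamp, list(compartments = unname(auc_json))),
                       file.path(config$out_dir, "auc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- windowed correlation stage ----------------------------------------
  correlations <- run_stage("correlate", {
    out <- list()
    for (s in strains) for (cp in config$correlation_compartments)
      for (pair in config$pairs) for (w in config$windows) {
        key <- paste(s, cp, paste(pair, collapse = ":"),
                     paste(w, collapse = "-"), sep = "|")
        out[[key]] <- window_correlation(
          cohort, s, cp, pair, w, B = config$B,
          seed = stage_seed(config$seed, paste("correlate", key)))
      }
    out
  })
  sp_json <- lapply(correlations, function(x) list(
    strain = x$strain, compartment = x$compartment,
    pair = paste(x$pair, collapse = ":"),
    window = sprintf("%g-%g h", x$window[1], x$window[2]),
    rho = x$rho, ci_low = x$ci_low, ci_high = x$ci_high, n = x$n,
    B = x$B, significant = x$significant, n_redrawn = x$n_redrawn))
  jsonlite::write_json(c(stamp, list(correlations = unname(sp_json))),
                       file.path(config$out_dir, "spearman.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- consolidated report -----------------------------------------------
  report <- c(stamp, list(
    strains = strains, compartments = compartments,
    threshold = config$threshold, alpha = config$alpha,
    skip_log = skip_log))
  if (two_strains) {
    ord_conn <- order(-ifelse(is.nan(ratios$connection_ratio), -Inf,
                              ratios$connection_ratio))
    ord_auc <- order(-ifelse(is.nan(ratios$auc_ratio), -Inf,
                             ratios$auc_ratio))
    report$ratio_numerator <- strains[1]
    report$ratio_denominator <- strains[2]
    report$connection_ratio_ranking <- lapply(ord_conn, function(i) list(
      compartment = ratios$compartment[i],
      connection_ratio = ratio_or_marker(ratios$connection_ratio[i])))
    report$auc_ratio_ranking <- lapply(ord_auc, function(i) list(
      compartment = ratios$compartment[i],
      auc_ratio = ratio_or_marker(ratios$auc_ratio[i])))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report_md(report, fits, correlations,
                  file.path(config$out_dir, "report.md"))

  invisible(list(cohort = cohort, fits = fits, auc = aucs,
                 correlations = correlations, report = report,
                 ratios = ratios))
}

write_report_md <- function(report, fits, correlations, path) {
  lines <- c(
    "# Dynamic network analysis report", "",
    sprintf("- seed: %d", report$seed),
    sprintf("- config hash: %s", report$config_hash),
    sprintf("- edge threshold |r| >= %g; baseline alpha = %g",
            report$threshold, report$alpha), "")
  if (!is.null(report$connection_ratio_ranking)) {
    lines <- c(lines, sprintf(
      "## Compartments by connection ratio (%s : %s)",
      report$ratio_numerator, report$ratio_denominator), "")
    for (e in report$connection_ratio_ranking)
      lines <- c(lines, sprintf("1. %s: %s", e$compartment,
                                format(e$connection_ratio)))
    lines <- c(lines, "", "## Compartments by AUC ratio", "")
    for (e in report$auc_ratio_ranking)
      lines <- c(lines, sprintf("1. %s: %s", e$compartment,
                                format(e$auc_ratio)))
  }
  lines <- c(lines, "", "## Total connections per group", "")
  for (fit in fits)
    lines <- c(lines, sprintf("- %s | %s: %d", fit$strain,
                              fit$compartment, fit$total_connections))
  if (length(correlations)) {
    lines <- c(lines, "", "## Windowed Spearman correlations", "")
    for (x in correlations)
      lines <- c(lines, sprintf(
        "- %s | %s | %s vs %s | %g-%g h: rho = %.3f [%.3f, %.3f]%s",
        x$strain, x$compartment, x$pair[1], x$pair[2], x$window[1],
        x$window[2], x$rho, x$ci_low, x$ci_high,
        if (x$significant) " *" else ""))
  }
  if (length(report$skip_log)) {
    lines <- c(lines, "", "## Skipped correlation pairs", "")
    for (e in report$skip_log)
      lines <- c(lines, sprintf("- %s | %s | %s: %d pair(s) skipped",
                                e$strain, e$compartment, e$interval,
                                e$skipped_pairs))
  }
  writeLines(lines, path)
}
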