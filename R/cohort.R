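#' Construct and validate a cohort table
#'
#' A cohort table holds long-format mediator measurements: one row per
#' (strain, compartment, time, animal, mediator) with a non-negative
#' concentration.  Animals are terminally sampled, so each animal contributes
#' exactly one time point within its strain; all compartments of that animal
#' share the time point.
#'
#' Validation enforces:
#' * required columns `strain`, `compartment`, `time_h`, `animal_id`,
#'   `mediator`, `concentration`;
#' * mediator names (after whitespace trimming) belong to the panel — no
#'   fuzzy matching;
#' * at most one value per mediator within each
#'   (strain, compartment, time_h, animal_id) block;
#' * each animal appears at exactly one time point within a strain;
#' * non-negative finite concentrations and times.
#'
#' Missing measurements are absent rows, never sentinel values.
#'
#' @param df A data.frame with the required columns.
#' @param panel A [mediator_panel()].
#' @return A `cohort_table`: a data.frame with the panel attached as
#'   attribute `panel`, rows ordered by strain, compartment, time, animal and
#'   panel order.
#' @export
cohort_table <- function(df, panel = mediator_panel()) {
  required <- c("strain", "compartment", "time_h", "animal_id",
                "mediator", "concentration")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  df <- as.data.frame(df)[required]
  df$strain <- as.character(df$strain)
  df$compartment <- as.character(df$compartment)
  df$animal_id <- as.character(df$animal_id)
  df$mediator <- trimws(as.character(df$mediator))
  df$time_h <- as.numeric(df$time_h)
  df$concentration <- as.numeric(df$concentration)

  bad_med <- setdiff(unique(df$mediator), panel$names)
  if (length(bad_med))
    stop("mediator(s) not in panel: ", paste(bad_med, collapse = ", "),
         call. = FALSE)
  if (anyNA(df$time_h) || any(df$time_h < 0))
    stop("time_h must be non-negative numbers", call. = FALSE)
  if (anyNA(df$concentration) || any(!is.finite(df$concentration)) ||
      any(df$concentration < 0))
    stop("concentrations must be non-negative finite numbers", call. = FALSE)

  key <- paste(df$strain, df$compartment, df$time_h, df$animal_id,
               df$mediator, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("cohort integrity error: duplicate (strain, compartment, time_h, ",
         "animal_id, mediator) rows: ",
         paste(gsub("\r", "/", utils::head(dups, 5L)), collapse = "; "),
         call. = FALSE)
  }

  # terminal sampling: one time point per animal within a strain
  at <- unique(df[c("strain", "animal_id", "time_h")])
  multi <- at$animal_id[duplicated(paste(at$strain, at$animal_id, sep = "\r"))]
  if (length(multi))
    stop("terminal-sampling violation: animal(s) at more than one time ",
         "point within a strain: ",
         paste(unique(multi), collapse = ", "), call. = FALSE)

  ord <- order(df$strain, df$compartment, df$time_h, df$animal_id,
               match(df$mediator, panel$names))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, panel = panel, class = c("cohort_table", "data.frame"))
}

#' Read a cohort CSV
#'
#' Reads long-format cohort measurements from a UTF-8 CSV with header columns
#' `strain, compartment, time_h, animal_id, mediator, concentration` and
#' validates them against the panel.  With `wide = TRUE` the file instead has
#' one column per mediator (columns `strain, compartment, time_h, animal_id`
#' followed by mediator columns) and is reshaped to long form first; `NA`
#' cells become absent rows.
#'
#' @param path CSV file path.
#' @param panel A [mediator_panel()].
#' @param wide Logical; is the file in wide (one column per mediator) form?
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, panel = mediator_panel(), wide = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (wide) {
    id_cols <- c("strain", "compartment", "time_h", "animal_id")
    missing_cols <- setdiff(id_cols, names(df))
    if (length(missing_cols))
      stop("cohort schema error: missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    med_cols <- setdiff(names(df), id_cols)
    long <- do.call(rbind, lapply(med_cols, function(m) {
      out <- df[id_cols]
      out$mediator <- m
      out$concentration <- df[[m]]
      out
    }))
    df <- long[!is.na(long$concentration), , drop = FALSE]
  }
  cohort_table(df, panel)
}

#' Write a cohort table to CSV
#'
#' @param cohort A [cohort_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "Cohort table: %d measurements | %d strain(s) x %d compartment(s) | %d time points | %d mediators\n",
    nrow(x), length(unique(x$strain)), length(unique(x$compartment)),
    length(unique(x$time_h)), length(unique(x$mediator))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

cohort_panel <- function(cohort) {
  p <- attr(cohort, "panel")
  if (is.null(p)) mediator_panel() else p
}

# values of one mediator for one strain/compartment at given time points;
# named by animal_id
mediator_values <- function(cohort, strain, compartment, mediator, times) {
  sel <- cohort$strain == strain & cohort$compartment == compartment &
    cohort$mediator == mediator & cohort$time_h %in% times
  stats::setNames(cohort$concentration[sel], cohort$animal_id[sel])
}
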