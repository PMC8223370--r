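#' Mediator panel
#'
#' A mediator panel declares the ordered set of mediator identifiers a cohort
#' may contain, together with the measurement unit per compartment.  The
#' default is the canonical 20-plex mouse cytokine/chemokine bead panel, with
#' concentrations in pg/ml for plasma and pg/mg total protein for solid
#' tissues.
#'
#' @param names Character vector of unique, non-empty mediator identifiers.
#' @param compartments Character vector of compartment labels the panel knows
#'   units for.
#' @param units Character vector of unit strings, one per compartment.
#'   Defaults to `"pg/ml"` for `"plasma"` and `"pg/mg"` elsewhere.
#' @return An object of class `mediator_panel`: a list with elements `names`
#'   and `units_by_compartment`.
#' @examples
#' p <- mediator_panel()
#' length(p$names)      # 20
#' p$units_by_compartment[["plasma"]]
#' @export
mediator_panel <- function(names = default_mediators(),
                           compartments = default_compartments(),
                           units = ifelse(compartments == "plasma",
                                          "pg/ml", "pg/mg")) {
  names <- as.character(names)
  if (anyDuplicated(names) || any(!nzchar(names)))
    stop("panel mediator names must be unique and non-empty", call. = FALSE)
  if (length(units) != length(compartments))
    stop("'units' must have one entry per compartment", call. = FALSE)
  structure(
    list(names = names,
         units_by_compartment = stats::setNames(as.character(units),
                                                compartments)),
    class = "mediator_panel"
  )
}

#' @describeIn mediator_panel The canonical 20-mediator multiplex panel.
#' @export
default_mediators <- function() {
  c("GM-CSF", "IFN-\u03b3", "IL-1\u03b1", "IL-1\u03b2", "IL-2", "IL-4",
    "IL-5", "IL-6", "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-17A",
    "IP-10", "KC", "MCP-1", "MIG", "MIP-1\u03b1", "TNF", "VEGF")
}

#' @describeIn mediator_panel The seven sampled compartments: plasma plus six
#'   organs.
#' @export
default_compartments <- function() {
  c("plasma", "heart", "liver", "kidney", "gut", "lung", "spleen")
}

#' @export
print.mediator_panel <- function(x, ...) {
  cat("Mediator panel:", length(x$names), "mediators\n")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  cat("Units:",
      paste(sprintf("%s (%s)", names(x$units_by_compartment),
                    x$units_by_compartment), collapse = ", "), "\n")
  invisible(x)
}
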