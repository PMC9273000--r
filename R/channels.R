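# Secondary-ion channel definitions shared by all modules.

# Registry of the detected species, their nominal masses (amu) and the role
# each plays in the evaluation. 12C2- is the structural reference used for
# normalisation and registration; the CN- isotopologues carry the 15N label.
.channel_registry <- data.frame(
  species_label = c("12C2", "12C14N", "12C15N", "31P", "34S", "19F", "194Pt"),
  nominal_mass  = c(24L, 26L, 27L, 31L, 34L, 19L, 194L),
  role = c("reference", "nitrogen_major", "nitrogen_minor",
           "biomarker", "biomarker", "tracer", "analyte"),
  stringsAsFactors = FALSE
)

#' Secondary-ion channel specification
#'
#' Describes one detected ion species. The species label is restricted to the
#' channels used by the evaluation procedure: \code{"12C2"} (structural
#' reference), \code{"12C14N"}/\code{"12C15N"} (nitrogen isotopologues),
#' \code{"31P"}/\code{"34S"} (biomarkers), \code{"19F"} (acidotropic-dye
#' tracer) and \code{"194Pt"} (drug analyte). Mass and role default to the
#' registry values for the species.
#'
#' @param species_label One of the controlled species labels above.
#' @param nominal_mass Nominal mass in amu (positive integer). Defaults to the
#'   registry value.
#' @param role Channel role, one of \code{"reference"}, \code{"nitrogen_major"},
#'   \code{"nitrogen_minor"}, \code{"biomarker"}, \code{"tracer"},
#'   \code{"analyte"}. Defaults to the registry value.
#' @return An object of class \code{"channel_spec"}.
#' @export
#' @examples
#' channel_spec("194Pt")
channel_spec <- function(species_label, nominal_mass = NULL, role = NULL) {
  i <- match(species_label, .channel_registry$species_label)
  if (is.na(i)) {
    stop("unknown species_label '", species_label, "'; must be one of: ",
         paste(.channel_registry$species_label, collapse = ", "))
  }
  if (is.null(nominal_mass)) nominal_mass <- .channel_registry$nominal_mass[i]
  if (is.null(role)) role <- .channel_registry$role[i]
  nominal_mass <- as.integer(nominal_mass)
  if (is.na(nominal_mass) || nominal_mass <= 0L) stop("nominal_mass must be > 0")
  roles <- c("reference", "nitrogen_major", "nitrogen_minor",
             "biomarker", "tracer", "analyte")
  role <- match.arg(role, roles)
  structure(list(species_label = species_label,
                 nominal_mass = nominal_mass,
                 role = role),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel %s, m/z %d, role %s>\n",
              x$species_label, x$nominal_mass, x$role))
  invisible(x)
}

# Channels that must be present for each run type.
.required_channels <- list(
  pt_run = c("194Pt", "12C2"),
  n_run  = c("12C14N", "12C15N", "12C2")
)
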