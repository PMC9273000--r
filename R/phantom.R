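# Synthetic phantom generator.
#
# Emulates the statistical structure of resin-section NanoSIMS measurements
# of drug-exposed cells: a centred cell with cytoplasm, nucleus (excluding
# nucleolus and chromatin rim), nucleolus, chromatin rim and S-rich
# cytoplasmic aggregates; per-compartment expected count rates per channel;
# independent Poisson shot noise on every pixel; and a rigid translation of
# the nitrogen run against the platinum run, mimicking stage drift between
# sequential acquisitions. Ground truth (label fraction, Pt/N index,
# stoichiometry per compartment) is returned in closed form.

# Deterministic per-stream seed derivation from one global seed (kept < 2^31).
.derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k * 2654435) %% 2147483647)
}

.phantom_compartments <- c("background", "cytoplasm", "nucleus", "nucleolus",
                           "chromatin", "aggregate")

# Expected counts per pixel per channel at zero drug ("CN" is the total
# biological CN- rate, split into the isotopologues by the 15N abundance).
.default_base_yields <- function() {
  m <- rbind(
    background = c(500,   50,   2,   2, 0.5, 0),
    cytoplasm  = c(2500, 1000,  60,  60, 2,   0),
    nucleus    = c(2500, 1500, 120,  60, 0.5, 0),
    nucleolus  = c(3000, 5000, 300, 250, 0.5, 0),
    chromatin  = c(2500, 2000, 400,  40, 0.5, 0),
    aggregate  = c(2500, 3000,  60, 400, 30,  0))
  colnames(m) <- c("12C2", "CN", "31P", "34S", "19F", "194Pt")
  m
}

# Expected 194Pt- counts per pixel per uM exposure (linear accumulation).
.default_drug_rates <- c(background = 0, cytoplasm = 0.010, nucleus = 0.012,
                         nucleolus = 0.050, chromatin = 0.015, aggregate = 0.040)

#' Phantom configuration
#'
#' Defines the geometry, ion yields, drug accumulation and isotopic
#' parameters of a synthetic paired pt_run/n_run acquisition. All lengths are
#' in micrometres.
#'
#' @param grid Integer \code{c(rows, cols)}; default 512 x 512.
#' @param pixel_size Pixel edge in um; default 40/512 (a 40 um field).
#' @param dwell_time Accumulated dwell per pixel in ms; default 250.
#' @param cell_radius,nucleus_radius,nucleolus_radius Radii of the nested
#'   cell, nucleus and nucleolus discs (um).
#' @param chromatin_thickness Thickness of the chromatin rim lining the inner
#'   nuclear boundary (um).
#' @param nucleolus_offset Offset of the nucleolus centre from the nucleus
#'   centre (um); must keep the nucleolus inside the rim-free nucleus.
#' @param n_aggregates,aggregate_radius Number and radius of non-overlapping
#'   S-rich cytoplasmic aggregate discs.
#' @param base_yields Matrix of expected counts/pixel at zero drug; rows
#'   \code{background, cytoplasm, nucleus, nucleolus, chromatin, aggregate},
#'   columns \code{12C2, CN, 31P, 34S, 19F, 194Pt}. \code{CN} is the total
#'   biological CN- rate.
#' @param drug_load Named vector of expected 194Pt- counts/pixel attributable
#'   to accumulated drug, per compartment. Default: linear accumulation rates
#'   times \code{exposure_concentration}.
#' @param ligand_number Named per-compartment number of labeled nitrogen
#'   atoms retained per accumulated Pt atom (0..3; 2 for the intact
#'   diammine drug). Default 2 everywhere.
#' @param rsf Relative sensitivity factors \code{c(pt = , n = )}: the Pt/N
#'   count ratio produced by a unit Pt/N atom ratio is \code{rsf["pt"]/rsf["n"]}.
#' @param a_cddp 15N abundance of the administered labeled drug (label
#'   purity), in (0, 1].
#' @param a_ctr 15N abundance of unlabeled biological nitrogen; default the
#'   terrestrial natural abundance 0.003676.
#' @param shift Integer \code{c(d_row, d_col)} translation applied to the
#'   n_run relative to the pt_run (inter-run stage drift).
#' @param exposure_concentration Exposure in uM (metadata; also scales the
#'   default \code{drug_load}).
#' @param seed Integer global seed; split deterministically per run/channel.
#' @return A validated list of class \code{"phantom_config"}.
#' @export
phantom_config <- function(grid = c(512L, 512L), pixel_size = 40 / 512,
                           dwell_time = 250,
                           cell_radius = 9, nucleus_radius = 5.5,
                           nucleolus_radius = 1.8, chromatin_thickness = 0.6,
                           nucleolus_offset = 1,
                           n_aggregates = 6, aggregate_radius = 0.8,
                           base_yields = .default_base_yields(),
                           drug_load = NULL,
                           ligand_number = NULL,
                           rsf = c(pt = 5, n = 1),
                           a_cddp = 0.99, a_ctr = 0.003676,
                           shift = c(0L, 0L),
                           exposure_concentration = 25,
                           seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2L, all(grid >= 8L), pixel_size > 0, dwell_time > 0)
  if (is.null(drug_load))
    drug_load <- .default_drug_rates * exposure_concentration
  if (is.null(ligand_number))
    ligand_number <- c(background = 0, cytoplasm = 2, nucleus = 2,
                       nucleolus = 2, chromatin = 2, aggregate = 2)
  drug_load <- .complete_compartment_vector(drug_load, 0)
  ligand_number <- .complete_compartment_vector(ligand_number, 0)
  stopifnot(is.matrix(base_yields),
            identical(rownames(base_yields), .phantom_compartments),
            identical(colnames(base_yields), c("12C2", "CN", "31P", "34S", "19F", "194Pt")),
            all(base_yields >= 0), all(drug_load >= 0))
  if (any(ligand_number < 0) || any(ligand_number > 3))
    stop("ligand_number must lie in [0, 3] (at most the drug's own N content)")
  stopifnot(all(rsf > 0), length(shift) == 2L, all(shift == floor(shift)))
  if (!(a_ctr > 0 && a_ctr < 1 && a_cddp > 0 && a_cddp <= 1))
    stop("abundances must be fractions in (0, 1]")
  if (a_ctr >= a_cddp) stop("a_ctr must be smaller than a_cddp")
  if (nucleolus_offset + nucleolus_radius > nucleus_radius - chromatin_thickness)
    stop("nucleolus must fit inside the nucleus interior (within the chromatin rim)")
  if (nucleus_radius >= cell_radius)
    stop("nucleus must fit inside the cell")
  half_um <- min(grid) / 2 * pixel_size
  if (cell_radius >= half_um)
    stop(sprintf("cell radius %.3g um does not fit the %.3g um half-field", cell_radius, half_um))
  structure(list(grid = grid, pixel_size = pixel_size, dwell_time = dwell_time,
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 nucleolus_radius = nucleolus_radius,
                 chromatin_thickness = chromatin_thickness,
                 nucleolus_offset = nucleolus_offset,
                 n_aggregates = as.integer(n_aggregates),
                 aggregate_radius = aggregate_radius,
                 base_yields = base_yields, drug_load = drug_load,
                 ligand_number = ligand_number, rsf = rsf,
                 a_cddp = a_cddp, a_ctr = a_ctr,
                 shift = as.integer(shift),
                 exposure_concentration = exposure_concentration,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

.complete_compartment_vector <- function(x, default) {
  out <- stats::setNames(rep(default, length(.phantom_compartments)),
                         .phantom_compartments)
  unknown <- setdiff(names(x), .phantom_compartments)
  if (length(unknown)) stop("unknown compartment(s): ", paste(unknown, collapse = ", "))
  out[names(x)] <- x
  out
}

#' Write / read a phantom configuration as YAML
#' @param config A \code{\link{phantom_config}}.
#' @param path YAML file path.
#' @return \code{path} (write) or a \code{phantom_config} (read).
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(inherits(config, "phantom_config"))
  x <- unclass(config)
  x$base_yields <- list(rows = rownames(x$base_yields),
                        cols = colnames(x$base_yields),
                        values = unname(apply(x$base_yields, 1, as.list)))
  for (k in c("drug_load", "ligand_number", "rsf")) x[[k]] <- as.list(x[[k]])
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  x <- yaml::read_yaml(path)
  by <- do.call(rbind, lapply(x$base_yields$values, unlist))
  dimnames(by) <- list(unlist(x$base_yields$rows), unlist(x$base_yields$cols))
  phantom_config(grid = unlist(x$grid), pixel_size = x$pixel_size,
                 dwell_time = x$dwell_time, cell_radius = x$cell_radius,
                 nucleus_radius = x$nucleus_radius,
                 nucleolus_radius = x$nucleolus_radius,
                 chromatin_thickness = x$chromatin_thickness,
                 nucleolus_offset = x$nucleolus_offset,
                 n_aggregates = x$n_aggregates,
                 aggregate_radius = x$aggregate_radius,
                 base_yields = by, drug_load = unlist(x$drug_load),
                 ligand_number = unlist(x$ligand_number), rsf = unlist(x$rsf),
                 a_cddp = x$a_cddp, a_ctr = x$a_ctr, shift = unlist(x$shift),
                 exposure_concentration = x$exposure_concentration,
                 seed = x$seed)
}

# Build the label image and legend for a config. Aggregates are placed by a
# seeded rejection sampler in the cytoplasmic annulus, pairwise disjoint.
.phantom_geometry <- function(config) {
  g <- config$grid
  cr <- (g[1] + 1) / 2; cc <- (g[2] + 1) / 2
  rows <- matrix(seq_len(g[1]), g[1], g[2])
  cols <- matrix(seq_len(g[2]), g[1], g[2], byrow = TRUE)
  d_cell <- sqrt((rows - cr)^2 + (cols - cc)^2) * config$pixel_size
  # nucleolus centre offset at a fixed 45 degree direction
  no <- config$nucleolus_offset / sqrt(2) / config$pixel_size
  d_nucl <- sqrt((rows - cr - no)^2 + (cols - cc - no)^2) * config$pixel_size

  labels <- matrix(0L, g[1], g[2])
  labels[d_cell <= config$cell_radius] <- 1L                    # cytoplasm
  labels[d_cell <= config$nucleus_radius] <- 2L                 # nucleus
  rim_in <- config$nucleus_radius - config$chromatin_thickness
  labels[d_cell <= config$nucleus_radius & d_cell > rim_in] <- 4L  # chromatin
  labels[d_nucl <= config$nucleolus_radius] <- 3L               # nucleolus

  legend <- data.frame(label = 1:4,
                       roi_id = c("cytoplasm_1", "nucleus_1", "nucleolus_1",
                                  "chromatin_1"),
                       compartment = c("cytoplasm", "nucleus", "nucleolus",
                                       "chromatin"),
                       stringsAsFactors = FALSE)

  k <- config$n_aggregates
  if (k > 0) {
    set.seed(.derive_seed(config$seed, 7L))
    ar <- config$aggregate_radius
    r_lo <- config$nucleus_radius + ar + 0.2
    r_hi <- config$cell_radius - ar - 0.2
    if (r_hi <= r_lo) stop("no room for aggregates between nucleus and cell boundary")
    centres <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centres) < k && tries < 2000L) {
      tries <- tries + 1L
      rad <- sqrt(stats::runif(1, r_lo^2, r_hi^2))
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(rad * cos(th), rad * sin(th))
      if (nrow(centres) == 0 ||
          all(sqrt(colSums((t(centres) - p)^2)) > 2 * ar + 0.2))
        centres <- rbind(centres, p)
    }
    if (nrow(centres) < k)
      stop("could not place ", k, " non-overlapping aggregates; reduce count or radius")
    for (i in seq_len(k)) {
      dr <- centres[i, 1] / config$pixel_size
      dc <- centres[i, 2] / config$pixel_size
      d_agg <- sqrt((rows - cr - dr)^2 + (cols - cc - dc)^2) * config$pixel_size
      labels[d_agg <= ar] <- 4L + i
      legend <- rbind(legend, data.frame(label = 4L + i,
                                         roi_id = sprintf("aggregate_%d", i),
                                         compartment = "aggregate",
                                         stringsAsFactors = FALSE))
    }
  }
  compartment_mask(labels, legend)
}

# Closed-form per-compartment rates and truth for a config.
.phantom_rates <- function(config) {
  y <- config$base_yields
  d <- config$drug_load[.phantom_compartments]
  rsf_ratio <- unname(config$rsf["pt"] / config$rsf["n"])
  cn_drug <- config$ligand_number[.phantom_compartments] * d / rsf_ratio
  cn_tot <- y[, "CN"] + cn_drug
  x_true <- ifelse(cn_tot > 0, cn_drug / cn_tot, 0)
  a <- config$a_ctr + x_true * (config$a_cddp - config$a_ctr)
  q_true <- ifelse(cn_tot > 0, d / cn_tot, 0)
  list(
    pt_run = cbind("194Pt" = y[, "194Pt"] + d, "12C2" = y[, "12C2"],
                   "31P" = y[, "31P"], "34S" = y[, "34S"], "19F" = y[, "19F"]),
    n_run = cbind("12C14N" = (1 - a) * cn_tot, "12C15N" = a * cn_tot,
                  "12C2" = y[, "12C2"]),
    truth = data.frame(compartment = .phantom_compartments,
                       label_fraction = unname(x_true),
                       pt_index = unname(q_true),
                       abundance = unname(a),
                       stoichiometry = unname(config$ligand_number[.phantom_compartments]),
                       drug_load = unname(d),
                       row.names = NULL, stringsAsFactors = FALSE))
}

# Integer translation with zero fill; out[r, c] = in[r - dr, c - dc].
.translate <- function(m, shift, fill = 0L) {
  dr <- shift[1]; dc <- shift[2]
  out <- matrix(fill, nrow(m), ncol(m))
  r_dst <- intersect(seq_len(nrow(m)), seq_len(nrow(m)) + dr)
  c_dst <- intersect(seq_len(ncol(m)), seq_len(ncol(m)) + dc)
  if (length(r_dst) && length(c_dst))
    out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

#' Generate a synthetic paired acquisition with ground truth
#'
#' Every pixel count is drawn independently from a Poisson distribution whose
#' mean is the compartment's expected rate for that channel; the CN-
#' isotopologue split realises the 15N abundance
#' \eqn{a = a_{ctr} + x (a_{CDDP} - a_{ctr})} where \eqn{x} is the
#' compartment's true label fraction; the n_run geometry is translated by the
#' configured inter-run shift. Identical seeds give bit-identical output.
#'
#' @param config A \code{\link{phantom_config}}.
#' @param runs Which runs to generate (\code{"pt_run"}, \code{"n_run"});
#'   default both.
#' @param sample_id Sample identifier for the stacks.
#' @return A list with elements \code{pt_run} and/or \code{n_run}
#'   (\code{\link{acquisition_stack}}s) and \code{truth}, a list holding the
#'   pt-frame \code{mask}, the per-compartment closed-form truth table
#'   (\code{label_fraction}, \code{pt_index}, \code{abundance},
#'   \code{stoichiometry}, \code{drug_load}), and the applied \code{shift}.
#' @export
generate_phantom <- function(config, runs = c("pt_run", "n_run"),
                             sample_id = sprintf("phantom_seed%d", config$seed)) {
  stopifnot(inherits(config, "phantom_config"))
  runs <- match.arg(runs, several.ok = TRUE)
  mask <- .phantom_geometry(config)
  rates <- .phantom_rates(config)
  is_ctrl <- config$exposure_concentration == 0 && all(config$drug_load == 0)

  draw_run <- function(run, labels, run_idx) {
    rate_tab <- rates[[run]]
    comp_of_label <- c("background", mask$legend$compartment)[
      match(labels, c(0L, mask$legend$label))]
    maps <- vector("list", ncol(rate_tab))
    for (j in seq_len(ncol(rate_tab))) {
      lambda <- rate_tab[comp_of_label, j]
      set.seed(.derive_seed(config$seed, 100L * run_idx + j))
      cnt <- matrix(stats::rpois(length(lambda), lambda),
                    config$grid[1], config$grid[2])
      maps[[j]] <- ion_count_map(cnt, colnames(rate_tab)[j],
                                 pixel_size = config$pixel_size,
                                 dwell_time = config$dwell_time)
    }
    acquisition_stack(maps, sample_id = sample_id, run_type = run,
                      exposure_concentration = config$exposure_concentration,
                      is_control = is_ctrl)
  }

  out <- list()
  if ("pt_run" %in% runs)
    out$pt_run <- draw_run("pt_run", mask$labels, 1L)
  if ("n_run" %in% runs) {
    n_labels <- .translate(mask$labels, config$shift, 0L)
    out$n_run <- draw_run("n_run", n_labels, 2L)
  }
  out$truth <- list(mask = mask,
                    compartments = rates$truth,
                    shift = config$shift,
                    a_ctr = config$a_ctr, a_cddp = config$a_cddp,
                    rsf = config$rsf)
  out
}

#' Generate a phantom exposure-concentration series
#'
#' One phantom triple per exposure concentration, with drug loads given by a
#' monotone accumulation model (default: linear in concentration with the
#' package's per-compartment rates) and per-concentration seeds derived
#' deterministically from the base configuration's seed.
#'
#' @param base_config A \code{\link{phantom_config}}; its \code{drug_load} is
#'   replaced per concentration.
#' @param concentrations Non-negative exposure concentrations in uM; must
#'   include 0 (the negative control).
#' @param accumulation_model Function mapping one concentration to a named
#'   per-compartment drug load (expected 194Pt- counts/pixel); must be
#'   monotone non-decreasing in concentration per compartment.
#' @return A list with one element per concentration (in the given order),
#'   each as returned by \code{\link{generate_phantom}} plus a
#'   \code{concentration} field.
#' @export
nested_exposure_series <- function(base_config, concentrations,
                                   accumulation_model = NULL) {
  stopifnot(inherits(base_config, "phantom_config"))
  if (length(concentrations) == 0) stop("empty concentration list")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (!any(concentrations == 0))
    stop("the series must include the 0 uM negative control")
  if (is.null(accumulation_model))
    accumulation_model <- function(conc) .default_drug_rates * conc
  loads <- lapply(concentrations, accumulation_model)
  ord <- order(concentrations)
  lm_mat <- do.call(rbind, lapply(loads[ord], .complete_compartment_vector, 0))
  if (any(apply(lm_mat, 2, function(v) any(diff(v) < -1e-12))))
    stop("accumulation model must be monotone non-decreasing in concentration")
  out <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    cfg <- base_config
    cfg$drug_load <- .complete_compartment_vector(loads[[i]], 0)
    cfg$exposure_concentration <- concentrations[i]
    cfg$seed <- .derive_seed(base_config$seed, 1000L + i)
    tri <- generate_phantom(cfg,
                            sample_id = sprintf("phantom_s%d_c%g",
                                                base_config$seed,
                                                concentrations[i]))
    tri$concentration <- concentrations[i]
    out[[i]] <- tri
  }
  out
}
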