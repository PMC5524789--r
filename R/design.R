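#' Experimental design for a blocked plate/panel transplant experiment
#'
#' Describes the layout of a field transplant experiment: temporal blocks,
#' backing panels within blocks, settlement plates within panels, and one or
#' more replicates of each treatment per plate. The default reproduces the
#' study design this package emulates: 4 blocks x 4 panels x 12 plates x
#' 6 treatments x 1 replicate = 1152 settlers, i.e. 192 replicates per
#' treatment (48 per treatment per block).
#'
#' @param n_blocks Number of temporal blocks (>= 1).
#' @param panels_per_block Number of panels per block (>= 1).
#' @param plates_per_panel Number of plates per panel (>= 1).
#' @param treatments Character vector of unique treatment labels; the first
#'   is the control/reference level.
#' @param replicates_per_plate_per_treatment Replicates of each treatment on
#'   each plate (>= 1).
#' @return An object of class `ms_design`.
#' @export
experiment_design <- function(n_blocks = 4L,
                              panels_per_block = 4L,
                              plates_per_panel = 12L,
                              treatments = c("control", "delay", "salinity",
                                             "heat", "copper", "multiple"),
                              replicates_per_plate_per_treatment = 1L) {
  chk_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        x < 1 || x != round(x)) {
      stop(sprintf("invalid design field '%s': must be an integer >= 1", name),
           call. = FALSE)
    }
    as.integer(x)
  }
  n_blocks <- chk_count(n_blocks, "n_blocks")
  panels_per_block <- chk_count(panels_per_block, "panels_per_block")
  plates_per_panel <- chk_count(plates_per_panel, "plates_per_panel")
  replicates_per_plate_per_treatment <-
    chk_count(replicates_per_plate_per_treatment,
              "replicates_per_plate_per_treatment")
  if (!is.character(treatments) || length(treatments) < 1 ||
      anyDuplicated(treatments) > 0 || any(!nzchar(treatments))) {
    stop("invalid design field 'treatments': must be unique non-empty labels",
         call. = FALSE)
  }
  structure(
    list(n_blocks = n_blocks,
         panels_per_block = panels_per_block,
         plates_per_panel = plates_per_panel,
         treatments = treatments,
         replicates_per_plate_per_treatment =
           replicates_per_plate_per_treatment),
    class = "ms_design")
}

#' @export
print.ms_design <- function(x, ...) {
  cat("Experiment design:", x$n_blocks, "block(s) x", x$panels_per_block,
      "panel(s) x", x$plates_per_panel, "plate(s),",
      length(x$treatments), "treatments x",
      x$replicates_per_plate_per_treatment, "replicate(s) per plate\n")
  cat("Treatments (control first):", paste(x$treatments, collapse = ", "),
      "\n")
  cat("Total records:", total_records(x), "\n")
  invisible(x)
}

total_records <- function(design) {
  design$n_blocks * design$panels_per_block * design$plates_per_panel *
    length(design$treatments) * design$replicates_per_plate_per_treatment
}

# occupants per plate
plate_occupancy <- function(design) {
  length(design$treatments) * design$replicates_per_plate_per_treatment
}

#' Treatment presets
#'
#' Physical configuration of the six stressor treatments: larval settlement
#' delay (hours), salinity (psu), water temperature (degrees C), and
#' dissolved copper (ug/L). These are metadata used for labelling and run
#' logs only; treatment effects on outcomes are expressed as model
#' coefficients, not derived from these levels.
#'
#' @return A data.frame with one row per treatment.
#' @export
treatment_presets <- function() {
  data.frame(
    treatment   = c("control", "delay", "salinity", "heat", "copper",
                    "multiple"),
    larval_delay_h = c(0, 2, 0, 0, 0, 2),
    salinity_psu   = c(36, 36, 30, 36, 36, 30),
    temperature_c  = c(17.5, 17.5, 17.5, 22, 17.5, 22),
    copper_ugL     = c(0, 0, 0, 0, 65, 65),
    stringsAsFactors = FALSE
  )
}

#' Generate the design skeleton
#'
#' Expands an [experiment_design()] into one row per settler with design
#' coordinates (block, panel, plate, treatment) and empty outcome columns.
#' Panels and plates receive globally unique identifiers (`b<i>p<j>` and
#' `b<i>p<j>l<k>`) so that panel enters downstream models as a single
#' categorical factor with `n_blocks * panels_per_block` levels.
#'
#' Ordering is deterministic: block, then panel, then plate, then treatment
#' in the order listed, then replicate.
#'
#' @param design An `ms_design`.
#' @return A data.frame with columns block, panel, plate, treatment,
#'   survived, size, fecundity, density (outcomes all NA).
#' @export
generate_design <- function(design) {
  if (!inherits(design, "ms_design")) design <- do.call(experiment_design, design)
  rows <- expand.grid(
    rep = seq_len(design$replicates_per_plate_per_treatment),
    treatment = design$treatments,
    plate_i = seq_len(design$plates_per_panel),
    panel_i = seq_len(design$panels_per_block),
    block = seq_len(design$n_blocks),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # expand.grid varies the first factor fastest; reorder columns to the
  # documented block > panel > plate > treatment ordering
  rows <- rows[order(rows$block, rows$panel_i, rows$plate_i,
                     match(rows$treatment, design$treatments), rows$rep), ]
  out <- data.frame(
    block = rows$block,
    panel = sprintf("b%dp%d", rows$block, rows$panel_i),
    plate = sprintf("b%dp%dl%d", rows$block, rows$panel_i, rows$plate_i),
    treatment = rows$treatment,
    survived = NA_integer_,
    size = NA_integer_,
    fecundity = NA_real_,
    density = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}
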