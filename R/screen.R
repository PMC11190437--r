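#' Control baselines for the inclusion gate
#'
#' The gate references three control proteins: a distal-end basal-body
#' marker (POC5) and a transition-zone marker (TZP150) bound the axial
#' distance window, and a basal-body-barrel protein (BBP136) sets the
#' minimum lateral pseudo-diameter.
#'
#' @param poc5_mean_distance_nm mean distance of the proximal control, nm.
#' @param tzp150_mean_distance_nm mean distance of the distal control, nm;
#'   must exceed the proximal control.
#' @param bbp136_mean_pseudo_diameter_nm mean pseudo-diameter of the
#'   barrel-width control, nm.
#' @return object of class `control_baselines`.
#' @export
control_baselines <- function(poc5_mean_distance_nm,
                              tzp150_mean_distance_nm,
                              bbp136_mean_pseudo_diameter_nm) {
  if (!all(c(poc5_mean_distance_nm, tzp150_mean_distance_nm,
             bbp136_mean_pseudo_diameter_nm) > 0))
    stop("baselines must be positive")
  if (poc5_mean_distance_nm >= tzp150_mean_distance_nm)
    stop("proximal control mean must be below the distal control mean")
  structure(list(poc5_mean_distance_nm = poc5_mean_distance_nm,
                 tzp150_mean_distance_nm = tzp150_mean_distance_nm,
                 bbp136_mean_pseudo_diameter_nm = bbp136_mean_pseudo_diameter_nm),
            class = "control_baselines")
}

#' Apply the screen's inclusion gate
#'
#' A candidate is included only if its mean distance from the basal-body
#' marker is strictly beyond the proximal control, strictly short of the
#' transition-zone control, and its mean pseudo-diameter strictly exceeds
#' the barrel-width control. Comparisons use protein-level means; boundary
#' values are excluded (strict inequalities).
#'
#' @param metrology data frame from [aggregate_metrology()].
#' @param baselines a [control_baselines()].
#' @return the metrology data frame with a `gate_verdict` factor column:
#'   `included`, `excluded_proximal`, `excluded_distal`, `excluded_narrow`,
#'   or `unclassified` (missing metrology, with a warning).
#' @export
apply_inclusion_gate <- function(metrology, baselines) {
  stopifnot(inherits(baselines, "control_baselines"))
  verdict <- character(nrow(metrology))
  for (i in seq_len(nrow(metrology))) {
    d <- metrology$mean_distance_nm[i]
    w <- metrology$mean_pseudo_diameter_nm[i]
    verdict[i] <- if (is.na(d) || is.na(w)) "unclassified"
      else if (d <= baselines$poc5_mean_distance_nm) "excluded_proximal"
      else if (d >= baselines$tzp150_mean_distance_nm) "excluded_distal"
      else if (w <= baselines$bbp136_mean_pseudo_diameter_nm) "excluded_narrow"
      else "included"
  }
  if (any(verdict == "unclassified"))
    warning("candidate(s) with missing metrology left unclassified")
  metrology$gate_verdict <- factor(verdict,
    levels = c("included", "excluded_proximal", "excluded_distal",
               "excluded_narrow", "unclassified"))
  metrology
}

#' Classify recruitment timing from per-cell focus-count observations
#'
#' Cells with two red (marker) foci are pre-duplication (G1 or G1/S); four
#' red foci mark S phase. The classes, checked in order:
#' * `probasal` - at least `min_fraction` of S-phase cells show green
#'   signal on probasal bodies (recruitment in the previous cell cycle);
#' * `before_duplication` - at least `min_fraction` of two-red-foci cells
#'   already show two or more green foci;
#' * `after_duplication` - a second green focus is (essentially) only seen
#'   once four red foci are present;
#' * otherwise `unclassified`.
#'
#' @param observations data frame: `red_focus_count` (2 or 4),
#'   `green_focus_count`, `green_on_probasal` (logical).
#' @param min_fraction detection fraction for a positive call (default
#'   0.25, accommodating probasal recruitment seen in about a third of
#'   early-S cells).
#' @return character scalar, one of the four classes.
#' @export
classify_recruitment <- function(observations, min_fraction = 0.25) {
  stopifnot(all(c("red_focus_count", "green_focus_count",
                  "green_on_probasal") %in% names(observations)))
  if (!all(observations$red_focus_count %in% c(2L, 4L)))
    stop("red_focus_count must be 2 or 4")
  pre <- observations$red_focus_count == 2L
  s <- observations$red_focus_count == 4L
  if (nrow(observations) < 10L || !any(pre) || !any(s)) {
    warning("need >= 10 observations spanning both red-focus counts")
    return("unclassified")
  }
  frac_probasal <- mean(observations$green_on_probasal[s])
  frac_pre2 <- mean(observations$green_focus_count[pre] >= 2L)
  frac_s2 <- mean(observations$green_focus_count[s] >= 2L)
  if (frac_probasal >= min_fraction) return("probasal")
  if (frac_pre2 >= min_fraction) return("before_duplication")
  if (frac_s2 >= min_fraction && frac_pre2 < min_fraction)
    return("after_duplication")
  "unclassified"
}

#' Read a 12-column tabular alignment hit table
#'
#' Standard tab-separated alignment output (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score). Malformed rows are skipped with
#' a message.
#'
#' @param path file path.
#' @return data frame: `query_id`, `subject_id`, `e_value`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) stop("expected a 12-column tabular hit table")
  out <- data.frame(query_id = as.character(raw[[1]]),
                    subject_id = as.character(raw[[2]]),
                    e_value = suppressWarnings(as.numeric(raw[[11]])),
                    bitscore = suppressWarnings(as.numeric(raw[[12]])))
  bad <- is.na(out$e_value) | is.na(out$bitscore) | out$e_value < 0
  if (any(bad)) message(sum(bad), " malformed hit row(s) skipped")
  out[!bad, , drop = FALSE]
}

# best hit per query: lowest E-value, then higher bitscore, then
# lexicographic subject id
.best_hits <- function(hits) {
  o <- order(hits$query_id, hits$e_value, -hits$bitscore, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Reciprocal best hits between two genomes
#'
#' A pair (a, b) is an orthologue pair when b is a's best hit in the
#' A-to-B table, a is b's best hit in the B-to-A table, and both hits have
#' E-value at or below the threshold. Each id appears in at most one pair.
#'
#' @param hits_ab,hits_ba hit data frames (see [read_hit_table()]):
#'   `query_id`, `subject_id`, `e_value`, `bitscore`.
#' @param e_threshold E-value acceptance threshold (default 1e-5).
#' @return data frame: `id_a`, `id_b`, `e_value_ab`, `e_value_ba`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, e_threshold = 1e-5) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      e_value_ab = numeric(), e_value_ba = numeric())
  if (!nrow(hits_ab) || !nrow(hits_ba)) return(empty)
  ba <- .best_hits(hits_ab)
  bb <- .best_hits(hits_ba)
  ba <- ba[ba$e_value <= e_threshold, , drop = FALSE]
  bb <- bb[bb$e_value <= e_threshold, , drop = FALSE]
  if (!nrow(ba) || !nrow(bb)) return(empty)
  m <- merge(ba, bb, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"),
             suffixes = c("_ab", "_ba"))
  if (!nrow(m)) return(empty)
  out <- data.frame(id_a = m$query_id, id_b = m$subject_id,
                    e_value_ab = m$e_value_ab, e_value_ba = m$e_value_ba)
  out[order(out$id_a), , drop = FALSE]
}

#' Class counts across the screen's classification axes
#'
#' Tabulates candidate records on each axis (recruitment timing,
#' new/old-flagellum intensity bias, evolutionary conservation, knockdown
#' phenotype) with fixed level sets, so absent classes count zero and the
#' per-axis totals equal the record count.
#'
#' @param records data frame with columns `recruitment_class`,
#'   `flagellum_bias`, `conservation`, `rnai_phenotype` (any subset).
#' @return list: `total` plus one named integer vector per present axis.
#' @export
summarize_classes <- function(records) {
  levels_of <- list(
    recruitment_class = c("before_duplication", "after_duplication",
                          "probasal", "unclassified"),
    flagellum_bias = c("old_enriched", "new_enriched", "equal", "untested"),
    conservation = c("beyond_kinetoplastids", "kinetoplastid_only", "unknown"),
    rnai_phenotype = c("assembly_defect", "length_defect",
                       "growth_defect_only", "none", "untested"))
  out <- list(total = nrow(records))
  for (ax in names(levels_of)) {
    if (!ax %in% names(records)) next
    tab <- table(factor(records[[ax]], levels = levels_of[[ax]]))
    out[[ax]] <- stats::setNames(as.integer(tab), names(tab))
  }
  out
}

#' Length of an ideal alpha-helix
#'
#' `length_nm = n_residues / residues_per_turn * pitch_angstrom / 10`:
#' 1000 residues at the canonical 5.4 A pitch and 3.6 residues per turn
#' give a 150 nm helix.
#'
#' @param n_residues number of amino acids (>= 0).
#' @param pitch_angstrom helix pitch, Angstrom per turn.
#' @param residues_per_turn residues per helical turn.
#' @return helix length in nm.
#' @export
helix_length <- function(n_residues, pitch_angstrom = 5.4,
                         residues_per_turn = 3.6) {
  if (any(n_residues < 0)) stop("n_residues must be nonnegative")
  if (pitch_angstrom <= 0 || residues_per_turn <= 0)
    stop("pitch and residues per turn must be positive")
  n_residues / residues_per_turn * pitch_angstrom / 10
}

#' Published per-protein screen assignments
#'
#' The screen's outcome table for the 30 transition-fibre proteins:
#' recruitment timing, new/old-flagellum intensity bias, conservation
#' beyond kinetoplastids, and inducible-knockdown phenotype. Shipped as a
#' plain-text fixture in `inst/extdata`.
#'
#' @return data frame, one row per protein.
#' @export
tfp_screen_table <- function() {
  path <- system.file("extdata", "tfp_screen_assignments.csv",
                      package = "tfscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
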