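#' Oxidation efficiency of a peptide
#'
#' Fraction of a peptide pool carrying the oxidative modification,
#' `Oxi% = I_oxi / (I_oxi + I_naked)`, computed from summed MS1+MS2
#' intensities of the oxidized and unmodified (naked) forms.
#'
#' @param intensity_oxi Summed intensity of the oxidized peptide (>= 0).
#' @param intensity_naked Summed intensity of the unmodified peptide (>= 0).
#' @return Oxidation fraction in `[0, 1]`. Vectorised.
#' @examples
#' oxidation_level(100, 300)  # 0.25
#' @export
oxidation_level <- function(intensity_oxi, intensity_naked) {
  stopifnot(is.numeric(intensity_oxi), is.numeric(intensity_naked))
  if (any(intensity_oxi < 0, na.rm = TRUE) || any(intensity_naked < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  total <- intensity_oxi + intensity_naked
  if (any(total == 0, na.rm = TRUE))
    stop("undefined oxidation level: oxidized and unmodified intensities are both zero")
  intensity_oxi / total
}

#' Relative oxidation of the treated condition against controls
#'
#' Ratio of the oxidation efficiency under hydroxyl-radical treatment (O)
#' to the summed efficiencies of the two controls: untreated (C) and
#' Fe(II)-EDTA only (F). Controls are taken at the same temperature as the
#' treated sample and are summed without renormalisation.
#'
#' @param oxi_o Oxidation fraction under the oxidizing condition.
#' @param oxi_c Oxidation fraction in the untreated control.
#' @param oxi_f Oxidation fraction in the Fe(II)-EDTA control.
#' @return Non-negative ratio. Vectorised.
#' @export
relative_oxidation <- function(oxi_o, oxi_c, oxi_f) {
  denom <- oxi_c + oxi_f
  if (any(denom <= 0, na.rm = TRUE))
    stop("undefined relative oxidation: control oxidation levels sum to zero")
  oxi_o / denom
}

#' Cold/warm fold change of relative oxidation
#'
#' `FC = Relative Oxi%(4 degC) / Relative Oxi%(30 degC)`. Values above 1
#' indicate a residue more exposed to solvent in the cold (activated)
#' state; values below 1 indicate burial.
#'
#' @param rel_4c Relative oxidation at 4 degC.
#' @param rel_30c Relative oxidation at 30 degC (> 0).
#' @return Positive fold change. Vectorised.
#' @export
fold_change <- function(rel_4c, rel_30c) {
  if (any(rel_30c <= 0, na.rm = TRUE))
    stop("undefined fold change: relative oxidation at 30 degC must be > 0")
  rel_4c / rel_30c
}

#' Classify an exposure change from its fold change
#'
#' Strict thresholds as used in hydroxyl-radical footprinting practice:
#' `FC > upper` is called "more_exposed", `FC < lower` "more_buried",
#' anything in between (boundaries included) "unchanged". The defaults
#' (1.20 / 0.83) represent a +/-20 percent change and absorb typical
#' inter-replicate MS variability. Note that with these defaults a
#' fold change of 0.87 is "unchanged" even though such values are
#' sometimes discussed as burial trends; thresholds are configurable.
#'
#' @param fc Positive fold change (vectorised).
#' @param upper Upper threshold (default 1.20).
#' @param lower Lower threshold (default 0.83); must satisfy `lower < upper`.
#' @return Character vector in `{more_exposed, more_buried, unchanged}`,
#'   `NA` where `fc` is `NA`.
#' @examples
#' call_exposure_change(c(1.25, 1.0, 0.80, 0.87))
#' @export
call_exposure_change <- function(fc, upper = 1.20, lower = 0.83) {
  if (!is.numeric(upper) || !is.numeric(lower) || lower >= upper || lower <= 0)
    stop("thresholds must satisfy 0 < lower < upper")
  if (any(fc <= 0, na.rm = TRUE)) stop("fold changes must be positive")
  out <- rep(NA_character_, length(fc))
  ok <- !is.na(fc)
  out[ok] <- ifelse(fc[ok] > upper, "more_exposed",
                    ifelse(fc[ok] < lower, "more_buried", "unchanged"))
  out
}

peptide_cols <- c("peptide_sequence", "protein_position", "oxidized_residue",
                  "n_oxidations_on_peptide", "condition", "temperature_C",
                  "replicate", "intensity")

validate_peptide_table <- function(table) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(peptide_cols, names(table))
  if (length(missing))
    stop("peptide table is missing columns: ", paste(missing, collapse = ", "))
  if (any(table$intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (!all(table$condition %in% c("C", "F", "O")))
    stop("condition must be one of C, F, O")
  span_end <- table$protein_position + nchar(table$peptide_sequence) - 1L
  oxi <- !is.na(table$oxidized_residue)
  if (any(oxi & (table$oxidized_residue < table$protein_position |
                 table$oxidized_residue > span_end)))
    stop("oxidized_residue must lie within the peptide span")
  invisible(table)
}

#' Keep only singly-oxidized (and unmodified) peptide records
#'
#' Site-level quantification requires unambiguous attribution of the
#' oxidation signal, so peptide records carrying more than one oxidation
#' are dropped. Unmodified records (`n_oxidations_on_peptide == 0`) are
#' always retained: they supply the "naked" denominator for every site
#' the peptide covers.
#'
#' @param table Peptide intensity table (see [simulate_footprint()] for the
#'   schema).
#' @return The filtered table, rows preserved in input order.
#' @export
filter_single_oxidation <- function(table) {
  validate_peptide_table(table)
  table[table$n_oxidations_on_peptide <= 1L, , drop = FALSE]
}

## Per-replicate Oxi% for one residue under one condition/temperature.
## The oxidized intensity sums records naming the residue as the single
## oxidation site; the naked intensity sums the unmodified partners of
## exactly those peptides (same sequence and span, charge-agnostic), so
## each peptide pool's bookkeeping stays self-contained.
residue_oxi_fraction <- function(table, residue, condition, temperature, replicate) {
  sel <- table$condition == condition & table$temperature_C == temperature &
    table$replicate == replicate
  oxi_rows <- sel & !is.na(table$oxidized_residue) & table$oxidized_residue == residue
  if (!any(oxi_rows)) return(NA_real_)
  keys <- paste(table$peptide_sequence, table$protein_position)
  oxi_keys <- unique(keys[oxi_rows])
  nak_rows <- sel & table$n_oxidations_on_peptide == 0L & keys %in% oxi_keys
  i_oxi <- sum(table$intensity[oxi_rows])
  i_nak <- sum(table$intensity[nak_rows])
  if ((i_oxi + i_nak) == 0) return(NA_real_)
  oxidation_level(i_oxi, i_nak)
}

#' Residue-level fold changes and exposure calls from a peptide table
#'
#' Runs the full footprinting quantification: single-oxidation filtering,
#' per-replicate oxidation efficiency per condition (C, F, O) and
#' temperature (4 and 30 degC), relative oxidation against the summed
#' per-temperature controls, the 4/30 degC fold change, replicate
#' aggregation (mean +/- s.e.m.), and the exposure call on the mean.
#'
#' Replicates in which a residue lacks either oxidized signal or control
#' coverage contribute no fold change; residues with no defined fold
#' change in any replicate are dropped with a warning.
#'
#' @param table Peptide intensity table.
#' @param upper,lower Classification thresholds, see [call_exposure_change()].
#' @param method `"per_replicate"` (default) computes one FC per replicate
#'   and averages; `"pooled"` sums intensities across replicates first and
#'   reports a single FC (no s.e.m.).
#' @return A data.frame with one row per residue: `residue`, `fc_mean`,
#'   `fc_sem` (`NA` when fewer than 2 detections), `n_detections`, `call`.
#' @export
residue_fc_table <- function(table, upper = 1.20, lower = 0.83,
                             method = c("per_replicate", "pooled")) {
  method <- match.arg(method)
  table <- filter_single_oxidation(table)
  residues <- sort(unique(table$oxidized_residue[!is.na(table$oxidized_residue)]))
  replicates <- sort(unique(table$replicate))
  if (method == "pooled") {
    pooled <- table
    pooled$replicate <- 1L
    pooled <- stats::aggregate(
      intensity ~ peptide_sequence + protein_position + oxidized_residue +
        n_oxidations_on_peptide + condition + temperature_C + replicate,
      data = transform(table, replicate = 1L,
                       oxidized_residue = ifelse(is.na(oxidized_residue), -1L,
                                                 oxidized_residue)),
      FUN = sum)
    pooled$oxidized_residue[pooled$oxidized_residue == -1L] <- NA_integer_
    table <- pooled
    replicates <- 1L
  }
  rows <- lapply(residues, function(res) {
    fcs <- vapply(replicates, function(rep) {
      ox <- vapply(c("C", "F", "O"), function(cond) {
        c(residue_oxi_fraction(table, res, cond, 4, rep),
          residue_oxi_fraction(table, res, cond, 30, rep))
      }, numeric(2))
      if (anyNA(ox)) return(NA_real_)
      rel4 <- tryCatch(relative_oxidation(ox[1, "O"], ox[1, "C"], ox[1, "F"]),
                       error = function(e) NA_real_)
      rel30 <- tryCatch(relative_oxidation(ox[2, "O"], ox[2, "C"], ox[2, "F"]),
                        error = function(e) NA_real_)
      if (is.na(rel4) || is.na(rel30) || rel30 <= 0) return(NA_real_)
      fold_change(rel4, rel30)
    }, numeric(1))
    fcs <- fcs[!is.na(fcs)]
    n <- length(fcs)
    if (n == 0L) return(NULL)
    data.frame(residue = res,
               fc_mean = mean(fcs),
               fc_sem = if (n >= 2L) stats::sd(fcs) / sqrt(n) else NA_real_,
               n_detections = n,
               call = call_exposure_change(mean(fcs), upper, lower))
  })
  dropped <- residues[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("residues without usable control/oxidized coverage dropped: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(residue = integer(), fc_mean = numeric(),
                      fc_sem = numeric(), n_detections = integer(),
                      call = character())
  rownames(out) <- NULL
  out
}

#' Read / write peptide intensity tables
#'
#' Plain TSV with a mandatory header row, UTF-8, dot decimal separator,
#' columns `peptide_sequence, protein_position, oxidized_residue,
#' n_oxidations_on_peptide, condition, temperature_C, replicate, intensity`.
#'
#' @param path File path.
#' @param table Peptide intensity table.
#' @return `read_peptide_table()` returns the validated data.frame;
#'   `write_peptide_table()` returns `path` invisibly.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_peptide_table(tab)
  tab
}

#' @rdname read_peptide_table
#' @export
write_peptide_table <- function(table, path) {
  validate_peptide_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
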