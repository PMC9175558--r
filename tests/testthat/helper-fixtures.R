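# Small in-code fixtures shared across test files.

# Long-format measurement table: n_wells wells on one plate, each with the
# given times and ODs (od may be a function(well_index, time) or a matrix).
tiny_measurements <- function(wells = c("A1", "A2"), times = c(0, 4),
                              od = function(w, t) 0.1 + 0.01 * w + 0.001 * t,
                              plate_id = "P01") {
  grid <- expand.grid(w = seq_along(wells), t = times)
  data.frame(plate_id = plate_id, well = wells[grid$w], time_h = grid$t,
             od600 = mapply(od, grid$w, grid$t), stringsAsFactors = FALSE)
}

tiny_annotations <- function(wells, plate_id = "P01", strain = "sdh1",
                             medium = "ISE", compound_id = NA_character_,
                             role = "negative_control",
                             concentration_uM = 0) {
  data.frame(plate_id = plate_id, well = wells, strain = strain,
             medium = medium, compound_id = compound_id,
             concentration_uM = concentration_uM, role = role,
             stringsAsFactors = FALSE)
}

tiny_library <- function(ids, contains_sulfate = FALSE,
                         colored_solution = FALSE) {
  data.frame(compound_id = ids, name = paste0("cmp-", ids),
             contains_sulfate = contains_sulfate,
             colored_solution = colored_solution, stock_mM = 10,
             stringsAsFactors = FALSE)
}

# Assemble a diff_result-shaped table from explicit significance structure;
# used where printed summary counts are the input to a set operation.
make_diff <- function(universe, sig_ids, lfc_sign = NULL) {
  sig <- universe %in% sig_ids
  lfc <- ifelse(sig, 2, 0.1)
  if (!is.null(lfc_sign)) lfc <- lfc * lfc_sign
  d <- data.frame(protein_id = universe, log2fc = lfc,
                  p = ifelse(sig, 1e-6, 0.5),
                  p_adjusted = ifelse(sig, 1e-5, 0.8),
                  significant = sig, floored = FALSE,
                  stringsAsFactors = FALSE)
  class(d) <- c("diff_result", class(d))
  d
}

# A growth-effects table covering all 8 strain x medium cells with a given
# significance/direction pattern (list of strain.medium -> pct).
make_effects <- function(compound_id, sig_cells = list(),
                         pct_cells = list()) {
  grid <- expand.grid(strain = c("WT", "sdh1", "sdh2", "jlp1"),
                      medium = c("AS", "ISE"), stringsAsFactors = FALSE)
  key <- paste(grid$strain, grid$medium, sep = ".")
  pct <- vapply(key, function(k) pct_cells[[k]] %||% 0, numeric(1))
  sig <- vapply(key, function(k) isTRUE(sig_cells[[k]]), logical(1))
  data.frame(strain = grid$strain, medium = grid$medium,
             compound_id = compound_id, concentration_uM = 25,
             pct_change = pct, pct_change_err = 1, n_replicates = 4,
             treated_mean = 0.5, treated_sd = 0.01, untreated_mean = 0.5,
             untreated_sd = 0.01,
             p_adjusted = ifelse(sig, 0.001, 0.6), significant = sig,
             stars = ifelse(sig, "**", "ns"), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
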