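#' @title Synthetic screen, proteome and metabolite data with planted truth
#' @description
#' The generator emulates the statistical structure the analysis assumes:
#' four strains (WT, sdh1, sdh2, jlp1) growing in two media (AS, ISE) over
#' 24 h; a 1280-compound library screened at 80 compounds per plate as
#' single wells against 4 vehicle-control wells; mitochondrial proteomes
#' with ~1000 differential proteins mostly shared between the two SDH-loss
#' mutants; and metabolite panels with succinate elevated up to ~5-fold and
#' 2-ketoglutarate reduced in the mutants. Every planted entity carries a
#' ground-truth record so downstream recovery can be measured.
#' @name synthetic_data
NULL

#' Default growth kinetics per strain and medium
#'
#' Noiseless growth is a sum of one or two logistic terms,
#' `od0 + cap1 * plogis(rate1 * (t - mid1)) (+ cap2 * plogis(rate2 * (t - mid2)))`,
#' the minimal family with an identifiable inter-phase deceleration (diauxic
#' shift). Defaults are calibrated qualitatively: in AS all strains reach
#' similar 24-h density with WT and jlp1 showing the diauxic second phase;
#' in ISE the ordering is WT > sdh1 ~ sdh2 > jlp1 with jlp1 near-flat, and
#' the SDH-loss strains grow by a single (fermentative) phase that
#' saturates early.
#'
#' @return data.frame with one row per strain x medium and columns `strain`,
#'   `medium`, `od0`, `cap1`, `rate1`, `mid1`, `cap2`, `rate2`, `mid2`,
#'   `diauxic`.
#' @export
default_kinetics <- function() {
  k <- rbind(
    data.frame(strain = "WT",   medium = "AS",  od0 = 0.05, cap1 = 1.00,
               rate1 = 0.9, mid1 = 3.0, cap2 = 0.30, rate2 = 0.6,
               mid2 = 15.0, diauxic = TRUE),
    data.frame(strain = "jlp1", medium = "AS",  od0 = 0.05, cap1 = 1.00,
               rate1 = 0.9, mid1 = 3.0, cap2 = 0.30, rate2 = 0.6,
               mid2 = 15.0, diauxic = TRUE),
    data.frame(strain = "sdh1", medium = "AS",  od0 = 0.05, cap1 = 1.25,
               rate1 = 0.9, mid1 = 3.5, cap2 = 0, rate2 = 0, mid2 = 0,
               diauxic = FALSE),
    data.frame(strain = "sdh2", medium = "AS",  od0 = 0.05, cap1 = 1.25,
               rate1 = 0.9, mid1 = 3.5, cap2 = 0, rate2 = 0, mid2 = 0,
               diauxic = FALSE),
    data.frame(strain = "WT",   medium = "ISE", od0 = 0.05, cap1 = 1.00,
               rate1 = 1.2, mid1 = 1.5, cap2 = 0.30, rate2 = 0.6,
               mid2 = 14.0, diauxic = TRUE),
    data.frame(strain = "sdh1", medium = "ISE", od0 = 0.05, cap1 = 0.90,
               rate1 = 1.2, mid1 = 1.5, cap2 = 0, rate2 = 0, mid2 = 0,
               diauxic = FALSE),
    data.frame(strain = "sdh2", medium = "ISE", od0 = 0.05, cap1 = 0.90,
               rate1 = 1.2, mid1 = 1.5, cap2 = 0, rate2 = 0, mid2 = 0,
               diauxic = FALSE),
    data.frame(strain = "jlp1", medium = "ISE", od0 = 0.05, cap1 = 0.05,
               rate1 = 0.3, mid1 = 8.0, cap2 = 0, rate2 = 0, mid2 = 0,
               diauxic = FALSE))
  rownames(k) <- NULL
  k
}

#' Look up one strain x medium kinetics row
#' @param strain,medium strain and medium level.
#' @param kinetics kinetics table, defaults to [default_kinetics()].
#' @return single-row data.frame.
#' @export
strain_kinetics <- function(strain, medium, kinetics = default_kinetics()) {
  i <- which(kinetics$strain == strain & kinetics$medium == medium)
  if (length(i) != 1L) {
    ss_stop("no kinetics defined for strain '", strain, "' in medium '",
            medium, "'")
  }
  kin <- kinetics[i, , drop = FALSE]
  if (kin$diauxic && !(kin$cap2 > 0 && kin$mid2 > kin$mid1)) {
    ss_stop("diauxic kinetics require cap2 > 0 and mid2 > mid1")
  }
  kin
}

#' Construct a compound-effect table
#'
#' @param compound_id character ids.
#' @param effect_class one of `inert`, `suppressor`, `sulfate_bypass`,
#'   `toxic`, `colored` (recycled).
#' @param magnitude fractional capacity change for growth effects (e.g.
#'   `+0.15`); for `colored`, the constant OD600 offset the pigment adds.
#' @param target_strains,target_media comma-separated target sets (recycled);
#'   defaults: suppressors hit `sdh1,sdh2` in `ISE`, every other class hits
#'   all strains in both media.
#' @return data.frame usable as the `effects` argument of the simulators.
#' @export
compound_effects <- function(compound_id, effect_class = "inert",
                             magnitude = 0, target_strains = NULL,
                             target_media = NULL) {
  classes <- c("inert", "suppressor", "sulfate_bypass", "toxic", "colored")
  if (!all(effect_class %in% classes)) {
    ss_stop("unknown effect_class; must be one of ",
            paste(classes, collapse = ", "))
  }
  n <- length(compound_id)
  effect_class <- rep_len(effect_class, n)
  magnitude <- rep_len(magnitude, n)
  ts <- rep_len(target_strains %||%
                  ifelse(effect_class == "suppressor", "sdh1,sdh2",
                         paste(ss_strains(), collapse = ",")), n)
  tm <- rep_len(target_media %||%
                  ifelse(effect_class == "suppressor", "ISE",
                         paste(ss_media(), collapse = ",")), n)
  data.frame(compound_id = as.character(compound_id),
             effect_class = effect_class, magnitude = magnitude,
             target_strains = ts, target_media = tm,
             stringsAsFactors = FALSE)
}

effect_applies <- function(effect, strain, medium) {
  strain %in% strsplit(effect$target_strains, ",")[[1]] &&
    medium %in% strsplit(effect$target_media, ",")[[1]]
}

#' Simulate one well's OD600 growth series
#'
#' Applies a compound effect to the strain's logistic capacities when the
#' effect targets the well's strain and medium: `suppressor` / `toxic` /
#' `inert` scale the capacities by `1 + magnitude`; `sulfate_bypass` moves
#' the total capacity a fraction `magnitude` of the way toward the same
#' strain's sulfur-replete (AS) capacity, so sulfur-limited strains are
#' lifted in ISE while AS growth is untouched; `colored` adds a constant
#' absorbance offset without changing growth. Gaussian noise (sd
#' `noise_sd`) is added and the series truncated at zero.
#'
#' @param kin single-row kinetics data.frame (see [strain_kinetics()]).
#' @param effect single-row effect data.frame or `NULL` for no compound.
#' @param times sorted ascending timepoints in hours.
#' @param noise_sd OD noise standard deviation (>= 0).
#' @param seed optional integer seed for the noise draws.
#' @param kinetics full kinetics table used to resolve the AS reference
#'   capacity for `sulfate_bypass` effects.
#' @return numeric OD600 vector, one value per timepoint.
#' @export
growth_curve <- function(kin, effect = NULL, times, noise_sd = 0,
                         seed = NULL, kinetics = default_kinetics()) {
  if (is.unsorted(times, strictly = FALSE)) {
    ss_stop("times must be sorted ascending")
  }
  ss_check_number(noise_sd, "noise_sd", lower = 0)
  cap1 <- kin$cap1
  cap2 <- if (kin$diauxic) kin$cap2 else 0
  offset <- 0
  if (!is.null(effect) && nrow(effect) == 1L &&
      effect_applies(effect, kin$strain, kin$medium)) {
    cls <- effect$effect_class
    if (cls %in% c("suppressor", "toxic", "inert")) {
      cap1 <- cap1 * (1 + effect$magnitude)
      cap2 <- cap2 * (1 + effect$magnitude)
    } else if (cls == "sulfate_bypass") {
      as_kin <- strain_kinetics(kin$strain, "AS", kinetics)
      cap_as <- as_kin$cap1 + if (as_kin$diauxic) as_kin$cap2 else 0
      lift <- effect$magnitude * max(0, cap_as - (cap1 + cap2))
      cap1 <- cap1 + lift
    } else if (cls == "colored") {
      offset <- effect$magnitude
    }
  }
  od <- kin$od0 + cap1 * stats::plogis(kin$rate1 * (times - kin$mid1)) +
    offset
  if (cap2 > 0) od <- od + cap2 * stats::plogis(kin$rate2 * (times - kin$mid2))
  if (noise_sd > 0) {
    od <- ss_with_seed(seed, od + stats::rnorm(length(times), 0, noise_sd))
  }
  pmax(od, 0)
}

#' Screen simulation configuration
#'
#' Defaults mirror the screen design: 7 timepoints spanning 0-24 h, OD
#' noise sd 0.01, 4 vehicle-control wells per plate, 80 compounds per
#' plate (single wells), a 1280-compound library.
#'
#' @param timepoints_h measurement times in hours.
#' @param noise_sd additive OD noise sd.
#' @param n_control_wells vehicle wells per plate (>= 2).
#' @param compounds_per_plate experimental wells per plate.
#' @param library_size total number of library compounds.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(timepoints_h = seq(0, 24, by = 4),
                          noise_sd = 0.01, n_control_wells = 4,
                          compounds_per_plate = 80, library_size = 1280) {
  ss_check_number(noise_sd, "noise_sd", lower = 0)
  if (n_control_wells < 2) ss_stop("need at least 2 control wells")
  structure(list(timepoints_h = sort(timepoints_h), noise_sd = noise_sd,
                 n_control_wells = as.integer(n_control_wells),
                 compounds_per_plate = as.integer(compounds_per_plate),
                 library_size = as.integer(library_size)),
            class = "screen_config")
}

#' Default planted library composition
#'
#' Plants a realistic mixture: 2 percent selective suppressors (capacity
#' lift drawn in \[0.10, 0.20\] unless fixed), 16 sulfate-formulation
#' bypass compounds, 4 colored compounds, 64 toxic compounds, the rest
#' inert.
#'
#' @param library_size number of compounds.
#' @param seed integer seed for class placement and magnitudes.
#' @param suppressor_frac fraction of suppressors.
#' @param suppressor_magnitude fixed suppressor magnitude, or `NULL` to draw
#'   uniformly in \[0.10, 0.20\].
#' @param n_bypass,n_colored,n_toxic counts of the other planted classes;
#'   defaults scale with the library (16, 4 and 64 per 1280 compounds).
#' @return effect table as from [compound_effects()].
#' @export
default_effects <- function(library_size = 1280, seed = NULL,
                            suppressor_frac = 0.02,
                            suppressor_magnitude = NULL,
                            n_bypass = round(library_size / 80),
                            n_colored = round(library_size / 320),
                            n_toxic = round(library_size / 20)) {
  n_supp <- round(suppressor_frac * library_size)
  n_special <- n_supp + n_bypass + n_colored + n_toxic
  if (n_special > library_size) ss_stop("planted classes exceed library size")
  ids <- sprintf("C%04d", seq_len(library_size))
  ss_with_seed(seed, {
    slots <- sample(library_size, n_special)
    cls <- rep("inert", library_size)
    cls[slots] <- rep(c("suppressor", "sulfate_bypass", "colored", "toxic"),
                      c(n_supp, n_bypass, n_colored, n_toxic))
    mag <- numeric(library_size)
    mag[cls == "suppressor"] <- suppressor_magnitude %||%
      stats::runif(n_supp, 0.10, 0.20)
    mag[cls == "sulfate_bypass"] <- 0.5
    mag[cls == "colored"] <- 0.3
    mag[cls == "toxic"] <- -0.3
    compound_effects(ids, cls, mag)
  })
}

effects_to_library <- function(effects, stock_mM = 10) {
  data.frame(compound_id = effects$compound_id,
             name = paste0("compound-", sub("^C", "", effects$compound_id)),
             contains_sulfate = effects$effect_class == "sulfate_bypass",
             colored_solution = effects$effect_class == "colored",
             stock_mM = stock_mM, stringsAsFactors = FALSE)
}

#' Simulate the primary suppression screen
#'
#' Each plate carries `compounds_per_plate` single experimental wells
#' (sdh1 in ISE, one compound each at the screen concentration) plus
#' vehicle-control wells in the last column. Returns the measurement,
#' annotation and library tables in the canonical plate-model layout plus
#' the planted truth.
#'
#' @param config [screen_config()] list.
#' @param effects compound-effect table ([compound_effects()]); defaults to
#'   [default_effects()] for `config$library_size` compounds.
#' @param seed integer seed driving all noise draws.
#' @param kinetics strain kinetics table.
#' @return list of class `screen_sim` with elements `measurements`,
#'   `annotations`, `library`, `truth`, `config`.
#' @export
simulate_screen <- function(config = screen_config(), effects = NULL,
                            seed = NULL, kinetics = default_kinetics()) {
  cpp <- config$compounds_per_plate
  ncw <- config$n_control_wells
  if (cpp > 88 || cpp + ncw > 96) {
    ss_stop("plate capacity exceeded: ", cpp, " compounds + ", ncw,
            " controls do not fit a 96-well plate with a control column")
  }
  n_plates <- ceiling(config$library_size / cpp)
  if (is.null(effects)) {
    effects <- default_effects(config$library_size, seed = seed)
  }
  if (nrow(effects) < config$library_size) {
    ss_stop("effects table covers ", nrow(effects), " compounds; ",
            config$library_size, " required (", n_plates, " plates)")
  }
  effects <- effects[seq_len(config$library_size), , drop = FALSE]
  library <- effects_to_library(effects)
  kin <- strain_kinetics("sdh1", "ISE", kinetics)
  times <- config$timepoints_h
  conc <- final_concentration_uM(10, 200, 200)

  # experimental wells: row-major over columns 1..11; controls in column 12
  exp_wells <- well_label(rep(LETTERS[1:8], each = 11L), rep(1:11, times = 8L))
  ctrl_wells <- well_label(LETTERS[seq_len(ncw)], 12L)

  ann <- vector("list", n_plates)
  meas <- vector("list", n_plates)
  ss_with_seed(seed, {
    for (p in seq_len(n_plates)) {
      plate_id <- sprintf("P%02d", p)
      idx <- ((p - 1L) * cpp + 1L):min(p * cpp, config$library_size)
      wells_p <- exp_wells[seq_along(idx)]
      ann[[p]] <- data.frame(
        plate_id = plate_id,
        well = c(wells_p, ctrl_wells),
        strain = "sdh1", medium = "ISE",
        compound_id = c(effects$compound_id[idx], rep(NA_character_, ncw)),
        concentration_uM = c(rep(conc, length(idx)), rep(0, ncw)),
        role = c(rep("experimental", length(idx)),
                 rep("negative_control", ncw)),
        stringsAsFactors = FALSE)
      od <- c(
        unlist(lapply(seq_along(idx), function(j) {
          growth_curve(kin, effects[idx[j], , drop = FALSE], times,
                       noise_sd = config$noise_sd, kinetics = kinetics)
        })),
        unlist(lapply(seq_len(ncw), function(j) {
          growth_curve(kin, NULL, times, noise_sd = config$noise_sd,
                       kinetics = kinetics)
        })))
      meas[[p]] <- data.frame(
        plate_id = plate_id,
        well = rep(c(wells_p, ctrl_wells), each = length(times)),
        time_h = rep(times, length(idx) + ncw),
        od600 = od, stringsAsFactors = FALSE)
    }
  })
  structure(list(measurements = validate_measurements(do.call(rbind, meas)),
                 annotations = validate_annotations(do.call(rbind, ann)),
                 library = validate_library(library),
                 truth = effects[, c("compound_id", "effect_class",
                                     "magnitude")],
                 config = config),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated suppression screen:\n",
      " plates:      ", length(unique(x$annotations$plate_id)), "\n",
      " compounds:   ", nrow(x$library), "\n",
      " wells:       ", nrow(x$annotations), " (",
      sum(x$annotations$role == "negative_control"), " vehicle controls)\n",
      " timepoints:  ", length(x$config$timepoints_h), " over ",
      max(x$config$timepoints_h), " h\n", sep = "")
  invisible(x)
}

#' Simulate a dose-response validation experiment
#'
#' Grows the four strains in both media, untreated and treated with each
#' compound at each dose, with technical replicates, producing the
#' long-format table the selectivity analysis consumes.
#'
#' @param effects compound-effect table for the compounds under validation.
#' @param doses_uM tested concentrations.
#' @param n_reps technical replicates per condition.
#' @param timepoints_h measurement grid.
#' @param noise_sd OD noise sd.
#' @param seed integer seed.
#' @param kinetics strain kinetics table.
#' @return data.frame with columns `strain`, `medium`, `compound_id`,
#'   `concentration_uM` (0 = untreated), `replicate`, `time_h`, `od600`.
#' @export
simulate_validation <- function(effects, doses_uM = 25, n_reps = 4,
                                timepoints_h = seq(0, 24, by = 2),
                                noise_sd = 0.01, seed = NULL,
                                kinetics = default_kinetics()) {
  if (n_reps < 2) ss_stop("need at least 2 replicates")
  grid <- expand.grid(strain = ss_strains(), medium = ss_media(),
                      stringsAsFactors = FALSE)
  out <- list()
  ss_with_seed(seed, {
    for (g in seq_len(nrow(grid))) {
      kin <- strain_kinetics(grid$strain[g], grid$medium[g], kinetics)
      for (cid in c(NA_character_, effects$compound_id)) {
        doses <- if (is.na(cid)) 0 else doses_uM
        eff <- if (is.na(cid)) NULL else
          effects[effects$compound_id == cid, , drop = FALSE]
        for (d in doses) for (r in seq_len(n_reps)) {
          od <- growth_curve(kin, eff, timepoints_h, noise_sd = noise_sd,
                             kinetics = kinetics)
          out[[length(out) + 1L]] <- data.frame(
            strain = grid$strain[g], medium = grid$medium[g],
            compound_id = cid, concentration_uM = d, replicate = r,
            time_h = timepoints_h, od600 = od, stringsAsFactors = FALSE)
        }
      }
    }
  })
  do.call(rbind, out)
}

#' Simulate a protein-abundance matrix with planted differentials
#'
#' Log-normal abundances for three groups (WT reference plus the two
#' SDH-loss mutants). Differential proteins are shifted by a signed true
#' log2 fold-change in the designated comparison(s): `de_shared` proteins
#' move in both mutants, `de_a_only` only in the first, `de_b_only` only in
#' the second. A configurable fraction of down-in-mutant differential
#' proteins is made fully absent (all-zero) in the mutant group to exercise
#' the zero-flooring path. Defaults mirror the observed partition
#' (991 shared, 24 + 77 unique, ~6000 proteins).
#'
#' @param n_proteins number of proteins.
#' @param n_reps replicates per group (>= 2).
#' @param de_shared,de_a_only,de_b_only differential counts by membership.
#' @param lfc_mean absolute true log2 fold-change of differential proteins.
#' @param noise_sd replicate noise sd in log2 units.
#' @param frac_up fraction of differential proteins that are higher in the
#'   mutant (the rest are higher in WT).
#' @param absent_frac fraction of down-in-mutant differential proteins set
#'   to zero in the mutant group.
#' @param groups group labels: reference, mutant A, mutant B.
#' @param seed integer seed.
#' @return list of class `abundance_sim` with `matrix` (proteins x samples),
#'   `groups` (sample-to-group map) and `truth`.
#' @export
simulate_abundance <- function(n_proteins = 6000, n_reps = 3,
                               de_shared = 991, de_a_only = 24,
                               de_b_only = 77, lfc_mean = 2.5,
                               noise_sd = 0.25, frac_up = 0.103,
                               absent_frac = 0.02,
                               groups = c("WT", "sdh1", "sdh2"),
                               seed = NULL) {
  if (n_reps < 2) ss_stop("need >= 2 replicates per group (variance undefined)")
  n_de <- de_shared + de_a_only + de_b_only
  if (n_de > n_proteins) ss_stop("differential counts exceed n_proteins")
  ids <- sprintf("PROT%05d", seq_len(n_proteins))
  membership <- rep("none", n_proteins)
  if (n_de > 0) {
    membership[seq_len(n_de)] <- rep(c("shared", "a_only", "b_only"),
                                     c(de_shared, de_a_only, de_b_only))
  }
  ss_with_seed(seed, {
    base <- stats::rnorm(n_proteins, 15, 2)
    sign <- ifelse(stats::runif(n_proteins) < frac_up, 1, -1)
    lfc <- ifelse(membership == "none", 0, sign * lfc_mean)
    lfc_a <- ifelse(membership %in% c("shared", "a_only"), lfc, 0)
    lfc_b <- ifelse(membership %in% c("shared", "b_only"), lfc, 0)
    samples <- paste0(rep(groups, each = n_reps), "_",
                      rep(seq_len(n_reps), length(groups)))
    gmap <- data.frame(sample = samples,
                       group = rep(groups, each = n_reps),
                       stringsAsFactors = FALSE)
    shift <- cbind(matrix(0, n_proteins, n_reps),
                   matrix(lfc_a, n_proteins, n_reps),
                   matrix(lfc_b, n_proteins, n_reps))
    log2x <- base + shift +
      matrix(stats::rnorm(n_proteins * length(samples), 0, noise_sd),
             n_proteins, length(samples))
    mat <- 2^log2x
    dimnames(mat) <- list(ids, samples)
    absent <- rep(FALSE, n_proteins)
    down <- which(membership != "none" & lfc < 0)
    if (absent_frac > 0 && length(down)) {
      n_abs <- round(absent_frac * length(down))
      pick <- down[seq_len(n_abs)]
      absent[pick] <- TRUE
      for (i in pick) {
        if (membership[i] %in% c("shared", "a_only")) {
          mat[i, gmap$group == groups[2]] <- 0
        }
        if (membership[i] %in% c("shared", "b_only")) {
          mat[i, gmap$group == groups[3]] <- 0
        }
      }
    }
    truth <- data.frame(protein_id = ids, differential = membership != "none",
                        membership = membership, true_lfc_a = lfc_a,
                        true_lfc_b = lfc_b, absent = absent,
                        stringsAsFactors = FALSE)
    structure(list(matrix = mat, groups = gmap, truth = truth),
              class = "abundance_sim")
  })
}

#' Simulate a metabolite concentration table
#'
#' Per-sample concentrations drawn around strain x treatment means:
#' succinate elevated `succinate_fold`-fold and 2-ketoglutarate reduced to
#' `kg_fold` of WT in the SDH-loss mutants; the treatment lowers mutant
#' succinate by a fraction `treatment_effect` and leaves WT untouched.
#' Two bystander metabolites are included for realism.
#'
#' @param strains strain levels (first is the reference).
#' @param treatment_levels treatment levels (first is untreated).
#' @param n_reps replicates per strain x treatment (>= 2).
#' @param succinate_fold mutant:WT succinate fold (> 0).
#' @param kg_fold mutant:WT 2-ketoglutarate fold (> 0, < 1 by default).
#' @param treatment_effect fractional succinate reduction in treated
#'   mutants (0 disables the treatment).
#' @param noise_cv coefficient of variation of replicate noise.
#' @param seed integer seed.
#' @return list of class `metabolite_sim` with `table` (long format:
#'   `sample_id`, `strain`, `treatment`, `replicate`, `metabolite`,
#'   `concentration_uM`, `quantitation`) and `truth` (true means).
#' @export
simulate_metabolites <- function(strains = c("WT", "sdh1", "sdh2"),
                                 treatment_levels = c("untreated", "DMAE"),
                                 n_reps = 3, succinate_fold = 5,
                                 kg_fold = 0.5, treatment_effect = 0.4,
                                 noise_cv = 0.10, seed = NULL) {
  if (n_reps < 2) ss_stop("need >= 2 replicates")
  if (succinate_fold <= 0 || kg_fold <= 0) {
    ss_stop("fold parameters must be positive")
  }
  base <- c(succinate = 120, `2-ketoglutarate` = 150,
            glycine = 80, pyruvate = 60)
  mutant_fold <- c(succinate = succinate_fold,
                   `2-ketoglutarate` = kg_fold, glycine = 2, pyruvate = 0.7)
  design <- expand.grid(strain = strains, treatment = treatment_levels,
                        metabolite = names(base), stringsAsFactors = FALSE)
  is_mut <- design$strain != strains[1]
  mean_uM <- base[design$metabolite] *
    ifelse(is_mut, mutant_fold[design$metabolite], 1)
  treat_scale <- ifelse(design$metabolite == "succinate" & is_mut &
                          design$treatment != treatment_levels[1],
                        1 - treatment_effect, 1)
  truth <- cbind(design, mean_uM = unname(mean_uM * treat_scale))
  rows <- truth[rep(seq_len(nrow(truth)), each = n_reps), ]
  rows$replicate <- rep(seq_len(n_reps), nrow(truth))
  ss_with_seed(seed, {
    conc <- pmax(0, stats::rnorm(nrow(rows), rows$mean_uM,
                                 noise_cv * rows$mean_uM))
    tab <- data.frame(
      sample_id = paste(rows$strain, rows$treatment, rows$replicate,
                        sep = "_"),
      strain = rows$strain, treatment = rows$treatment,
      replicate = rows$replicate, metabolite = rows$metabolite,
      concentration_uM = conc, quantitation = "absolute",
      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    structure(list(table = tab, truth = truth), class = "metabolite_sim")
  })
}
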