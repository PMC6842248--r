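# Synthetic shake-flask fermentation tables with dose-response structure.

#' Specify a dose-response fermentation experiment
#'
#' @param effect_model data.frame of per-strain, per-dose model means with
#'   columns `strain`, `dox_ug_ml`, `protein_mg`, `dry_weight_g`,
#'   `citric_g_l`, `oxaloacetate_g_l`, `glucose_depleted_g_l`; all means
#'   must be nonnegative. See [default_effect_model()].
#' @param replicate_count replicate flasks per strain x dose (>= 2).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   measurement noise (>= 0; 0 reproduces the model means exactly).
#' @param seed integer seed.
#' @return A `dose_response_spec` list.
#' @export
dose_response_spec <- function(effect_model = default_effect_model(),
                               replicate_count = 4L, noise_cv = 0.1,
                               seed = 1L) {
  needed <- c("strain", "dox_ug_ml", "protein_mg", "dry_weight_g",
              "citric_g_l", "oxaloacetate_g_l", "glucose_depleted_g_l")
  check_that(is.data.frame(effect_model) && all(needed %in% names(effect_model)),
             "`effect_model` must have columns %s", paste(needed, collapse = ", "))
  meas <- as.matrix(effect_model[, needed[-(1:2)]])
  check_that(all(meas >= 0), "all model means must be nonnegative")
  check_that(!anyDuplicated(effect_model[, c("strain", "dox_ug_ml")]),
             "one model row per strain x dose is required")
  check_that(is_count(replicate_count, 2L), "`replicate_count` must be >= 2")
  check_that(is_scalar_number(noise_cv) && noise_cv >= 0,
             "`noise_cv` must be nonnegative")
  structure(list(effect_model = effect_model,
                 replicate_count = as.integer(replicate_count),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "dose_response_spec")
}

#' Default dose-response effect model
#'
#' Invented model means emulating the qualitative strain x dose patterns of
#' a titratable-promoter (Tet-on) experiment in *Aspergillus niger*: a
#' progenitor control (`MA70.15`) with dose-independent output, a `secG`-type
#' mutant (`TC4.4`) whose citric acid titre is zero at 0 and 0.2 ug/ml
#' doxycycline while oxaloacetate rises, and `ageB`/`geaB`-type mutants
#' (`TC5.5`, `TC6.1`) whose growth and protein secretion collapse at
#' 0.2 ug/ml Dox and recover at 2 ug/ml. Doses for the essential-gene
#' mutants omit 0 ug/ml. All numeric levels are the generator's own.
#'
#' @return data.frame suitable for [dose_response_spec()].
#' @export
default_effect_model <- function() {
  row <- function(strain, dox, protein, dw, citric, oxa, glc) {
    data.frame(strain = strain, dox_ug_ml = dox, protein_mg = protein,
               dry_weight_g = dw, citric_g_l = citric, oxaloacetate_g_l = oxa,
               glucose_depleted_g_l = glc, stringsAsFactors = FALSE)
  }
  rbind(
    row("MA70.15", 0.0, 50, 2.0, 2.0, 0.50, 18),
    row("MA70.15", 0.2, 50, 2.0, 2.0, 0.50, 18),
    row("MA70.15", 2.0, 50, 2.0, 2.0, 0.50, 18),
    row("MA70.15", 20,  50, 2.0, 2.0, 0.50, 18),
    row("TC4.4",   0.0, 58, 2.0, 0.0, 1.50, 17),
    row("TC4.4",   0.2, 52, 2.0, 0.0, 1.40, 17),
    row("TC4.4",   2.0, 50, 2.0, 1.60, 0.60, 18),
    row("TC4.4",   20,  50, 2.0, 1.10, 0.55, 18),
    row("TC5.5",   0.2,  6, 0.8, 0.10, 0.15, 9),
    row("TC5.5",   2.0, 48, 1.9, 1.60, 0.45, 18),
    row("TC5.5",   20,  32, 1.8, 1.80, 0.40, 17),
    row("TC6.1",   0.2,  6, 0.8, 0.10, 0.15, 9),
    row("TC6.1",   2.0, 49, 2.0, 1.90, 0.50, 18),
    row("TC6.1",   20,  50, 2.0, 2.00, 0.50, 18)
  )
}

#' Generate a replicated fermentation measurement table
#'
#' Each strain x dose cell of the effect model is expanded into
#' `replicate_count` rows; every measurement equals its model mean times an
#' independent lognormal factor with unit mean and coefficient of variation
#' `noise_cv` (multiplicative noise keeps titres nonnegative). Zero model
#' means stay exactly zero, mirroring "not detected" readings.
#'
#' @param spec a [dose_response_spec()].
#' @return data.frame with columns `strain`, `dox_ug_ml`, `replicate`,
#'   `protein_mg`, `dry_weight_g`, `citric_g_l`, `oxaloacetate_g_l`,
#'   `glucose_depleted_g_l`.
#' @export
#' @examples
#' tab <- generate_fermentation_table(dose_response_spec(noise_cv = 0))
#' head(tab)
generate_fermentation_table <- function(spec) {
  check_that(inherits(spec, "dose_response_spec"),
             "`spec` must be a dose_response_spec")
  em <- spec$effect_model
  meas_cols <- c("protein_mg", "dry_weight_g", "citric_g_l",
                 "oxaloacetate_g_l", "glucose_depleted_g_l")
  n_rep <- spec$replicate_count
  idx <- rep(seq_len(nrow(em)), each = n_rep)
  out <- data.frame(strain = em$strain[idx], dox_ug_ml = em$dox_ug_ml[idx],
                    replicate = rep(seq_len(n_rep), nrow(em)),
                    stringsAsFactors = FALSE)
  means <- as.matrix(em[idx, meas_cols])
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    noise <- with_seed(spec$seed, matrix(
      stats::rlnorm(length(means), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow(means), ncol(means)))
    means <- means * noise
  }
  out[meas_cols] <- means
  out
}

#' Write or read a fermentation table CSV
#'
#' @param table data.frame as produced by [generate_fermentation_table()].
#' @param path file path.
#' @return `read_fermentation_table` returns the validated data.frame.
#' @export
write_fermentation_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fermentation_table
#' @export
read_fermentation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_fermentation_table(df)
  df
}

validate_fermentation_table <- function(df) {
  needed <- c("strain", "dox_ug_ml", "replicate", "protein_mg",
              "dry_weight_g", "citric_g_l", "oxaloacetate_g_l",
              "glucose_depleted_g_l")
  check_that(all(needed %in% names(df)),
             "fermentation table must have columns %s",
             paste(needed, collapse = ", "))
  meas <- as.matrix(df[, needed[-(1:3)]])
  check_that(all(meas >= 0), "fermentation measurements must be nonnegative")
  invisible(df)
}
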