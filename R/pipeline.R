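# ---------------------------------------------------------------------------
# Funnel orchestration: synthetic inputs -> hypothesis generation ->
# decoy-set validation -> library screening -> binding-energy ranking ->
# trajectory stability, with per-stage counts and persisted artifacts.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' A declarative description of which stages run and with what parameters.
#' Any stage entry set to NULL is skipped.
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @param planted a `planted_spec` for the screening library (or NULL).
#' @param decoy a `decoy_set_spec` for GH validation (or NULL).
#' @param generate logical: enumerate hypotheses from the planted actives.
#' @param allow_omit,match_tolerance screening parameters.
#' @param energetics logical: attach synthetic binding energies to passed
#'   compounds and rank them against two reference inhibitors.
#' @param trajectory logical: generate and assess a stability trajectory
#'   per final hit.
#' @param reference_dg named numeric of reference mean binding energies in
#'   kJ/mol (first = primary gate).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            planted = planted_spec(n_actives = 4L,
                                                   n_decoys = 16L),
                            decoy = decoy_set_spec(110L, 6L, 2L, 2L),
                            generate = TRUE,
                            allow_omit = 0L, match_tolerance = 1.0,
                            energetics = TRUE, trajectory = TRUE,
                            reference_dg = c(CT7001_ref = -90.58,
                                             THZ1_ref = -91.48)) {
  structure(list(seed = as.integer(seed), planted = planted, decoy = decoy,
                 generate = generate, allow_omit = as.integer(allow_omit),
                 match_tolerance = match_tolerance,
                 energetics = energetics, trajectory = trajectory,
                 reference_dg = reference_dg),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with fields mirroring [pipeline_config()] (specs
#'   given as plain lists of their constructor arguments).
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    seed = js$seed %||% 1L,
    planted = if (!is.null(js$planted)) do.call(planted_spec, js$planted),
    decoy = if (!is.null(js$decoy)) do.call(decoy_set_spec, js$decoy),
    generate = js$generate %||% TRUE,
    allow_omit = js$allow_omit %||% 0L,
    match_tolerance = js$match_tolerance %||% 1.0,
    energetics = js$energetics %||% TRUE,
    trajectory = js$trajectory %||% TRUE,
    reference_dg = if (!is.null(js$reference_dg)) unlist(js$reference_dg)
                   else c(CT7001_ref = -90.58, THZ1_ref = -91.48))
}

#' Run the screening funnel
#'
#' Executes the enabled stages in order (generate/validate hypotheses ->
#' screen -> energetics -> trajectory), logging one line per stage with
#' input/output counts. Deterministic given the config seed; artifacts are
#' written under `out_dir` when given.
#'
#' @param cfg a `pipeline_config`.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @param quiet suppress stage logging.
#' @return object of class `funnel_report`: per-stage counts, the selected
#'   hypothesis with validation statistics, the ranked hit table, and
#'   stability verdicts.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_stage <- function(stage, n_in, n_out) {
    if (!quiet)
      message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  persist <- function(obj, name) {
    if (!is.null(out_dir))
      utils::write.table(obj, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  report <- list(stages = data.frame(stage = character(), n_in = integer(),
                                     n_out = integer()))
  add_stage <- function(stage, n_in, n_out) {
    report$stages <<- rbind(report$stages,
                            data.frame(stage = stage, n_in = n_in,
                                       n_out = n_out))
    log_stage(stage, n_in, n_out)
  }

  # --- synthetic inputs ----------------------------------------------------
  hypothesis <- NULL
  library_data <- NULL
  if (!is.null(cfg$planted)) {
    library_data <- gen_planted_library(cfg$planted, seed = cfg$seed)
    hypothesis <- library_data$hypothesis
    add_stage("simulate_library", 0L, length(library_data$library))
  }

  # --- hypothesis generation ----------------------------------------------
  if (isTRUE(cfg$generate) && !is.null(library_data)) {
    actives <- library_data$library[library_data$labels]
    ts <- training_set(lapply(actives, function(fs)
      list(conformers = fs, principal = 2L, max_omit = 0L)))
    gcfg <- generation_config(min_features = length(cfg$planted$kinds),
                              max_features = max(length(cfg$planted$kinds),
                                                 7L),
                              match_tolerance = cfg$match_tolerance)
    gen <- enumerate_common_pharmacophores(ts, gcfg)
    add_stage("generate_hypotheses", length(actives), length(gen))
    if (length(gen)) {
      hypothesis <- gen[[1]]$hypothesis
      report$hypothesis_table <- hypothesis_report(gen)
      persist(report$hypothesis_table, "hypotheses.tsv")
    }
  }
  if (is.null(hypothesis))
    abort_pharm("pipeline has no hypothesis (enable planted or generate)",
                "stage_failure:generate")

  # --- GH validation -------------------------------------------------------
  if (!is.null(cfg$decoy)) {
    dec <- gen_decoy_set(cfg$decoy, seed = cfg$seed + 1L)
    ev <- evaluate_decoy_set(dec$hypothesis, dec$library, dec$labels,
                             allow_omit = cfg$allow_omit,
                             match_tolerance = cfg$match_tolerance)
    report$gh <- ev
    report$gh_table <- gh_report(list(hypothesis = ev))
    persist(report$gh_table, "gh_validation.tsv")
    add_stage("gh_validate", cfg$decoy$D, ev$Ht)
  }

  # --- screening -----------------------------------------------------------
  hits <- NULL
  if (!is.null(library_data)) {
    rec <- screen_library(hypothesis, library_data$library,
                          allow_omit = cfg$allow_omit,
                          match_tolerance = cfg$match_tolerance)
    report$screen <- rec
    persist(rec, "screen_records.tsv")
    hits <- rec$id[rec$passed]
    add_stage("screen", nrow(rec), length(hits))
  }

  # --- energetics ----------------------------------------------------------
  if (isTRUE(cfg$energetics) && length(hits)) {
    summaries <- lapply(seq_along(hits), function(k) {
      sp <- snapshot_spec(
        mean = c(vdw = -120 - 8 * k, elec = -30 - 2 * k,
                 polar_solv = 60, nonpolar_sasa = -12),
        sd = c(vdw = 10, elec = 8, polar_solv = 12, nonpolar_sasa = 1.2))
      summarize_snapshots(gen_snapshots(sp, seed = cfg$seed + 100L + k),
                          id = hits[k])
    })
    refs <- lapply(seq_along(cfg$reference_dg), function(r) {
      sp <- snapshot_spec(
        mean = c(vdw = unname(cfg$reference_dg[r]) - 40, elec = -20,
                 polar_solv = 72, nonpolar_sasa = -12),
        sd = c(vdw = 10, elec = 8, polar_solv = 12, nonpolar_sasa = 1.2))
      summarize_snapshots(gen_snapshots(sp, seed = cfg$seed + 200L + r),
                          id = names(cfg$reference_dg)[r])
    })
    ranked <- rank_candidates(c(summaries, refs), names(cfg$reference_dg))
    report$ranking <- ranked
    report$binding_table <- binding_report(c(summaries, refs))
    persist(report$binding_table, "binding_energies.tsv")
    hits <- ranked$id[ranked$selected]
    add_stage("energetics", nrow(ranked), length(hits))
  }

  # --- trajectory stability ------------------------------------------------
  if (isTRUE(cfg$trajectory) && length(hits)) {
    verdicts <- vapply(seq_along(hits), function(k) {
      traj <- gen_trajectory(trajectory_spec(n_residues = 30L,
                                             n_frames = 40L,
                                             jitter_profile = 0.12),
                             seed = cfg$seed + 300L + k)
      rs <- rmsd_series(traj)
      rf <- rmsf(traj)
      stability_assess(rs, rf, threshold = 0.3,
                       from_time = max(traj$times) * 0.5)$stable
    }, logical(1))
    report$stability <- data.frame(id = hits, stable = verdicts)
    persist(report$stability, "stability.tsv")
    hits <- hits[verdicts]
    add_stage("trajectory", length(verdicts), length(hits))
  }

  report$final_hits <- hits %||% character()
  class(report) <- "funnel_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(stages = report$stages,
           final_hits = report$final_hits,
           gh = if (!is.null(report$gh)) unclass(report$gh)),
      file.path(out_dir, "funnel_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$stages, row.names = FALSE)
  if (!is.null(x$gh))
    cat(sprintf("GH: GF = %.4f (%.2f truncated)\n", x$gh$GF, x$gh$GF_2dec))
  cat("final hits:", if (length(x$final_hits))
    paste(x$final_hits, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
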