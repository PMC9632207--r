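#' Read and write the titration CSV dialect
#'
#' Comma-separated, UTF-8, header row required, "." decimal. Columns:
#' \code{injection}, \code{ligand_uM}, \code{heat}, \code{heat_unit},
#' optionally \code{LA}, \code{LB}. Malformed rows are reported with
#' their line number; a non-increasing ligand column names the offending
#' line.
#'
#' @param path file path.
#' @return a \code{titration_series}.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection", "ligand_uM", "heat", "heat_unit")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("ligand_uM", "heat")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("non-numeric %s at file line(s) %s", col,
                   paste(bad + 1L, collapse = ", ")))  # +1 for the header
    df[[col]] <- as.numeric(df[[col]])
  }
  nonmono <- which(diff(df$ligand_uM) <= 0)
  if (length(nonmono) > 0)
    stop(sprintf("ligand_uM not strictly increasing at file line(s) %s",
                 paste(nonmono + 2L, collapse = ", ")))
  unit <- unique(df$heat_unit)
  if (length(unit) != 1L) stop("heat_unit column must be constant")
  keep <- intersect(c("injection", "ligand_uM", "heat", "LA", "LB"),
                    names(df))
  new_titration_series(df[keep], design = NULL, heat_unit = unit)
}

#' @rdname read_titration_csv
#' @param series a \code{titration_series}.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- as.data.frame(series)
  df$heat_unit <- attr(series, "heat_unit")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the rate-grid CSV dialect
#'
#' Columns: \code{substrate_mM}, \code{inhibitor_uM}, \code{velocity},
#' \code{replicate}.
#'
#' @param path file path.
#' @return a \code{kinetics_dataset}.
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate_mM", "inhibitor_uM", "velocity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (length(unique(df$substrate_mM)) < 3L)
    stop("need at least 3 distinct substrate levels")
  structure(df, class = c("kinetics_dataset", "data.frame"))
}

#' @rdname read_kinetics_csv
#' @param dataset a \code{kinetics_dataset}.
#' @export
write_kinetics_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write the dose-response CSV dialect
#'
#' Columns: \code{inhibitor_uM}, \code{activity} (fractional, 1 at zero
#' dose).
#'
#' @param path file path.
#' @return a \code{dose_response} data.frame.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("inhibitor_uM", "activity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  structure(df, class = c("dose_response", "data.frame"))
}

#' @rdname read_dose_response_csv
#' @param dose_response a \code{dose_response} data.frame.
#' @export
write_dose_response_csv <- function(dose_response, path) {
  utils::write.csv(as.data.frame(dose_response), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a ground-truth sidecar for a generated dataset
#'
#' Every simulated dataset carries its generating parameters and seed as
#' attributes; this serialises them to JSON next to the data file so a
#' recovery study can be reconstructed from files alone.
#'
#' @param dataset a simulated object with \code{truth}/\code{seed}
#'   attributes.
#' @param path output JSON path.
#' @export
write_truth_sidecar <- function(dataset, path) {
  truth <- attr(dataset, "truth")
  payload <- list(truth = if (inherits(truth, "solvation_parameters"))
                    unclass(truth) else truth,
                  seed = attr(dataset, "seed"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Pipeline configuration
#'
#' Run-level configuration shared by all stages. Physical constants are
#' package-level and not part of the configuration. The configuration is
#' serialised into every report so a run is reproducible from its
#' outputs.
#'
#' @param temperature_itc ITC temperature, K.
#' @param temperature_docking docking-convention temperature, K.
#' @param region_threshold low/high mole-fraction boundary in (0, 1).
#' @param classification_tolerance mechanism classification tolerance.
#' @param seed integer seed recorded with (and used by) the run.
#' @return object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(temperature_itc = 300,
                            temperature_docking = 298.15,
                            region_threshold = 0.5,
                            classification_tolerance = 0.15,
                            seed = 1L) {
  stopifnot(temperature_itc > 0, temperature_docking > 0,
            region_threshold > 0, region_threshold < 1,
            classification_tolerance > 0)
  structure(list(temperature_itc = temperature_itc,
                 temperature_docking = temperature_docking,
                 region_threshold = region_threshold,
                 classification_tolerance = classification_tolerance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order over the supplied inputs and
#' returns (and optionally writes) a report bundle. Stages:
#' \describe{
#'   \item{fit-itc}{extended solvation fit of \code{inputs$titration},
#'     with Ka estimate and derived thermodynamics}
#'   \item{fit-hill}{two-region Hill analysis of \code{inputs$titration}}
#'   \item{fit-kinetics}{mechanism classification and global inhibition
#'     fit of \code{inputs$kinetics}}
#'   \item{ic50}{logistic IC50 fit of \code{inputs$dose_response}}
#'   \item{energetics}{MM-PBSA component sum of \code{inputs$mmpbsa} and,
#'     when the other stages ran, the cross-method dG comparison}
#' }
#' A stage failure halts the bundle with a structured error that retains
#' the partial results.
#'
#' @param config a \code{pipeline_config}.
#' @param inputs named list of inputs (see stage descriptions).
#' @param stages character vector of stage names, executed in the order
#'   given.
#' @param outdir optional directory; when given, the JSON report and
#'   per-table CSVs are written there.
#' @return the report bundle (named list), invisibly when written.
#' @export
run_pipeline <- function(config, inputs, stages, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("fit-itc", "fit-hill", "fit-kinetics", "ic50", "energetics")
  if (length(stages) == 0L)
    stop("no stages requested; choose from: ", paste(known, collapse = ", "))
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  report <- list(config = unclass(config))
  results <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial results retained for: %s)",
                   name, conditionMessage(e),
                   paste(names(results), collapse = ", ")), call. = FALSE)
    })
  }

  for (stage in stages) {
    if (stage == "fit-itc") {
      results$itc <- run_stage("fit-itc", {
        fit <- fit_solvation(inputs$titration)
        ka <- association_constant(inputs$titration, fit$parameters)
        dH <- if (!is.null(inputs$dH_itc)) inputs$dH_itc else fit$parameters$q_max
        th <- thermodynamics(ka$Ka, dH, config$temperature_itc)
        list(parameters = as.list(coef(fit)), ssr = fit$ssr,
             model = fit$model,
             Ka = ka$Ka, estimator = ka$estimator, thermo = unclass(th),
             cooperativity = classify_cooperativity(fit$parameters$p))
      })
    } else if (stage == "fit-hill") {
      results$hill <- run_stage("fit-hill", {
        fits <- hill_two_region(inputs$titration,
                                threshold = config$region_threshold)
        lapply(fits, function(f)
          list(region = f$region, n = f$n, Ka = f$Ka, q_max = f$q_max,
               thermo = unclass(f$thermo),
               cooperativity = classify_cooperativity(f$n)))
      })
    } else if (stage == "fit-kinetics") {
      results$kinetics <- run_stage("fit-kinetics", {
        fit <- fit_inhibition(inputs$kinetics, mechanism = "auto",
                              rel_tol = config$classification_tolerance)
        list(mechanism = fit$mechanism, Vmax = fit$Vmax, Km = fit$Km,
             Ki = fit$Ki, Ki_secondary = fit$Ki_secondary,
             lb_lines = as.data.frame(fit$lb))
      })
    } else if (stage == "ic50") {
      results$ic50 <- run_stage("ic50", {
        fit <- estimate_ic50(inputs$dose_response)
        list(ic50 = fit$ic50, slope = fit$slope,
             ic50_ci95 = fit$ic50_ci95)
      })
    } else if (stage == "energetics") {
      results$energetics <- run_stage("energetics", {
        s <- sum_components(inputs$mmpbsa)
        out <- list(components = unclass(inputs$mmpbsa), total = s$total,
                    residual_vs_reported = s$residual_vs_reported)
        if (!is.null(results$itc) && !is.null(inputs$docking_dG_kcal)) {
          cmp <- compare_methods(results$itc$thermo$dG,
                                 inputs$docking_dG_kcal, s$total)
          out$comparison <- list(values_kJmol = as.list(cmp$values_kJmol),
                                 ordering = cmp$ordering)
        }
        out
      })
    }
  }
  report$results <- results
  report$config_hash <- config_hash(config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    if (!is.null(results$itc))
      utils::write.csv(
        data.frame(p = results$itc$parameters[["p"]],
                   Ka_Lmol = results$itc$Ka,
                   dH_kJmol = results$itc$thermo$dH,
                   dG_kJmol = results$itc$thermo$dG,
                   TdS_kJmol = results$itc$thermo$TdS,
                   delta_A = results$itc$parameters[["delta_A"]],
                   delta_B = results$itc$parameters[["delta_B"]]),
        file.path(outdir, "solvation_parameters.csv"), row.names = FALSE)
    if (!is.null(results$hill))
      utils::write.csv(
        do.call(rbind, lapply(results$hill, function(h)
          data.frame(region = h$region, n = h$n, Ka_Lmol = h$Ka,
                     dH_kJmol = h$thermo$dH, dG_kJmol = h$thermo$dG,
                     TdS_kJmol = h$thermo$TdS))),
        file.path(outdir, "hill_regions.csv"), row.names = FALSE)
    if (!is.null(results$kinetics))
      utils::write.csv(results$kinetics$lb_lines,
                       file.path(outdir, "lineweaver_burk.csv"),
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}

# internal: deterministic hash of the serialized config (no extra deps)
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
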