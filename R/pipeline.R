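#' Pipeline run configuration
#'
#' Collects inputs, stage selection and tuning parameters for
#' [run_pipeline()]. All fields mirror the arguments of the per-stage
#' functions; a YAML file with the same keys can be loaded with
#' [read_run_config()] and individual fields overridden on top.
#'
#' @param records A [record_set()], or a path to its JSON serialization.
#' @param stages Character subset of
#'   `c("descriptors", "binding", "dos", "pdos", "vib")`.
#' @param out_dir Output directory (created if missing).
#' @param ref A [reference_metal()] for the electron-transfer fraction.
#' @param broadening A [broadening_spec()].
#' @param fermi_mode `"midgap"` or `"homo"`.
#' @param binding_complexes List of [fragment_set()] objects (for the
#'   `binding` stage), or `NULL` to skip it.
#' @param vib_model,vib_exp [band_list()]s (or CSV paths) for the `vib`
#'   stage, or `NULL` to skip it.
#' @param assign_tol,diff_tol Matching tolerances in cm^-1.
#' @param reference_table Optional data.frame with columns `label` and any of
#'   `mu`, `eta`, `sigma`, `omega`, `gap`, `I`, `A`, `tdm`: printed values to
#'   check the computed descriptor table against; disagreements beyond
#'   `reference_tol` are listed in `consistency.csv`.
#' @param reference_tol Tolerance for the consistency check (printed scale).
#' @param precision Decimal places for the rounded CSV views (full precision
#'   is always written to the `*_full.csv` sidecars).
#' @param verbose Log stage progress to stderr?
#' @return Object of class `run_config`.
#' @export
run_config <- function(records,
                       stages = c("descriptors", "dos", "pdos"),
                       out_dir = ".",
                       ref = reference_metal(),
                       broadening = broadening_spec(),
                       fermi_mode = "midgap",
                       binding_complexes = NULL,
                       vib_model = NULL, vib_exp = NULL,
                       assign_tol = 100, diff_tol = 50,
                       reference_table = NULL, reference_tol = 0.0015,
                       precision = 3, verbose = TRUE) {
  if (is.character(records)) {
    if (!file.exists(records)) stop("record input not found: ", records)
    records <- read_record_set(records)
  }
  stopifnot(inherits(records, "record_set"))
  stages <- match.arg(stages, c("descriptors", "binding", "dos", "pdos", "vib"),
                      several.ok = TRUE)
  if (is.character(vib_model)) vib_model <- read_band_list(vib_model)
  if (is.character(vib_exp)) vib_exp <- read_band_list(vib_exp)
  structure(list(records = records, stages = stages, out_dir = out_dir,
                 ref = ref, broadening = broadening, fermi_mode = fermi_mode,
                 binding_complexes = binding_complexes,
                 vib_model = vib_model, vib_exp = vib_exp,
                 assign_tol = assign_tol, diff_tol = diff_tol,
                 reference_table = reference_table, reference_tol = reference_tol,
                 precision = precision, verbose = verbose),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; nested keys
#' `broadening: {fwhm, grid_step, padding}` and `ref: {chi_ref, eta_ref,
#' rule}` build the corresponding parameter objects. Arguments passed in
#' `...` override file values.
#'
#' @param path YAML file path.
#' @param ... Overrides forwarded to [run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("broadening", "ref"))]
  if (!is.null(y$broadening)) args$broadening <- do.call(broadening_spec, y$broadening)
  if (!is.null(y$ref)) args$ref <- do.call(reference_metal, y$ref)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

write_table_pair <- function(df, out_dir, name, precision) {
  full <- file.path(out_dir, paste0(name, "_full.csv"))
  rounded <- df
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], round_half_away, digits = precision)
  utils::write.csv(df, full, row.names = FALSE)
  utils::write.csv(rounded, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages over the configured record set and writes one
#' CSV per report into `out_dir` (each with a full-precision `_full.csv`
#' sidecar): `descriptors.csv` (the reactivity cascade per structure),
#' `gap_tdm.csv` (gap and dipole magnitude), `binding.csv`, per-structure
#' `dos_<label>.csv` / `pdos_<label>.csv` spectra, `vib_assignment.csv` and
#' `vib_diff_*.csv`, and — when a reference table is supplied —
#' `consistency.csv` flagging cells that disagree beyond tolerance. Re-running
#' with the same configuration and inputs reproduces identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list of the computed in-memory objects (`descriptors`,
#'   `binding`, `dos`, `pdos`, `vib`, `consistency`), with `n_failed` counting
#'   stages that raised errors (each logged, none aborting the rest).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (cfg$verbose) message(sprintf(...))
  out <- list(n_failed = 0L)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      out$n_failed <<- out$n_failed + 1L
      NULL
    })
  }

  if ("descriptors" %in% cfg$stages) {
    out$descriptors <- run_stage("descriptors", {
      log_msg("descriptors: %d structure(s)", length(cfg$records))
      tab <- descriptor_table(cfg$records, ref = cfg$ref, digits = cfg$precision)
      write_table_pair(tab[setdiff(names(tab), grep("\\.r$", names(tab), value = TRUE))],
                       cfg$out_dir, "descriptors", cfg$precision)
      write_table_pair(tab[c("label", "gap", "tdm")], cfg$out_dir, "gap_tdm",
                       cfg$precision)
      if (!is.null(cfg$reference_table)) {
        out$consistency <- consistency_vs_table(tab, cfg$reference_table,
                                                tol = cfg$reference_tol)
        utils::write.csv(out$consistency, file.path(cfg$out_dir, "consistency.csv"),
                         row.names = FALSE)
      }
      tab
    })
  }

  if ("binding" %in% cfg$stages && !is.null(cfg$binding_complexes)) {
    out$binding <- run_stage("binding", {
      log_msg("binding: %d complex(es)", length(cfg$binding_complexes))
      res <- rank_sites(lapply(cfg$binding_complexes, binding_energy))
      df <- data.frame(
        label = vapply(res, `[[`, character(1), "complex_label"),
        site = vapply(res, `[[`, character(1), "site_tag"),
        BE_au = vapply(res, `[[`, numeric(1), "BE_au"),
        BE_eV = vapply(res, `[[`, numeric(1), "BE_eV"),
        stringsAsFactors = FALSE)
      write_table_pair(df, cfg$out_dir, "binding", cfg$precision)
      df
    })
  }

  if (any(c("dos", "pdos") %in% cfg$stages)) {
    out$dos <- list(); out$pdos <- list()
    for (r in cfg$records$records) {
      run_stage(paste0("dos/", r$label), {
        hl <- homo_lumo(r)
        shift <- fermi_reference(hl["homo"], hl["lumo"], cfg$fermi_mode)
        if ("dos" %in% cfg$stages) {
          curve <- dos_curve(r$orbital_energies, cfg$broadening, shift = shift,
                             label = r$label)
          write_spectrum_csv(curve, file.path(cfg$out_dir,
                                              paste0("dos_", r$label, ".csv")))
          out$dos[[r$label]] <- curve
        }
        if ("pdos" %in% cfg$stages && !is.null(r$population_weights)) {
          curves <- pdos_curves(r$orbital_energies, r$population_weights,
                                cfg$broadening, shift = shift)
          write_spectrum_csv(curves, file.path(cfg$out_dir,
                                               paste0("pdos_", r$label, ".csv")))
          out$pdos[[r$label]] <- curves
        }
        NULL
      })
    }
  }

  if ("vib" %in% cfg$stages && !is.null(cfg$vib_model) && !is.null(cfg$vib_exp)) {
    out$vib <- run_stage("vib", {
      log_msg("vibrational: assignment at tol %g cm^-1", cfg$assign_tol)
      ar <- assign_bands(cfg$vib_model, cfg$vib_exp, tol = cfg$assign_tol)
      write_table_pair(ar$pairs, cfg$out_dir, "vib_assignment", cfg$precision)
      ar
    })
  }

  invisible(out)
}

#' Consistency of a computed descriptor table with printed reference values
#'
#' @param computed A [descriptor_table()] result.
#' @param printed Data.frame with `label` plus any of `gap`, `I`, `A`, `mu`,
#'   `eta`, `sigma`, `omega`, `tdm` holding printed values.
#' @param tol Absolute tolerance on the printed scale.
#' @return A [compare_to_reference()] report over all shared cells.
#' @export
consistency_vs_table <- function(computed, printed, tol = 0.0015) {
  shared <- intersect(c("gap", "I", "A", "mu", "eta", "sigma", "omega", "tdm"),
                      names(printed))
  idx <- match(printed$label, computed$label)
  labs <- c(); comp <- c(); prt <- c()
  for (cc in shared) {
    labs <- c(labs, paste(printed$label, cc))
    comp <- c(comp, computed[[cc]][idx])
    prt <- c(prt, printed[[cc]])
  }
  keep <- !is.na(prt)
  compare_to_reference(comp[keep], prt[keep], tol = tol, labels = labs[keep])
}
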