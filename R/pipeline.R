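# Orchestration layer: each run_* function mirrors one shell subcommand.
# All outputs are plain text with "# key=value" provenance header lines
# sufficient to re-run the command; logging goes to stderr via message().

pkg_version <- function() {
  as.character(utils::packageVersion("modechar"))
}

provenance_header <- function(params) {
  c(sprintf("# generated_by=modechar %s", pkg_version()),
    sprintf("# %s=%s", names(params),
            vapply(params, function(p) paste(format(p), collapse = ","),
                   character(1))))
}

write_tsv_provenance <- function(df, file, params) {
  writeLines(c(provenance_header(params),
               paste(names(df), collapse = "\t"),
               do.call(paste, c(lapply(df, format), sep = "\t"))),
             file)
  invisible(file)
}

#' Run the mode-character decomposition pipeline
#'
#' Reads a structure (CIF) and a mode file (JSON), checks that they index
#' the same atoms, decomposes every mode for every molecule and writes the
#' per-(mode, species) character table as TSV with a provenance header.
#'
#' @param structure_file CIF path.
#' @param modes_file Mode JSON path.
#' @param out_dir Output directory (created if needed).
#' @param mass_weighted,principal_axes Passed to [mode_character()].
#' @param per_molecule Also write the unaveraged per-molecule table.
#' @return Invisibly, a list with the summary tibble and output paths.
#' @export
run_decompose <- function(structure_file, modes_file, out_dir = ".",
                          mass_weighted = TRUE, principal_axes = FALSE,
                          per_molecule = FALSE) {
  for (f in c(structure_file, modes_file)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  xtal <- read_cif(structure_file)
  modes <- read_modes(modes_file)
  if (modes$n_atoms != n_atoms(xtal)) {
    stop("atom-count mismatch: structure has ", n_atoms(xtal),
         " sites but modes cover ", modes$n_atoms, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  part <- partition_molecules(xtal)
  message("decomposing ", length(modes), " mode(s) over ",
          length(part$molecules), " molecule(s)")
  chars <- mode_character(xtal, modes, part, mass_weighted = mass_weighted,
                          principal_axes = principal_axes)
  summ <- summarize_unit_cell(chars)
  params <- list(command = "decompose", structure = structure_file,
                 modes = modes_file, mass_weighted = mass_weighted,
                 principal_axes = principal_axes)
  out <- file.path(out_dir, "mode_character.tsv")
  write_tsv_provenance(summ, out, params)
  paths <- out
  if (per_molecule) {
    out2 <- file.path(out_dir, "mode_character_molecules.tsv")
    write_tsv_provenance(chars, out2, params)
    paths <- c(paths, out2)
  }
  invisible(list(summary = summ, per_molecule = chars, files = paths))
}

#' Run the spectrum-synthesis pipeline
#'
#' Reads a stick spectrum (TSV/CSV with columns frequency_thz, intensity
#' or a mode JSON file), applies an optional frequency-scaling preset
#' (guarded against double application), Lorentzian broadening, optional
#' exponential baseline subtraction and peak picking.
#'
#' @param sticks_file Stick table (or mode JSON) path.
#' @param out_dir Output directory.
#' @param scale `"anhydrous"`, `"monohydrate"`, a positive number, or
#'   `"none"`.
#' @param fwhm Lorentzian FWHM in THz.
#' @param from,to,by Frequency grid (THz).
#' @param baseline Subtract a fitted exponential baseline before peak
#'   picking (only useful when the input rides on one).
#' @param min_prominence Peak prominence threshold.
#' @return Invisibly, list with `spectrum`, `peaks`, `files`.
#' @export
run_spectra <- function(sticks_file, out_dir = ".", scale = "none",
                        fwhm = 0.1, from = 0.2, to = 3.0, by = 0.002,
                        baseline = FALSE, min_prominence = 0) {
  if (!file.exists(sticks_file)) {
    stop("input file not found: ", sticks_file, call. = FALSE)
  }
  if (grepl("\\.json$", sticks_file)) {
    modes <- read_modes(sticks_file)
    sticks <- stick_spectrum(modes)
  } else {
    sticks <- utils::read.table(sticks_file, header = TRUE,
                                sep = "", comment.char = "#")
    names(sticks)[1:2] <- c("frequency_thz", "intensity")
  }
  factor_applied <- NA_real_
  if (!identical(scale, "none")) {
    if (is.character(scale)) {
      presets <- scaling_presets()
      if (!scale %in% names(presets)) {
        stop("unknown preset '", scale, "'; available: ",
             paste(c(names(presets), "none"), collapse = ", "),
             call. = FALSE)
      }
      factor_applied <- presets[[scale]]
    } else {
      factor_applied <- as.numeric(scale)
      if (!is.finite(factor_applied) || factor_applied <= 0) {
        stop("numeric scale must be positive", call. = FALSE)
      }
    }
    sticks$frequency_thz <- sticks$frequency_thz * factor_applied
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- broaden_spectrum(sticks, fwhm = fwhm, from = from, to = to, by = by)
  if (baseline && any(spec$alpha != 0)) {
    spec <- subtract_baseline(spec)$corrected
  }
  peaks <- if (nrow(sticks) == 0) {
    tibble::tibble(frequency_thz = numeric(), height = numeric(),
                   prominence = numeric())
  } else {
    find_peaks(spec, min_prominence = min_prominence)
  }
  params <- list(command = "spectra", sticks = sticks_file,
                 scale = scale, scaling_factor = factor_applied,
                 fwhm = fwhm, grid = c(from, to, by), baseline = baseline,
                 min_prominence = min_prominence)
  f1 <- file.path(out_dir, "spectrum.csv")
  writeLines(c(provenance_header(params), "frequency_thz,alpha_cm-1",
               sprintf("%.6f,%.8g", spec$frequency_thz, spec$alpha)), f1)
  f2 <- file.path(out_dir, "peaks.tsv")
  write_tsv_provenance(peaks, f2, params)
  invisible(list(spectrum = spec, peaks = peaks, files = c(f1, f2)))
}

#' Run the THz-TDS optical-constant extraction pipeline
#'
#' Reads reference and sample waveform files, extracts n and alpha with
#' the thick-slab transfer-function method and writes them as CSV.
#'
#' @param reference_file,sample_file Two-column waveform text files.
#' @param out_dir Output directory.
#' @param thickness_cm Pellet thickness in cm (falls back to the sample
#'   file header).
#' @param floor Dynamic-range floor for the valid band.
#' @return Invisibly, list with `optical_constants`, `files`.
#' @export
run_extract <- function(reference_file, sample_file, out_dir = ".",
                        thickness_cm = NULL, floor = 0.01) {
  for (f in c(reference_file, sample_file)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  ref <- read_waveform(reference_file, role = "reference")
  smp <- read_waveform(sample_file, role = "sample",
                       thickness_cm = thickness_cm)
  if (is.null(smp$thickness_cm)) {
    stop("thickness missing: pass thickness_cm or put '# thickness_cm=' ",
         "in the sample file header", call. = FALSE)
  }
  oc <- extract_optical_constants(ref, smp, floor = floor)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(command = "extract", reference = reference_file,
                 sample = sample_file, thickness_cm = smp$thickness_cm,
                 floor = floor)
  f1 <- file.path(out_dir, "optical_constants.csv")
  writeLines(c(provenance_header(params), "frequency_thz,n,alpha_cm-1,valid",
               sprintf("%.6f,%.8g,%.8g,%d", oc$frequency_thz, oc$n,
                       oc$alpha_cm, as.integer(oc$valid))), f1)
  invisible(list(optical_constants = oc, files = f1))
}

#' Run the hydrogen-bond analysis pipeline
#'
#' @param structure_file CIF path.
#' @param out_dir Output directory.
#' @param max_ha,min_angle Geometric criteria (Angstrom, degrees).
#' @return Invisibly, list with `hbonds`, `files`.
#' @export
run_hbonds <- function(structure_file, out_dir = ".", max_ha = 2.5,
                       min_angle = 120) {
  if (!file.exists(structure_file)) {
    stop("input file not found: ", structure_file, call. = FALSE)
  }
  xtal <- read_cif(structure_file)
  hb <- find_hydrogen_bonds(xtal, max_ha = max_ha, min_angle = min_angle)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(command = "hbonds", structure = structure_file,
                 max_ha = max_ha, min_angle = min_angle)
  f1 <- file.path(out_dir, "hydrogen_bonds.tsv")
  write_tsv_provenance(hb, f1, params)
  invisible(list(hbonds = hb, files = f1))
}

#' Generate a complete synthetic test set
#'
#' Writes a toy hydrate CIF, a prescribed-mixture mode JSON and a
#' reference/sample waveform pair — the same formats the analysis
#' pipelines consume.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for all three generators.
#' @return Invisibly, the list of files written.
#' @export
run_synth <- function(out_dir = ".", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  xtal <- make_toy_crystal(toy_crystal_spec(seed = seed))
  part <- partition_molecules(xtal)
  modes <- make_mode_field(part, mixture_spec(seed = seed))
  wf <- make_waveform_pair(seed = seed)
  f_cif <- file.path(out_dir, "toy_hydrate.cif")
  f_modes <- file.path(out_dir, "modes.json")
  f_ref <- file.path(out_dir, "reference.txt")
  f_smp <- file.path(out_dir, "sample.txt")
  write_cif(xtal, f_cif)
  write_modes(modes, f_modes)
  write_waveform(wf$reference, f_ref, comments = sprintf("# seed=%d", seed))
  write_waveform(wf$sample, f_smp, comments = sprintf("# seed=%d", seed))
  message("wrote ", paste(c(f_cif, f_modes, f_ref, f_smp), collapse = ", "))
  invisible(c(f_cif, f_modes, f_ref, f_smp))
}
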