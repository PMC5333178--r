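# End-to-end pipeline: load (or generate) -> attributes -> automatic
# simplification -> report exports, with a hashed artifact manifest so a
# rerun with the same configuration is verifiably identical.

#' Pipeline configuration
#'
#' Validated configuration for [run_all()]. Either `input` names the files
#' of a real dataset (multi-model PDB + ligand selector, optional PQR,
#' tunnel CSV and active-site spec), or it is `NULL` and the synthetic
#' default scenario with `seed`/`n_steps` is generated.
#'
#' @param outdir Output directory.
#' @param seed Random seed for the synthetic scenario (default 42).
#' @param n_steps Synthetic scenario length (default 2000).
#' @param input Optional list with elements `trajectory` (PDB path),
#'   `ligand` (selector), and optionally `charges`, `tunnel`, `active_site`
#'   (paths).
#' @param stuck_n,lining_k,cutoff Attribute parameters (see
#'   [derive_attributes()]).
#' @param thresholds A [category_thresholds()].
#' @param backend,nu,tau,eps_frac,window,order,dp_base Automatic
#'   simplification parameters (see [simplify_auto()]).
#' @param n_bins Bar-aggregation bin count (default 100).
#' @param scatter Character vector of two attribute names for the scatter
#'   export (default distance vs stuckness).
#' @param ... Rejected; unknown configuration keys are an error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 42, n_steps = 2000, input = NULL,
                       stuck_n = 4, lining_k = 3, cutoff = 2,
                       thresholds = category_thresholds(),
                       backend = "smooth", nu = 2, tau = NULL,
                       eps_frac = 0.01, window = 9, order = 2, dp_base = 0.5,
                       n_bins = 100, scatter = c("dist_active_site", "stuckness"),
                       ...) {
  extra <- list(...)
  if (length(extra) > 0)
    abort(paste0("unknown configuration key(s): ",
                 paste(names(extra), collapse = ", ")))
  if (!is.null(tau) && tau <= 0) abort("tau must be positive")
  if (eps_frac <= 0) abort("eps_frac must be positive")
  if (nu <= 0) abort("nu must be positive")
  if (stuck_n < 1) abort("stuck_n must be >= 1")
  if (!backend %in% c("smooth", "dp")) abort("backend must be smooth or dp")
  if (length(scatter) != 2) abort("scatter must name exactly two attributes")
  if (!is.null(input)) {
    unknown <- setdiff(names(input),
                       c("trajectory", "ligand", "charges", "tunnel", "active_site"))
    if (length(unknown) > 0)
      abort(paste0("unknown input key(s): ", paste(unknown, collapse = ", ")))
    if (is.null(input$trajectory) || is.null(input$ligand))
      abort("input needs at least trajectory and ligand")
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_steps = as.integer(n_steps), input = input,
                 stuck_n = stuck_n, lining_k = lining_k, cutoff = cutoff,
                 thresholds = thresholds, backend = backend, nu = nu,
                 tau = tau, eps_frac = eps_frac, window = window,
                 order = order, dp_base = dp_base, n_bins = n_bins,
                 scatter = scatter),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML mapping of [run_config()] arguments; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @param outdir Output directory (overrides any `outdir` key in the file).
#' @return A `run_config`.
#' @export
load_run_config <- function(path, outdir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(outdir)) raw$outdir <- outdir
  if (!is.null(raw$thresholds)) raw$thresholds <- do.call(category_thresholds, raw$thresholds)
  if (!is.null(raw$scatter)) raw$scatter <- as.character(raw$scatter)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Executes load (or synthetic generation) -> attribute derivation ->
#' automatic simplification -> report exports, writing every artifact under
#' `config$outdir` together with a manifest JSON listing each file with its
#' MD5 content hash. Any stage error aborts with the stage name, and
#' partially written outputs are removed.
#'
#' @param config A [run_config()].
#' @return A list with `manifest` (tibble: `artifact`, `path`, `md5`),
#'   `table`, `simplification` and `scenario` (when synthetic), invisibly.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) abort("config must be a run_config()")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  scenario <- NULL
  data <- stage("load", {
    if (is.null(config$input)) {
      scenario <- generate_scenario(
        scenario_spec(seed = config$seed, n_steps = config$n_steps))
      list(frames = scenario$frames, ligand = scenario$ligand,
           ligand_atoms = scenario$ligand_atoms,
           active_site = scenario$active_site, tunnel = NULL)
    } else {
      loaded <- load_frameset(config$input$trajectory, config$input$ligand,
                              charges_path = config$input$charges)
      list(frames = loaded$frames, ligand = loaded$ligand,
           ligand_atoms = loaded$ligand_atoms,
           active_site = load_active_site(config$input$active_site),
           tunnel = if (!is.null(config$input$tunnel))
             load_tunnel_profile(config$input$tunnel))
    }
  })

  table <- stage("attributes", {
    tab <- derive_attributes(
      data$frames, data$ligand, data$active_site,
      ligand_atoms = data$ligand_atoms, tunnel = data$tunnel,
      stuck_n = config$stuck_n, lining_k = config$lining_k,
      cutoff = config$cutoff, thresholds = config$thresholds)
    write_attribute_table(tab, note(file.path(outdir, "attributes.csv")), "csv")
    write_attribute_table(tab, note(file.path(outdir, "attributes.json")), "json")
    tab
  })

  simp <- stage("simplify", {
    s <- simplify_auto(data$ligand, tau = config$tau, eps_frac = config$eps_frac,
                       nu = config$nu, backend = config$backend,
                       window = config$window, order = config$order,
                       dp_base = config$dp_base)
    write_trajectory(s$trajectory, note(file.path(outdir, "simplified.pdb")), "pdb")
    write_trajectory(s$trajectory, note(file.path(outdir, "simplified.csv")), "csv")
    write_simplification_state(s, note(file.path(outdir, "state.json")))
    s
  })

  stage("report", {
    build_overview(table, csv = note(file.path(outdir, "overview.csv")),
                   png = note(file.path(outdir, "overview.png")))
    build_residue_timelines(lining_table(table), "hydrophobicity",
                            csv = note(file.path(outdir, "timelines.csv")),
                            png = note(file.path(outdir, "timelines.png")))
    scat_name <- paste0("scatter_", config$scatter[1], "_", config$scatter[2])
    export_scatter_data(table, config$scatter[1], config$scatter[2],
                        window = config$window,
                        csv = note(file.path(outdir, paste0(scat_name, ".csv"))),
                        png = note(file.path(outdir, paste0(scat_name, ".png"))))
    bars <- aggregate_bars(table$free_space, config$n_bins, table$category)
    readr::write_csv(bars, note(file.path(outdir, "bars_free_space.csv")))
  })

  manifest <- stage("manifest", {
    files <- sort(written[file.exists(written)])
    man <- tibble(artifact = basename(files), path = files,
                  md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
    man
  })

  invisible(list(manifest = manifest, table = table, simplification = simp,
                 scenario = scenario))
}
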