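# ligand molecular weights used to convert mass doses to molar (kDa);
# conversion factors are configuration data, not code constants
LIGAND_MW_KDA <- c(egf = 6.2, insulin = 5.808)

#' Convert a mass-per-volume ligand dose to nanomolar
#' @param ngml Dose in ng/mL.
#' @param mw_kda Molecular weight in kDa.
#' @return Dose in nM.
#' @export
ngml_to_nM <- function(ngml, mw_kda) ngml / mw_kda

#' Construct an experiment configuration
#'
#' Doses are given in assay units (EGF ng/mL, insulin ug/mL, TRAIL ng/mL,
#' inhibitors and etoposide uM) and converted to the engine's units at run
#' time. All stimuli are applied at time zero of the experiment (after the
#' 24-h stochastic population pre-run).
#'
#' @param name Label.
#' @param egf_ngml,ins_ugml,trail_ngml,meki_um,akti_um,etop_um Doses.
#' @param duration_h Simulated duration, hours.
#' @param n_cells Population size.
#' @param base_seed Base RNG seed; cell i uses `base_seed + i`.
#' @param save_stride_min Trajectory save stride, minutes.
#' @param readout_times Hours at which population summaries are taken.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(name, egf_ngml = 0, ins_ugml = 0,
                              trail_ngml = 0, meki_um = 0, akti_um = 0,
                              etop_um = 0, duration_h = 72, n_cells = 100,
                              base_seed = 1L, save_stride_min = 6,
                              readout_times = c(24, 48, 72)) {
  stopifnot(n_cells >= 1, duration_h > 0,
            egf_ngml >= 0, ins_ugml >= 0, trail_ngml >= 0,
            meki_um >= 0, akti_um >= 0, etop_um >= 0)
  structure(list(name = name, egf_ngml = egf_ngml, ins_ugml = ins_ugml,
                 trail_ngml = trail_ngml, meki_um = meki_um,
                 akti_um = akti_um, etop_um = etop_um,
                 duration_h = duration_h, n_cells = as.integer(n_cells),
                 base_seed = as.integer(base_seed),
                 save_stride_min = save_stride_min,
                 readout_times = readout_times),
            class = "experiment_config")
}

#' Engine dose vector for a config
#' @param config An `experiment_config`.
#' @return Named numeric vector in engine units.
#' @export
config_inputs <- function(config) {
  c(egf = ngml_to_nM(config$egf_ngml, LIGAND_MW_KDA[["egf"]]),
    ins = ngml_to_nM(config$ins_ugml * 1000, LIGAND_MW_KDA[["insulin"]]),
    trail = config$trail_ngml,
    meki = config$meki_um,
    akti = config$akti_um,
    etop = config$etop_um)
}

#' Validate an experiment configuration
#' @param config An `experiment_config`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  req <- c("name", "egf_ngml", "ins_ugml", "trail_ngml", "meki_um",
           "akti_um", "etop_um", "duration_h", "n_cells", "base_seed",
           "save_stride_min", "readout_times")
  missing <- setdiff(req, names(config))
  if (length(missing)) stop("config missing fields: ",
                            paste(missing, collapse = ", "))
  stopifnot(config$n_cells >= 1, config$duration_h > 0,
            all(config$readout_times <= config$duration_h + 1e-9))
  invisible(TRUE)
}

#' Canned experiment configurations of the study scenarios
#'
#' Serum starvation, EGF (20 ng/mL) + insulin (10 ug/mL), single and combined
#' MEK/AKT inhibition (10 uM each), etoposide (100 uM) with and without
#' mitogens, and a TRAIL dose ladder (2-300 ng/mL).
#'
#' @param n_cells Population size used for each config.
#' @param base_seed Base RNG seed.
#' @return Named list of `experiment_config` objects.
#' @export
make_experiment_configs <- function(n_cells = 100, base_seed = 1L) {
  ec <- function(name, ...) experiment_config(name, n_cells = n_cells,
                                              base_seed = base_seed, ...)
  trail_doses <- c(2, 10, 30, 100, 300)
  trail <- lapply(trail_doses, function(d)
    ec(sprintf("trail_%g", d), trail_ngml = d, duration_h = 24,
       readout_times = c(5, 24)))
  names(trail) <- sprintf("trail_%g", trail_doses)
  c(list(
    starved = ec("starved"),
    gf = ec("gf", egf_ngml = 20, ins_ugml = 10),
    egf = ec("egf", egf_ngml = 20),
    insulin = ec("insulin", ins_ugml = 10),
    gf_meki = ec("gf_meki", egf_ngml = 20, ins_ugml = 10, meki_um = 10),
    gf_akti = ec("gf_akti", egf_ngml = 20, ins_ugml = 10, akti_um = 10),
    gf_meki_akti = ec("gf_meki_akti", egf_ngml = 20, ins_ugml = 10,
                      meki_um = 10, akti_um = 10),
    etop = ec("etop", etop_um = 100),
    gf_etop = ec("gf_etop", egf_ngml = 20, ins_ugml = 10, etop_um = 100),
    meki = ec("meki", meki_um = 10),
    akti = ec("akti", akti_um = 10)
  ), trail)
}

#' Serialize / deserialize experiment configs as JSON
#' @param configs Named list of `experiment_config` objects.
#' @param path File path.
#' @export
write_configs <- function(configs, path) {
  jsonlite::write_json(lapply(configs, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_configs
#' @export
read_configs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) {
    x$readout_times <- as.numeric(unlist(x$readout_times))
    do.call(experiment_config, x)
  })
}
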