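#' Measurement noise model for synthetic titrations
#'
#' @param sigma_reading reading noise (pH units or mV, matching the curve's
#'   reading kind).
#' @param sigma_volume burette delivery noise, mL (applied to the delivered
#'   volume before the equilibrium is evaluated, i.e. the reading reflects
#'   the true delivered volume while the nominal volume is recorded).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a `noise_model` object.
#' @export
noise_model <- function(sigma_reading = 0.003, sigma_volume = 0.002,
                        seed = 1L) {
  stopifnot(sigma_reading >= 0, sigma_volume >= 0)
  structure(list(sigma_reading = sigma_reading,
                 sigma_volume = sigma_volume, seed = as.integer(seed)),
            class = "noise_model")
}

# Run code under a local RNG stream without disturbing the global state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate replicate noisy titration curves
#'
#' Each replicate perturbs the delivered volumes (jittered, then sorted)
#' and the readings independently.  With zero noise the replicates equal
#' the noiseless [simulate_titration()] output.
#'
#' @param db an `equilibrium_database` carrying the generative constants.
#' @param protocol a [titration_protocol()].
#' @param noise a [noise_model()].
#' @param replicates number of replicate curves (>= 1).
#' @param reading_kind `"pH"` or `"emf"`.
#' @return list of `titration_curve`s; generative metadata attached to each.
#' @export
make_titration_dataset <- function(db, protocol, noise = noise_model(),
                                   replicates = 2L,
                                   reading_kind = c("pH", "emf")) {
  reading_kind <- match.arg(reading_kind)
  stopifnot(replicates >= 1L)
  clean <- simulate_titration(db, protocol, reading_kind = reading_kind)
  v_nom <- clean$volume_mL
  with_local_seed(noise$seed, {
    lapply(seq_len(replicates), function(r) {
      v_act <- sort(v_nom + stats::rnorm(length(v_nom), 0,
                                         noise$sigma_volume))
      v_act <- pmax(v_act, 0)
      cv <- if (noise$sigma_volume > 0)
        simulate_titration(db, protocol, reading_kind = reading_kind,
                           volumes = v_act, replicate = r)
      else { x <- clean; x$replicate <- r; x }
      cv$volume_mL <- v_nom
      cv$reading <- cv$reading + stats::rnorm(length(v_nom), 0,
                                              noise$sigma_reading)
      attr(cv, "generative") <- list(db_version = db$version,
                                     seed = noise$seed, replicate = r)
      cv
    })
  })
}

#' Jittered soil/nutrient solution composition
#'
#' Applies multiplicative log-uniform jitter (factor in
#' \[1 - jitter, 1 + jitter\], uniform in log) to each total of a base
#' composition; pH/Eh/I come from the scenario configuration.
#'
#' @param base_composition named totals, mol/dm^3.
#' @param jitter_fraction in \[0, 1).
#' @param seed integer seed.
#' @return named totals vector.
#' @export
make_soil_solution <- function(base_composition, jitter_fraction = 0,
                               seed = 1L) {
  stopifnot(jitter_fraction >= 0, jitter_fraction < 1)
  if (jitter_fraction == 0) return(base_composition)
  with_local_seed(seed, {
    f <- exp(stats::runif(length(base_composition),
                          log(1 - jitter_fraction),
                          log(1 + jitter_fraction)))
    base_composition * f
  })
}

#' The nutrient-solution base composition of the pot-trial scenario
#'
#' 0.5 mmol/dm^3 MgSO4, 0.5 umol/dm^3 MnSO4, 0.2 umol/dm^3 CuSO4,
#' 0.5 umol/dm^3 ZnSO4 and 0.1 mmol/dm^3 Fe(III)-EDTA, expressed as
#' component totals (sulfate pooled; EDTA equimolar with iron).
#'
#' @param pdma_total PDMA dose, mol/dm^3 (default sub-stoichiometric to
#'   the Zn pool; the free-ligand fertilizer dose is scavenged in soil).
#' @param jitter_fraction multiplicative log-uniform jitter applied per
#'   *salt* (Fe and EDTA stay equimolar: they enter as one compound).
#' @param seed jitter seed.
#' @return named totals vector.
#' @export
suzuki_nutrient_solution <- function(pdma_total = 2.5e-7,
                                     jitter_fraction = 0, seed = 1L) {
  salts <- c(MgSO4 = 5e-4, MnSO4 = 5e-7, CuSO4 = 2e-7, ZnSO4 = 5e-7,
             FeEDTA = 1e-4, PDMA = pdma_total)
  salts <- make_soil_solution(salts, jitter_fraction, seed)
  c(Mg = salts[["MgSO4"]], Mn = salts[["MnSO4"]], Cu = salts[["CuSO4"]],
    Zn = salts[["ZnSO4"]], Fe3 = salts[["FeEDTA"]],
    Edta = salts[["FeEDTA"]],
    SO4 = sum(salts[c("MgSO4", "MnSO4", "CuSO4", "ZnSO4")]),
    Pdma = salts[["PDMA"]])
}
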