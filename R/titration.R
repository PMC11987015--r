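#' Potentiometric titration protocol
#'
#' The experiment layout: a 30 mL analyte solution (ligand slightly in
#' excess over the metal to avoid hydrolysis interference, plus a strong
#' acid excess so the first point sits near pH 2.8) titrated with
#' carbonate-free NaOH in a constant NaCl medium, 80-100 points across
#' pH 3-10.
#'
#' @param totals named analyte totals, mol/dm^3, on the fully deprotonated
#'   ligand basis (default PDMA 6.7e-4 with metal 6.0e-4 supplied via
#'   `metal`).
#' @param metal optional metal component name added at `metal_total`.
#' @param metal_total metal concentration, mol/dm^3.
#' @param V0 initial volume, mL.
#' @param base_conc NaOH titrant concentration, mol/dm^3.
#' @param electrolyte NaCl concentration, mol/dm^3 (also the fixed ionic
#'   strength).
#' @param acid_excess initial strong-acid excess, mol/dm^3; `NULL` solves
#'   for the excess that puts the untitrated solution at `start_pH`.
#' @param start_pH target initial pH when `acid_excess` is NULL.
#' @param n_points number of titration points.
#' @param pH_window pH range covered by the curve.
#' @param T_K temperature, kelvin.
#' @param E0 reference electrode potential, mV (emf readings).
#' @param slope electrode slope, mV/decade; default Nernstian at `T_K`.
#' @return a `titration_protocol` object.
#' @export
titration_protocol <- function(totals = c(Pdma = 6.7e-4), metal = NULL,
                               metal_total = 6.0e-4, V0 = 30,
                               base_conc = 0.1, electrolyte = 0.15,
                               acid_excess = NULL, start_pH = 2.8,
                               n_points = 90L, pH_window = c(3, 10),
                               T_K = 298.1, E0 = 400,
                               slope = nernst_slope_mV(T_K)) {
  stopifnot(V0 > 0, base_conc > 0, n_points >= 2L)
  if (!is.null(metal)) {
    if (metal_total > sum(totals[grep("Pdma|Dma", names(totals))], na.rm = TRUE) &&
        length(totals))
      stop("ligand total must be at least the metal total")
    totals[metal] <- metal_total
  }
  structure(list(totals = totals, V0 = V0, base_conc = base_conc,
                 electrolyte = electrolyte, acid_excess = acid_excess,
                 start_pH = start_pH, n_points = as.integer(n_points),
                 pH_window = pH_window, T_K = T_K, E0 = E0, slope = slope),
            class = "titration_protocol")
}

# Analyte totals after adding v mL titrant (dilution-corrected); the NaCl
# medium is present in analyte and titrant alike, so Cl is undiluted.
.titr_totals <- function(protocol, v, acid_excess) {
  dil <- protocol$V0 / (protocol$V0 + v)
  tt <- protocol$totals * dil
  tt["H"] <- (protocol$V0 * acid_excess - v * protocol$base_conc) /
    (protocol$V0 + v)
  tt["Cl"] <- protocol$electrolyte
  tt
}

.titr_spec <- function(protocol, tt) {
  solution_spec(totals = tt, pH = NULL, pe = NULL, I = protocol$electrolyte,
                pH_scale = "concentration", T_K = protocol$T_K)
}

# -log10 [H+] at titrant volume v.
.titr_pH <- function(db, protocol, v, acid_excess, start = NULL) {
  res <- solve_equilibrium(db, .titr_spec(protocol,
                                          .titr_totals(protocol, v,
                                                       acid_excess)),
                           start = start)
  list(pH = -log10(res$free[["H"]]), x = res$x)
}

# Strong-acid excess giving pH = start_pH at v = 0.
.solve_acid_excess <- function(db, protocol) {
  if (!is.null(protocol$acid_excess)) return(protocol$acid_excess)
  f <- function(a) .titr_pH(db, protocol, 0, a)$pH - protocol$start_pH
  stats::uniroot(f, c(1e-5, 0.05), tol = 1e-10)$root
}

#' Simulate a potentiometric titration curve
#'
#' For each titrant volume the dilution-corrected totals are speciated (on
#' the concentration pH scale, fixed ionic strength of the NaCl medium) and
#' the reading is -log10\[H+\] or the electrode emf
#' E0 + slope * log10\[H+\].  Volumes are chosen to span the protocol's pH
#' window unless given explicitly.
#'
#' @param db an `equilibrium_database`.
#' @param protocol a [titration_protocol()].
#' @param reading_kind `"pH"` or `"emf"`.
#' @param volumes optional explicit titrant volumes (mL); otherwise
#'   `n_points` evenly spaced volumes across the pH window.
#' @param replicate replicate identifier stored with the curve.
#' @return a `titration_curve` data.frame (volume_mL, reading,
#'   reading_kind, replicate) with the protocol and acid excess attached
#'   as attributes.
#' @export
simulate_titration <- function(db, protocol, reading_kind = c("pH", "emf"),
                               volumes = NULL, replicate = 1L) {
  reading_kind <- match.arg(reading_kind)
  acid <- .solve_acid_excess(db, protocol)
  if (is.null(volumes)) {
    ## equivalents available to the base: strong acid + remaining ligand and
    ## hydroxo-releasable protons; generous bracket for the root search
    vmax <- 1.5 * protocol$V0 *
      (acid + 6 * sum(abs(protocol$totals))) / protocol$base_conc + 0.5
    pH_at <- local({
      start <- NULL
      function(v) {
        out <- .titr_pH(db, protocol, v, acid, start = NULL)
        out$pH
      }
    })
    v_hi <- stats::uniroot(function(v) pH_at(v) - protocol$pH_window[2],
                           c(0, vmax), tol = 1e-7)$root
    v_lo <- if (pH_at(0) >= protocol$pH_window[1]) 0 else
      stats::uniroot(function(v) pH_at(v) - protocol$pH_window[1],
                     c(0, v_hi), tol = 1e-7)$root
    volumes <- seq(v_lo, v_hi, length.out = protocol$n_points)
  }
  ph <- numeric(length(volumes))
  start <- NULL
  for (i in seq_along(volumes)) {
    out <- tryCatch(.titr_pH(db, protocol, volumes[i], acid, start = start),
                    error = function(e)
                      stop("titration point did not converge at v = ",
                           signif(volumes[i], 6), " mL: ",
                           conditionMessage(e)))
    ph[i] <- out$pH
    start <- out$x
  }
  reading <- if (reading_kind == "pH") ph else protocol$E0 - protocol$slope * ph
  curve <- data.frame(volume_mL = volumes, reading = reading,
                      reading_kind = reading_kind,
                      replicate = replicate, stringsAsFactors = FALSE)
  attr(curve, "protocol") <- protocol
  attr(curve, "acid_excess") <- acid
  class(curve) <- c("titration_curve", "data.frame")
  curve
}

#' Calibrate a glass electrode against a strong acid / strong base titration
#'
#' Least-squares fit of E = E0 + slope * log10\[H+\] on points away from the
#' equivalence region, where \[H+\] follows from the strong acid/base
#' stoichiometry analytically.
#'
#' @param curve emf titration curve of a strong acid (no ligand/metal).
#' @param acid_conc strong acid concentration in the analyte, mol/dm^3.
#' @param V0 initial volume, mL; defaults from the curve's protocol.
#' @param base_conc titrant concentration, mol/dm^3.
#' @param I ionic strength (for the conditional water ion product).
#' @param slope_fixed if non-NULL, hold the slope and fit E0 only.
#' @param exclusion minimum |strong acid excess| (mol/dm^3) for a point to
#'   enter the fit.
#' @return an `electrode_calibration` list: `E0`, `slope`, standard errors,
#'   residual sd, points used.
#' @export
calibrate_electrode <- function(curve, acid_conc, V0 = NULL, base_conc = NULL,
                                I = 0.15, slope_fixed = NULL,
                                exclusion = 1e-4) {
  proto <- attr(curve, "protocol")
  if (is.null(V0)) V0 <- proto$V0
  if (is.null(base_conc)) base_conc <- proto$base_conc
  if (!all(curve$reading_kind == "emf"))
    stop("electrode calibration needs emf readings")
  v <- curve$volume_mL
  net <- (V0 * acid_conc - v * base_conc) / (V0 + v)
  Kw_c <- 10^intrinsic_to_conditional(-13.997, 2, I)
  use <- abs(net) > exclusion
  if (sum(use & net > 0) < 3)
    stop("insufficient acid-side points for electrode calibration")
  h <- ifelse(net > 0,
              (net + sqrt(net^2 + 4 * Kw_c)) / 2,
              Kw_c / ((-net + sqrt(net^2 + 4 * Kw_c)) / 2))
  lh <- log10(h[use]); E <- curve$reading[use]
  if (is.null(slope_fixed)) {
    fit <- stats::lm(E ~ lh)
    E0 <- unname(stats::coef(fit)[1]); slope <- unname(stats::coef(fit)[2])
    se <- sqrt(diag(stats::vcov(fit)))
  } else {
    slope <- slope_fixed
    E0 <- mean(E - slope * lh)
    se <- c(stats::sd(E - slope * lh) / sqrt(length(E)), NA_real_)
  }
  nernst <- nernst_slope_mV(if (!is.null(proto)) proto$T_K else 298.1)
  non_nernstian <- abs(abs(slope) - nernst) / nernst > 0.05
  structure(list(E0 = E0, slope = slope, se_E0 = se[1], se_slope = se[2],
                 residual_sd = stats::sd(E - (E0 + slope * lh)),
                 n_used = sum(use), non_nernstian = non_nernstian),
            class = "electrode_calibration")
}

#' Refine stability constants from titration curves
#'
#' Joint Levenberg-Marquardt minimisation of the weighted squared
#' differences between observed and calculated readings over all supplied
#' curves at once (replicates refined as a single set).  Parameters are the
#' conditional cumulative formation constants (at the curve medium's ionic
#' strength) of the species in `refine_set`; all other constants stay
#' fixed.  Weights follow the standard potentiometric error model
#' w = 1 / (sigma_reading^2 + (dR/dV)^2 sigma_v^2).
#'
#' @param db an `equilibrium_database` holding the chemical model.
#' @param curves a `titration_curve` or list of them (each carrying its
#'   protocol attribute).
#' @param refine_set character vector of species names to refine.
#' @param start optional named starting values (conditional log beta at the
#'   medium ionic strength); defaults to the database values.
#' @param sigma_reading reading error (pH units or mV, per reading kind).
#' @param sigma_volume burette error, mL.
#' @param min_formation species never reaching this fraction of any of its
#'   components across the curves are flagged ill-conditioned and dropped.
#' @return a `refinement_result`: refined values with 1-sigma standard
#'   deviations, correlation matrix, per-curve residual statistics,
#'   objective trace, convergence flag.
#' @export
refine_constants <- function(db, curves, refine_set, start = NULL,
                             sigma_reading = NULL, sigma_volume = 0.002,
                             min_formation = 0.01) {
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  if (!length(curves)) stop("at least one titration curve is required")
  idx <- match(refine_set, db$species$species)
  if (anyNA(idx))
    stop("refine_set species absent from the database: ",
         paste(refine_set[is.na(idx)], collapse = ", "))
  I_ref <- attr(curves[[1]], "protocol")$electrolyte
  base <- db
  cond0 <- intrinsic_to_conditional(db$species$log_beta0[idx],
                                    db$species$delta_z2[idx], I_ref,
                                    db$model)
  names(cond0) <- refine_set
  par0 <- if (is.null(start)) cond0 else {
    stopifnot(all(refine_set %in% names(start)))
    start[refine_set]
  }
  if (is.null(sigma_reading))
    sigma_reading <- if (curves[[1]]$reading_kind[1] == "pH") 0.003 else 0.1

  set_pars <- function(p) {
    db2 <- base
    db2$species$log_beta0[idx] <-
      conditional_to_intrinsic(p, db2$species$delta_z2[idx], I_ref,
                               db2$model)
    db2
  }
  calc_curve <- function(db2, curve) {
    proto <- attr(curve, "protocol")
    acid <- attr(curve, "acid_excess")
    stopifnot(!is.null(proto), !is.null(acid))
    ph <- numeric(nrow(curve)); st <- NULL
    for (i in seq_len(nrow(curve))) {
      out <- .titr_pH(db2, proto, curve$volume_mL[i], acid, start = st)
      ph[i] <- out$pH; st <- out$x
    }
    if (curve$reading_kind[1] == "pH") ph else proto$E0 - proto$slope * ph
  }

  ## ill-conditioning screen with the starting model
  db_st <- set_pars(par0)
  keep <- logical(length(refine_set))
  for (cv in curves) {
    proto <- attr(cv, "protocol"); acid <- attr(cv, "acid_excess")
    vv <- cv$volume_mL[round(seq(1, nrow(cv), length.out = min(15, nrow(cv))))]
    st <- NULL
    for (v in vv) {
      res <- solve_equilibrium(db_st, .titr_spec(proto,
                                                 .titr_totals(proto, v, acid)),
                               start = st)
      st <- res$x
      fr <- res$fractions
      for (k in seq_along(refine_set))
        if (any(fr$species == refine_set[k] &
                fr$fraction >= min_formation, na.rm = TRUE))
          keep[k] <- TRUE
    }
  }
  if (any(!keep)) {
    warning("ill-conditioned (never >= ", min_formation * 100,
            "% of any component): ",
            paste(refine_set[!keep], collapse = ", "), "; excluded")
    refine_set <- refine_set[keep]
    idx <- idx[keep]; par0 <- par0[keep]
    if (!length(refine_set)) stop("no refinable species left")
  }

  w <- lapply(curves, function(cv) {
    dRdV <- stats::splinefun(cv$volume_mL, cv$reading)(cv$volume_mL,
                                                       deriv = 1)
    1 / (sigma_reading^2 + dRdV^2 * sigma_volume^2)
  })
  obs <- lapply(curves, `[[`, "reading")
  resid_fn <- function(p) {
    db2 <- set_pars(stats::setNames(p, refine_set))
    unlist(lapply(seq_along(curves), function(i)
      sqrt(w[[i]]) * (obs[[i]] - calc_curve(db2, curves[[i]]))))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-10))
  p_hat <- stats::setNames(fit$par, refine_set)
  r <- resid_fn(p_hat)
  n <- length(r); np <- length(p_hat)
  J <- num_jacobian(resid_fn, p_hat)
  JtJ <- crossprod(J)
  s2 <- sum(r^2) / max(n - np, 1)
  cov <- tryCatch(solve(JtJ) * s2, error = function(e)
    matrix(NA_real_, np, np))
  sig <- sqrt(pmax(diag(cov), 0))
  corr <- if (all(is.finite(sig)) && all(sig > 0))
    cov / tcrossprod(sig) else diag(np)
  per_curve <- do.call(rbind, lapply(seq_along(curves), function(i) {
    db2 <- set_pars(p_hat)
    ri <- obs[[i]] - calc_curve(db2, curves[[i]])
    data.frame(replicate = curves[[i]]$replicate[1], n = length(ri),
               rmse = sqrt(mean(ri^2)), max_abs = max(abs(ri)))
  }))
  structure(list(estimates = p_hat, sigma = stats::setNames(sig, refine_set),
                 I_ref = I_ref, correlation = corr,
                 fixed = setdiff(db$species$species, refine_set),
                 per_curve = per_curve, rsstrace = fit$rsstrace,
                 deviance = fit$deviance,
                 converged = fit$info %in% 1:4, info = fit$info,
                 message = fit$message),
            class = "refinement_result")
}

num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (k in seq_along(p)) {
    pk <- p; h <- eps * max(1, abs(p[k])); pk[k] <- pk[k] + h
    J[, k] <- (f(pk) - f0) / h
  }
  J
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("<refinement_result>", if (x$converged) "converged" else
    "NOT converged", "\n")
  print(data.frame(log_beta = x$estimates, sigma = x$sigma))
  invisible(x)
}
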