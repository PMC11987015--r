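#' Specify a solution condition
#'
#' A fully specified solution for the equilibrium solver: analytical totals
#' per component, optionally a fixed pH and/or fixed pe (fixed-activity
#' components excluded from mass balance, the convention speciation codes
#' use for pH/Eh sweeps), the ionic strength treatment, and the temperature.
#'
#' @param totals named numeric vector of analytical totals, mol/dm^3.
#'   A negative value is allowed only for the proton component (excess
#'   strong base).  Components with total zero are dropped.
#' @param pH fixed pH, or NULL to balance total proton.
#' @param pe fixed pe (use [eh_to_pe()] for Eh in mV), or NULL for no
#'   redox coupling (ferrous/ferric and cuprous/cupric then behave as
#'   independent components).
#' @param I ionic strength, mol/dm^3 (fixed mode), normally the background
#'   electrolyte concentration.
#' @param ionic_strength_mode `"fixed"` (default) or `"self_consistent"`
#'   (I recomputed from the speciated charges, outer iteration).
#' @param pH_scale `"activity"` (pH = -log10 a_H, geochemical-code
#'   convention) or `"concentration"` (pH = -log10 [H+], potentiometric
#'   convention).
#' @param T_K temperature, kelvin.
#' @param allow_solids let supersaturated solids precipitate to SI = 0
#'   (requires fixed pH).
#' @return an object of class `solution_spec`.
#' @export
solution_spec <- function(totals, pH = NULL, pe = NULL, I = 0.1,
                          ionic_strength_mode = c("fixed", "self_consistent"),
                          pH_scale = c("activity", "concentration"),
                          T_K = 298.1, allow_solids = FALSE) {
  ionic_strength_mode <- match.arg(ionic_strength_mode)
  pH_scale <- match.arg(pH_scale)
  if (is.null(names(totals)) || any(!nzchar(names(totals))))
    stop("`totals` must be a named vector")
  neg <- names(totals)[totals < 0 & names(totals) != "H"]
  if (length(neg))
    stop("negative total for component(s): ", paste(neg, collapse = ", "))
  if (I <= 0) stop("fixed ionic strength must be positive")
  structure(list(totals = totals, pH = pH, pe = pe, I = I,
                 ionic_strength_mode = ionic_strength_mode,
                 pH_scale = pH_scale, T_K = T_K,
                 allow_solids = allow_solids),
            class = "solution_spec")
}

# ---------------------------------------------------------------------------
# Tableau assembly: pick components, apply the redox rewrite when pe is
# fixed, convert intrinsic constants to conditional at the working ionic
# strength, and build the stoichiometry matrix.
# ---------------------------------------------------------------------------
build_tableau <- function(db, spec, I = spec$I) {
  totals <- spec$totals
  zc <- stats::setNames(db$components$charge, db$components$name)
  unknown <- setdiff(names(totals), db$components$name)
  if (length(unknown))
    stop("totals name component(s) absent from the database: ",
         paste(unknown, collapse = ", "))

  sp <- db$species
  stoich <- sp$stoich
  logb0 <- sp$log_beta0
  charge <- sp$charge
  phase <- sp$phase
  spname <- sp$species

  fix_H <- !is.null(spec$pH)
  fix_e <- !is.null(spec$pe)

  ## redox rewrite: pool reduced components onto their oxidized masters
  pooled_from <- character(0)
  if (fix_e && nrow(db$redox_couples)) {
    rc <- db$redox_couples
    rc_red <- sub("_red$", "", rc$species)
    for (k in seq_len(nrow(rc))) {
      red <- rc_red[k]
      st_c <- rc$stoich[[k]]
      ox <- setdiff(names(st_c), "e")
      ## the free reduced ion becomes an ordinary species of the master
      stoich <- c(stoich, list(st_c))
      logb0 <- c(logb0, rc$log_beta0[k])
      charge <- c(charge, rc$charge[k])
      phase <- c(phase, "aqueous")
      spname <- c(spname, red)
      ## rewrite every species built on the reduced component
      for (j in seq_along(stoich)) {
        stj <- stoich[[j]]
        if (red %in% names(stj) && spname[j] != red) {
          n <- stj[[red]]
          stj <- stj[names(stj) != red]
          stj[ox] <- (if (ox %in% names(stj)) stj[[ox]] else 0) + n
          stj["e"] <- (if ("e" %in% names(stj)) stj[["e"]] else 0) + n
          stoich[[j]] <- stj
          logb0[j] <- logb0[j] + n * rc$log_beta0[k]
        }
      }
      if (red %in% names(totals)) {
        totals[ox] <- (if (ox %in% names(totals)) totals[[ox]] else 0) +
          totals[[red]]
        totals <- totals[names(totals) != red]
        pooled_from <- c(pooled_from, stats::setNames(ox, red))
      }
    }
  }

  fixed <- character(0)
  if (fix_H) fixed <- c(fixed, "H")
  if (fix_e) fixed <- c(fixed, "e")
  free <- setdiff(names(totals)[abs(totals) > 0 | names(totals) == "H"],
                  fixed)
  ## H participates implicitly whenever fixed; when neither fixed nor given
  ## a total, protonated species cannot be formed meaningfully
  avail <- c(free, fixed)
  if (!length(free) || all(abs(totals[free]) == 0))
    if (!any(abs(totals) > 0)) stop("all totals are zero")

  keep <- vapply(stoich, function(st) all(names(st) %in% avail), logical(1))
  keep <- keep & phase != "couple"
  is_solid <- phase == "solid"
  keep_aq <- keep & !is_solid
  keep_solid <- keep & is_solid & isTRUE(spec$allow_solids)

  ## identity rows for free components
  nm <- c(free, spname[keep_aq])
  all_st <- c(lapply(free, function(f) stats::setNames(1, f)),
              stoich[keep_aq])
  zsp <- c(unname(zc[free]), charge[keep_aq])
  lb0 <- c(rep(0, length(free)), logb0[keep_aq])

  dz2 <- mapply(function(z, st) reaction_delta_z2(z, st, zc), zsp, all_st)
  logbc <- intrinsic_to_conditional(lb0, dz2, I, db$model)

  A <- matrix(0, length(nm), length(avail),
              dimnames = list(nm, avail))
  for (j in seq_along(all_st)) A[j, names(all_st[[j]])] <- all_st[[j]]

  ## fixed-component concentrations (conditional, concentration scale)
  lnc_fix <- numeric(0)
  if (fix_H) {
    gH <- if (spec$pH_scale == "activity")
      davies_log_gamma(1, I, db$model) else 0
    lnc_fix["H"] <- log(10) * (-spec$pH - gH)
  }
  if (fix_e) lnc_fix["e"] <- log(10) * (-spec$pe)

  solids <- NULL
  if (any(keep_solid)) {
    sd_st <- stoich[keep_solid]
    sd_dz2 <- mapply(function(z, st) reaction_delta_z2(z, st, zc),
                     charge[keep_solid], sd_st)
    solids <- list(name = spname[keep_solid], stoich = sd_st,
                   logbc = intrinsic_to_conditional(logb0[keep_solid],
                                                    sd_dz2, I, db$model))
  }

  list(A = A, logbc = logbc, species = nm, charge = zsp,
       free = free, fixed = fixed, lnc_fix = lnc_fix,
       totals = totals[free], solids = solids, pooled_from = pooled_from)
}

# ---------------------------------------------------------------------------
# Damped Newton iteration on log free component concentrations.
# ---------------------------------------------------------------------------
newton_solve <- function(A_free, lnb_eff, totals, Kw_c, start = NULL,
                         max_iter = 200L, tol = 1e-10) {
  free <- colnames(A_free)
  Tv <- totals[free]
  x <- if (!is.null(start)) start else default_start(free, Tv, Kw_c)
  Aabs <- abs(A_free)
  resid_of <- function(x) {
    S <- exp(lnb_eff + as.vector(A_free %*% x))
    R <- as.vector(crossprod(A_free, S)) - Tv
    den <- pmax(abs(Tv), as.vector(crossprod(Aabs, S)), 1e-30)
    list(S = S, R = R, den = den, norm = sqrt(sum((R / den)^2)))
  }
  ## componentwise log-correction pre-polish: cheap fixed-point steps that
  ## bring badly scaled components (strongly hydrolysed cations) into the
  ## Newton basin
  pos <- Tv > 0
  if (any(pos)) {
    for (k in 1:40) {
      S <- exp(lnb_eff + as.vector(A_free %*% x))
      tot <- as.vector(crossprod(A_free, S))
      corr <- log(pmax(tot[pos], 1e-300) / Tv[pos])
      if (all(abs(corr) < 1e-3)) break
      x[pos] <- x[pos] - pmin(pmax(corr, -2), 2)
    }
  }
  st <- resid_of(x)
  iter <- 0L
  while (iter < max_iter) {
    if (max(abs(st$R) / st$den) <= tol) break
    iter <- iter + 1L
    J <- crossprod(A_free, A_free * st$S)
    dx <- tryCatch(solve(J, -st$R),
                   error = function(e)
                     solve(J + diag(1e-10 * max(diag(J)), nrow(J)), -st$R))
    mx <- max(abs(dx))
    if (mx > 6) dx <- dx * (6 / mx)
    t <- 1
    repeat {
      cand <- resid_of(x + t * dx)
      if (cand$norm < st$norm || t < 1e-12) break
      t <- t / 2
    }
    x <- x + t * dx
    st <- cand
  }
  converged <- max(abs(st$R) / st$den) <= tol
  list(x = stats::setNames(x, free), S = st$S,
       residual_rel = stats::setNames(st$R / st$den, free),
       converged = converged, iterations = iter)
}

default_start <- function(free, Tv, Kw_c) {
  x <- numeric(length(Tv))
  for (i in seq_along(free)) {
    if (free[i] == "H") {
      x[i] <- if (Tv[i] > 1e-9) log(Tv[i] * 0.9)
      else if (Tv[i] < -1e-9) log(Kw_c / (-Tv[i]))
      else log(sqrt(Kw_c))
    } else x[i] <- log(max(Tv[i], 1e-18) * 1e-2)
  }
  x
}

#' Solve chemical equilibrium for a specified solution
#'
#' Damped Newton iteration on the logarithms of the free component
#' concentrations: mass-action expressions (conditional constants at the
#' working ionic strength) are combined with mass balances for every
#' non-fixed component.  Fixed-pH/pe components are held at fixed activity
#' and excluded from mass balance.  With `allow_solids`, supersaturated
#' solids precipitate until their saturation index is zero (the solid then
#' pins the free concentration of its metal at fixed pH).
#'
#' @param db an `equilibrium_database` (see [pdma_database()]).
#' @param spec a [solution_spec()].
#' @param start optional named vector of ln free concentrations (warm start).
#' @param max_iter Newton iteration cap.
#' @return a `speciation_result`: species table (name, concentration,
#'   stoichiometry), free concentrations, per-component fractions, relative
#'   mass-balance residuals, solid amounts and saturation indices,
#'   convergence diagnostics.
#' @export
solve_equilibrium <- function(db, spec, start = NULL, max_iter = 200L) {
  stopifnot(inherits(db, "equilibrium_database"),
            inherits(spec, "solution_spec"))
  if (all(abs(spec$totals) == 0)) stop("all totals are zero")
  I <- spec$I
  outer_max <- if (spec$ionic_strength_mode == "self_consistent") 30L else 1L
  res <- NULL
  for (outer in seq_len(outer_max)) {
    res <- solve_at_I(db, spec, I, start, max_iter)
    if (spec$ionic_strength_mode == "fixed") break
    I_new <- 0.5 * sum(res$species$concentration * res$species$charge^2)
    if (abs(I_new - I) < 1e-6 * max(I, 1e-6)) { res$I <- I_new; break }
    I <- 0.5 * (I + I_new)
    start <- res$x
  }
  res
}

solve_at_I <- function(db, spec, I, start, max_iter) {
  tb <- build_tableau(db, spec, I)
  Kw_c <- 10^intrinsic_to_conditional(-db$Kw, 2, I, db$model)
  fixed_idx <- match(tb$fixed, colnames(tb$A))
  free_idx <- match(tb$free, colnames(tb$A))
  lnb_eff <- log(10) * tb$logbc +
    if (length(fixed_idx))
      as.vector(tb$A[, fixed_idx, drop = FALSE] %*% tb$lnc_fix[tb$fixed])
  else 0

  active <- logical(length(tb$solids$name))
  pinned <- character(0)
  lnc_pin <- numeric(0)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    free_now <- setdiff(tb$free, pinned)
    A_free <- tb$A[, free_now, drop = FALSE]
    lnb_now <- lnb_eff
    if (length(pinned))
      lnb_now <- lnb_now +
        as.vector(tb$A[, pinned, drop = FALSE] %*% lnc_pin[pinned])
    st0 <- if (!is.null(start)) start[free_now] else NULL
    if (!is.null(st0) && anyNA(st0)) st0 <- NULL
    ns <- newton_solve(A_free, lnb_now, tb$totals, Kw_c, start = st0,
                       max_iter = max_iter)
    if (!ns$converged && !is.null(st0))   # warm start led astray: restart cold
      ns <- newton_solve(A_free, lnb_now, tb$totals, Kw_c, start = NULL,
                         max_iter = max_iter)
    if (!ns$converged)
      stop(structure(class = c("pdmaspec_convergence_error", "error",
                               "condition"),
                     list(message = paste0(
                       "equilibrium solver did not converge; worst relative ",
                       "residual ", format(max(abs(ns$residual_rel))),
                       " on ", names(which.max(abs(ns$residual_rel)))),
                       call = NULL, residuals = ns$residual_rel)))
    if (is.null(tb$solids) || guard > 12L) break

    ## solid bookkeeping at fixed pH: an active solid pins its metal
    lnc_all <- c(ns$x, lnc_pin[pinned], tb$lnc_fix[tb$fixed])
    SI <- vapply(seq_along(tb$solids$name), function(k) {
      stk <- tb$solids$stoich[[k]]
      tb$solids$logbc[k] + sum(stk * lnc_all[names(stk)]) / log(10)
    }, numeric(1))
    if (length(pinned)) {
      diss <- vapply(pinned, function(p)
        sum(tb$A[, p] * ns$S) , numeric(1))
      over <- tb$totals[pinned] - diss  # precipitated amount
      bad <- which(over < -1e-12 * pmax(tb$totals[pinned], 1e-30))
      if (length(bad)) {
        drop_comp <- pinned[bad[1]]
        k_drop <- which(vapply(tb$solids$stoich, function(s)
          drop_comp %in% names(s), logical(1)) & active)
        active[k_drop[1]] <- FALSE
        pinned <- pin_components(tb, active, tb$lnc_fix)$pinned
        lnc_pin <- pin_components(tb, active, tb$lnc_fix)$lnc
        start <- NULL
        next
      }
    }
    cand <- which(!active & SI > 1e-9)
    if (length(cand)) {
      if (is.null(spec$pH))
        stop("solid precipitation requires a fixed pH")
      active[cand[which.max(SI[cand])]] <- TRUE
      pp <- pin_components(tb, active, tb$lnc_fix)
      pinned <- pp$pinned
      lnc_pin <- pp$lnc
      start <- NULL
      next
    }
    break
  }

  ## assemble result ---------------------------------------------------------
  lnc_free <- c(ns$x, lnc_pin[pinned])
  S_all <- ns$S
  spname <- rownames(A_free)
  if (length(pinned)) {
    ## pinned components appear as species too (their identity rows were in
    ## the free set); recompute the full species vector over all components
    A_all <- tb$A[, c(names(lnc_free), tb$fixed), drop = FALSE]
    lnS <- log(10) * tb$logbc +
      as.vector(A_all %*% c(lnc_free, tb$lnc_fix[tb$fixed]))
    S_all <- exp(lnS)
    spname <- rownames(tb$A)
  }
  species <- data.frame(species = spname, concentration = unname(S_all),
                        charge = tb$charge[match(spname, tb$species)],
                        stringsAsFactors = FALSE)
  A_out <- tb$A[match(spname, rownames(tb$A)), , drop = FALSE]

  solids_df <- NULL
  if (!is.null(tb$solids)) {
    lnc_all <- c(lnc_free, tb$lnc_fix[tb$fixed])
    SI <- vapply(seq_along(tb$solids$name), function(k) {
      stk <- tb$solids$stoich[[k]]
      tb$solids$logbc[k] + sum(stk * lnc_all[names(stk)]) / log(10)
    }, numeric(1))
    amt <- numeric(length(SI))
    for (k in which(active)) {
      p <- intersect(names(tb$solids$stoich[[k]]), tb$free)
      amt[k] <- tb$totals[p] - sum(A_out[, p] * S_all)
      SI[k] <- 0
    }
    solids_df <- data.frame(solid = tb$solids$name, amount = amt, SI = SI,
                            active = active, stringsAsFactors = FALSE)
  }

  ## fractions & residuals over non-fixed components
  fr <- list(); resid <- numeric(0)
  for (p in tb$free) {
    Tp <- tb$totals[[p]]
    contrib <- A_out[, p] * S_all
    tot_solid <- if (!is.null(solids_df))
      sum(solids_df$amount * vapply(tb$solids$stoich, function(s)
        if (p %in% names(s)) s[[p]] else 0, numeric(1))) else 0
    resid[p] <- if (abs(Tp) > 0)
      (sum(contrib) + tot_solid - Tp) / abs(Tp) else sum(contrib) + tot_solid
    if (Tp > 0) {
      sel <- which(contrib != 0)
      f <- data.frame(component = p, species = spname[sel],
                      fraction = contrib[sel] / Tp,
                      stringsAsFactors = FALSE)
      if (tot_solid != 0 && !is.null(solids_df)) {
        act <- which(solids_df$active)
        f <- rbind(f, data.frame(component = p,
                                 species = solids_df$solid[act],
                                 fraction = solids_df$amount[act] / Tp))
      }
      fr[[p]] <- f
    }
  }
  fractions <- if (length(fr)) do.call(rbind, fr) else
    data.frame(component = character(0), species = character(0),
               fraction = numeric(0))
  rownames(fractions) <- NULL

  structure(list(species = species, A = A_out, free = exp(lnc_free),
                 x = lnc_free, totals = tb$totals, fixed = tb$lnc_fix,
                 fractions = fractions, residuals = resid,
                 solids = solids_df, pooled_from = tb$pooled_from,
                 I = I, pH = spec$pH, pe = spec$pe,
                 converged = ns$converged, iterations = ns$iterations),
            class = "speciation_result")
}

# ln concentrations pinned by the active solids (fixed pH required; each
# solid must involve exactly one non-fixed component).
pin_components <- function(tb, active, lnc_fix) {
  pinned <- character(0); lnc <- numeric(0)
  for (k in which(active)) {
    stk <- tb$solids$stoich[[k]]
    p <- setdiff(names(stk), tb$fixed)
    if (length(p) != 1L)
      stop("solid ", tb$solids$name[k],
           " involves more than one free component; unsupported")
    fixed_part <- sum(stk[tb$fixed[tb$fixed %in% names(stk)]] *
                        lnc_fix[tb$fixed[tb$fixed %in% names(stk)]])
    lnc[p] <- -(log(10) * tb$solids$logbc[k] + fixed_part) / stk[[p]]
    pinned <- c(pinned, p)
  }
  list(pinned = pinned, lnc = lnc)
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("<speciation_result: %d species, converged=%s, iter=%d>\n",
              nrow(x$species), x$converged, x$iterations))
  top <- x$species[order(-x$species$concentration), ][1:min(8, nrow(x$species)), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Fraction of a metal bound in metal-ligand complexes
#'
#' Sum of the concentrations of all species containing both the metal and
#' the ligand component (weighted by the metal stoichiometry), divided by
#' the metal's analytical total.  Under fixed pe use the oxidized master
#' component names (`"Cu"`, `"Fe3"`), which carry the pooled redox totals.
#'
#' @param result a converged `speciation_result`.
#' @param metal,ligand component names.
#' @return fraction in \[0, 1\].
#' @export
fraction_complexed <- function(result, metal, ligand) {
  stopifnot(inherits(result, "speciation_result"))
  if (!metal %in% names(result$totals) || result$totals[[metal]] <= 0)
    stop("metal total is zero or component absent: ", metal)
  if (!ligand %in% colnames(result$A)) return(0)
  sel <- result$A[, metal] > 0 & result$A[, ligand] > 0
  sum(result$A[sel, metal] * result$species$concentration[sel]) /
    result$totals[[metal]]
}

#' Log selectivity ratio of a metal over the reference metal for a ligand
#'
#' log10 of the summed concentration of metal-ligand complexes over the
#' summed concentration of reference-ligand complexes.  Positive values
#' mean the ligand prefers the metal over the reference.  A zero reference
#' complex pool returns -Inf with attribute `zero_reference = TRUE`.
#'
#' @param result a converged `speciation_result`.
#' @param metal competitor component name.
#' @param ligand ligand component name (default `"Pdma"`).
#' @param reference reference metal (default `"Zn"`).
#' @param complexes `"one_to_one"` (default) compares the concentrations of
#'   the \[M(ligand)\] complexes themselves, the quantity the selectivity
#'   ratio is defined on; `"all"` sums every metal-ligand species including
#'   protonated (MHL) and hydroxo (MLOH) forms.
#' @export
selectivity_log_S <- function(result, metal, ligand = "Pdma",
                              reference = "Zn",
                              complexes = c("one_to_one", "all")) {
  complexes <- match.arg(complexes)
  csum <- function(m) {
    if (!m %in% colnames(result$A)) return(0)
    sel <- result$A[, m] > 0 & result$A[, ligand] > 0
    if (complexes == "one_to_one" && "H" %in% colnames(result$A))
      sel <- sel & result$A[, "H"] == 0
    sum(result$species$concentration[sel])
  }
  num <- csum(metal); den <- csum(reference)
  if (den <= 0) {
    out <- -Inf
    attr(out, "zero_reference") <- TRUE
    return(out)
  }
  log10(num / den)
}

#' Sweep a condition axis and tabulate the speciation
#'
#' Solves the same solution over a sorted grid of pH, Eh (mV) or ionic
#' strength values, warm-starting each point from its neighbour, and
#' returns a long-format table plus the underlying results.
#'
#' @param db an `equilibrium_database`.
#' @param spec a [solution_spec()] template.
#' @param axis `"pH"`, `"Eh"` or `"I"`.
#' @param grid sorted numeric grid, non-empty.
#' @return data.frame (axis value, component, species, concentration,
#'   fraction); the list of `speciation_result`s is attached as
#'   `attr(, "results")`.
#' @export
sweep_axis <- function(db, spec, axis = c("pH", "Eh", "I"), grid) {
  axis <- match.arg(axis)
  if (!length(grid)) stop("empty grid")
  if (is.unsorted(grid)) stop("grid must be sorted")
  start <- NULL
  out <- vector("list", length(grid))
  results <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    sp_i <- spec
    if (axis == "pH") sp_i$pH <- grid[i]
    if (axis == "Eh") sp_i$pe <- eh_to_pe(grid[i], spec$T_K)
    if (axis == "I") sp_i$I <- grid[i]
    res <- tryCatch(solve_equilibrium(db, sp_i, start = start),
                    error = function(e)
                      stop("sweep failed at ", axis, " = ", grid[i], ": ",
                           conditionMessage(e)))
    start <- res$x
    results[[i]] <- res
    tab <- res$fractions
    conc <- res$species$concentration[match(tab$species,
                                            res$species$species)]
    out[[i]] <- data.frame(axis = axis, value = grid[i],
                           component = tab$component, species = tab$species,
                           concentration = conc, fraction = tab$fraction,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "results") <- results
  tab
}
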