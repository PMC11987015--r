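#' Brute-force equilibrium oracle (nested bisection)
#'
#' Independent cross-check for the Newton solver on systems with at most
#' two non-fixed components: the mass-balance residual of each free
#' component is monotone in its own free concentration (all formation
#' coefficients of non-proton components are non-negative, and the proton
#' residual is monotone in \[H+\]), so nested 1-D bisection on log10 free
#' concentrations brackets the root without derivatives.  The numerical
#' path shares only the tableau data with [solve_equilibrium()], not the
#' iteration.
#'
#' @inheritParams solve_equilibrium
#' @return a `speciation_result` (no solid handling).
#' @export
brute_force_oracle <- function(db, spec) {
  if (isTRUE(spec$allow_solids)) stop("oracle does not handle solids")
  tb <- build_tableau(db, spec, spec$I)
  if (length(tb$free) > 2L)
    stop("brute-force oracle supports at most 2 non-fixed components")
  nm <- rownames(tb$A)
  nsp <- length(nm)
  lnb <- log(10) * tb$logbc
  if (length(tb$fixed))
    lnb <- lnb + as.vector(tb$A[, tb$fixed, drop = FALSE] %*%
                             tb$lnc_fix[tb$fixed])
  Af <- tb$A[, tb$free, drop = FALSE]

  conc_at <- function(lc) {       # lc: log10 free concs, plain loops
    s <- numeric(nsp)
    for (j in seq_len(nsp)) {
      acc <- lnb[j]
      for (k in seq_along(tb$free)) acc <- acc + Af[j, k] * log(10) * lc[k]
      s[j] <- exp(acc)
    }
    s
  }
  resid_k <- function(lc, k) {
    s <- conc_at(lc)
    tot <- 0
    for (j in seq_len(nsp)) tot <- tot + Af[j, k] * s[j]
    tot - tb$totals[[k]]
  }
  bisect <- function(f, lo = -40, hi = 3, n = 120L) {
    flo <- f(lo)
    if (flo > 0) return(lo)          # residual positive even at zero: take floor
    for (i in seq_len(n)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }

  if (length(tb$free) == 1L) {
    lc <- bisect(function(v) resid_k(v, 1L))
    lcs <- stats::setNames(lc, tb$free)
  } else {
    inner <- function(l1) bisect(function(v) resid_k(c(l1, v), 2L))
    l1 <- bisect(function(v) resid_k(c(v, inner(v)), 1L))
    lcs <- stats::setNames(c(l1, inner(l1)), tb$free)
  }
  S <- conc_at(lcs)
  resid <- vapply(seq_along(tb$free), function(k)
    resid_k(lcs, k) / max(abs(tb$totals[[k]]), 1e-30), numeric(1))
  species <- data.frame(species = nm, concentration = S,
                        charge = tb$charge, stringsAsFactors = FALSE)
  fr <- list()
  for (p in tb$free) {
    Tp <- tb$totals[[p]]
    if (Tp > 0) {
      contrib <- tb$A[, p] * S
      sel <- which(contrib != 0)
      fr[[p]] <- data.frame(component = p, species = nm[sel],
                            fraction = contrib[sel] / Tp,
                            stringsAsFactors = FALSE)
    }
  }
  structure(list(species = species, A = tb$A,
                 free = stats::setNames(10^lcs, tb$free), x = log(10^lcs),
                 totals = tb$totals, fixed = tb$lnc_fix,
                 fractions = if (length(fr)) do.call(rbind, fr) else NULL,
                 residuals = stats::setNames(resid, tb$free), solids = NULL,
                 I = spec$I, pH = spec$pH, pe = spec$pe,
                 converged = all(abs(resid) < 1e-6), iterations = NA_integer_),
            class = "speciation_result")
}
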