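# Shared fixtures: the shipped database (built once per test run) and a
# conditional-constant accessor used when tests need the published scale.
DB <- pdma_database()

cond_at <- function(db, species, I) {
  i <- match(species, db$species$species)
  intrinsic_to_conditional(db$species$log_beta0[i],
                           db$species$delta_z2[i], I, db$model)
}

# background electrolyte totals for a NaCl medium at ionic strength I
nacl <- function(I) c(Na = I, Cl = I)

# small battery of random single-metal / single-ligand systems (fixed seed)
random_ml_specs <- function(n, seed = 421) {
  set.seed(seed)
  mets <- c("Zn", "Cu", "Ni", "Co", "Mn", "Mg")
  lapply(seq_len(n), function(k) {
    m <- sample(mets, 1)
    tot <- stats::setNames(c(10^stats::runif(1, -7, -5),
                             10^stats::runif(1, -6, -4)), c(m, "Pdma"))
    solution_spec(tot, pH = stats::runif(1, 3, 10),
                  I = 10^stats::runif(1, -2, -0.5))
  })
}
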