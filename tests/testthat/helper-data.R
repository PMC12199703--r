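# Shared fixtures, all generated in code.

# Single-agent immobility records drawn from a log-logistic truth on the
# nanoparticle concentration grid.
make_records <- function(ec50, slope = 3, n_per_well = 5L, wells = 4L,
                         concs = c(5, 10, 20, 30, 50), timepoint = 48,
                         condition = "x") {
  g <- expand.grid(w = seq_len(wells), conc = concs)
  p <- ll4_effect(g$conc, slope, ec50)
  data.frame(condition = condition, timepoint_h = timepoint,
             conc_ug_per_l = g$conc, n_exposed = n_per_well,
             n_immobile = stats::rbinom(nrow(g), n_per_well, p))
}

# Noise-free records: counts are the rounded expected values at large n, so
# the likelihood optimum sits essentially at the generating parameters.
make_noisefree_records <- function(ec50, slope, n_per_well = 10000L,
                                   concs = c(2, 5, 10, 20, 40)) {
  p <- ll4_effect(concs, slope, ec50)
  data.frame(condition = "x", timepoint_h = 48, conc_ug_per_l = concs,
             n_exposed = n_per_well, n_immobile = as.integer(round(n_per_well * p)))
}

# Exhaustive grid minimum of a two-parameter negative log-likelihood
# nll_fn(h, e_vector) -> vector over e. Optionally refines once around the
# coarse minimum so "within one grid cell" is checked on a fine local grid.
grid_search_2d <- function(nll_fn, h_range, e_range, n_grid = 400L,
                           refine = TRUE) {
  scan <- function(hs, es) {
    best <- list(val = Inf)
    for (h in hs) {
      nll <- nll_fn(h, es)
      j <- which.min(nll)
      if (nll[j] < best$val) best <- list(val = nll[j], h = h, e = es[j])
    }
    c(best, list(dh = diff(hs[1:2]), de = diff(es[1:2])))
  }
  hs <- seq(h_range[1], h_range[2], length.out = n_grid)
  es <- seq(e_range[1], e_range[2], length.out = n_grid)
  best <- scan(hs, es)
  if (refine) {
    hs2 <- seq(max(h_range[1], best$h - 3 * best$dh),
               min(h_range[2], best$h + 3 * best$dh), length.out = 121L)
    es2 <- seq(max(e_range[1], best$e - 3 * best$de),
               min(e_range[2], best$e + 3 * best$de), length.out = 121L)
    best <- scan(hs2, es2)
  }
  best
}

# Grid oracle for the single-agent LL4 binomial likelihood.
grid_search_ll4 <- function(wells, h_range = c(0.5, 8), e_range = c(1, 50),
                            n_grid = 400L, refine = TRUE) {
  wells <- wells[wells$conc_ug_per_l > 0, ]
  logc <- log(wells$conc_ug_per_l)
  n <- wells$n_exposed; y <- wells$n_immobile
  nll_fn <- function(h, es) {
    p <- stats::plogis(h * outer(-log(es), logc, "+"))
    -as.numeric(log(p) %*% y + log1p(-p) %*% (n - y))
  }
  grid_search_2d(nll_fn, h_range, e_range, n_grid, refine)
}

# Grid oracle for the additivity particle-curve likelihood (ion fixed).
grid_search_particle <- function(np, ion, tab, h_range = c(0.5, 10),
                                 e_range = c(5, 100), n_grid = 300L,
                                 refine = TRUE) {
  np <- np[np$conc_ug_per_l > 0, ]
  lv <- sort(unique(np$conc_ug_per_l))
  dl <- sapply(lv, function(l) dose_at(tab, l))
  idx <- match(np$conc_ug_per_l, lv)
  pd <- dl["particle_dose", idx]
  e_i <- ll4_effect(dl["ion_dose", idx], ion$slope, ion$ec50)
  n <- np$n_exposed; y <- np$n_immobile
  nll_fn <- function(h, es) {
    ep <- stats::plogis(h * outer(-log(es), log(pd), "+"))
    p <- 1 - sweep(1 - ep, 2, 1 - e_i, "*")
    -as.numeric(log(p) %*% y + log1p(-p) %*% (n - y))
  }
  grid_search_2d(nll_fn, h_range, e_range, n_grid, refine)
}
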