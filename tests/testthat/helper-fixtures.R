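# Frozen expected values, each computed by an independent line-by-line
# arithmetic evaluation of the model equations (separate script, written
# before the package code). The tolerance used against them is 1e-8
# relative unless a test states otherwise.
oracle <- list(
  patm_4361 = 58.79574812023576,           # barometric formula at 4361 m
  tdj_fix = 15.72014116585449,             # Tmax 18, Tmin 8, lat 29.6, decl 21.2
  kmm_25_sea = 70.8457886599345,           # Kc25 * (1 + Po/Ko25), sea level
  gammastar_25_sea = 4.332,
  chi_fix = 0.7536165248978381,            # 25 C, D0 1 kPa, sea level, ca 40 Pa
  chi_iso_fix = 0.6761773686158401,        # Delta 20 permil, ca 40.53 Pa, 25 C
  vcmax_fix = 92.06821151968573,           # 25 C, chi .8, ca 40, R0 800, sea
  fv_10 = 0.2609756329634171,
  lma_theory_fix = 73.95771485968682,      # I_abs 20, LL 180, 25 C, ca 40, chi*
  lma_decid_fix = 79.06225008897799,       # R_LAI 20, f .6, Tg 12, alpha_p .8
  narea_two_step_fix = 1.5180239230582624, # Ma 80, Vcmax25 60, alloc 7.2
  t_elasticity = 3.0631577677819877        # -100 d ln(Ma)/dT at standard cond.
)

# Independent design for coefficient-recovery experiments: predictors drawn
# independently so the regression is well conditioned (unlike a real
# transect, where drivers covary with elevation).
make_lma_design <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      r_lai = runif(n, 5, 40),
      f = runif(n, 0.3, 1),
      tg = runif(n, 2, 25),
      alpha_p = runif(n, 0.3, 1.2)
    )
  })
}

lma_truth <- function(design, coeffs = leaf_constants()$lma_coeffs) {
  lma_deciduous(design$r_lai, design$f, design$tg, design$alpha_p, coeffs)
}

# numeric central-difference derivative
num_deriv <- function(fn, x, h = 1e-6 * max(abs(x), 1)) {
  (fn(x + h) - fn(x - h)) / (2 * h)
}
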