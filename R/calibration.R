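#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

## drop rows with missing values in the named columns, with a log message
drop_incomplete <- function(data, cols, context) {
  keep <- stats::complete.cases(data[cols])
  if (any(!keep)) {
    inform(paste0(context, ": dropped ", sum(!keep),
                  " record(s) with missing values."))
  }
  data[keep, , drop = FALSE]
}

check_varying <- function(data, cols) {
  for (col in cols) {
    v <- data[[col]]
    if (length(unique(v[is.finite(v)])) < 2) {
      abort(paste0("Collinear or degenerate design: column `", col,
                   "` has no variation."))
    }
  }
}

#' Re-estimate the deciduous-LMA regression coefficients
#'
#' Ordinary least squares of `ln(Ma)` on `ln(R_LAI)`, `ln(f)`, `Tg` and
#' `ln(alpha_p)` with an intercept -- the regression that calibrates the
#' linearised deciduous-LMA model on a trait table joined to its site
#' bioclimate.
#'
#' @param data A data frame with columns `ma`, `r_lai`, `f`, `tg`,
#'   `alpha_p` (species-level traits joined to site environment).
#' @return An object of class `"lma_fit"` wrapping the `lm` fit, with
#'   [tidy()] and [glance()] methods. `coef()` returns the coefficients
#'   named as in `leaf_constants()$lma_coeffs`.
#' @examples
#' sc <- transect_scenario(seed = 1)
#' traits <- generate_traits(generate_sites(sc), sc)
#' fit <- fit_lma_coefficients(traits)
#' tidy(fit)
#' @export
fit_lma_coefficients <- function(data) {
  data <- as_tibble(data)
  cols <- c("ma", "r_lai", "f", "tg", "alpha_p")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- drop_incomplete(data, cols, "fit_lma_coefficients")
  if (nrow(data) < 20) {
    abort("At least 20 complete records are required to fit the LMA model.")
  }
  check_varying(data, c("r_lai", "f", "tg", "alpha_p"))
  fit <- lm(log(ma) ~ log(r_lai) + log(f) + tg + log(alpha_p), data = data)
  structure(list(fit = fit, n = nrow(data)), class = "lma_fit")
}

#' @export
coef.lma_fit <- function(object, ...) {
  co <- coef(object$fit)
  setNames(co[c("log(r_lai)", "log(f)", "tg", "log(alpha_p)", "(Intercept)")],
           c("ln_r_lai", "ln_f", "tg", "ln_alpha_p", "intercept"))
}

#' @export
tidy.lma_fit <- function(x, ...) {
  out <- broom::tidy(x$fit, ...)
  out$term <- dplyr::recode(out$term,
    "log(r_lai)" = "ln_r_lai", "log(f)" = "ln_f",
    "log(alpha_p)" = "ln_alpha_p", "(Intercept)" = "intercept")
  out
}

#' @export
glance.lma_fit <- function(x, ...) broom::glance(x$fit, ...)

#' @export
print.lma_fit <- function(x, ...) {
  cat("<lma_fit> ln(Ma) ~ ln(R_LAI) + ln(f) + Tg + ln(alpha_p), n =",
      x$n, "\n")
  print(coef(x))
  invisible(x)
}

#' Re-estimate the direct Narea regression coefficients
#'
#' Zero-intercept least squares of Narea on Ma and Vcmax25, optionally with
#' an additive nitrogen-fixer term, mirroring the direct calibration of the
#' simple Narea model.
#'
#' @param data A data frame with columns `narea`, `ma`, `vcmax25` and
#'   optionally `n_fixer` (logical).
#' @param include_n_fixer Add `n_fixer` as an additive factor?
#' @return An object of class `"narea_fit"` wrapping the `lm` fit.
#'   `coef()` returns `ma`, `vcmax25` and (when fitted) `n_fixer` terms.
#' @examples
#' d <- data.frame(ma = c(50, 80, 120), vcmax25 = c(30, 50, 70))
#' d$narea <- narea_simple(d$ma, d$vcmax25)
#' coef(fit_narea_coefficients(d))
#' @export
fit_narea_coefficients <- function(data, include_n_fixer = FALSE) {
  data <- as_tibble(data)
  cols <- c("narea", "ma", "vcmax25", if (include_n_fixer) "n_fixer")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- drop_incomplete(data, cols, "fit_narea_coefficients")
  if (nrow(data) < 3) {
    abort("At least 3 complete records are required to fit the Narea model.")
  }
  check_varying(data, c("ma", "vcmax25"))
  fml <- if (include_n_fixer) {
    ## numeric 0/1 so non-fixers keep a zero intercept
    data$n_fixer <- as.numeric(data$n_fixer)
    narea ~ 0 + ma + vcmax25 + n_fixer
  } else {
    narea ~ 0 + ma + vcmax25
  }
  fit <- lm(fml, data = data)
  structure(list(fit = fit, n = nrow(data),
                 include_n_fixer = include_n_fixer),
            class = "narea_fit")
}

#' @export
coef.narea_fit <- function(object, ...) {
  co <- coef(object$fit)
  names(co) <- sub("^n_fixerTRUE$", "n_fixer", names(co))
  co
}

#' @export
tidy.narea_fit <- function(x, ...) {
  out <- broom::tidy(x$fit, ...)
  out$term <- sub("^n_fixerTRUE$", "n_fixer", out$term)
  out
}

#' @export
glance.narea_fit <- function(x, ...) broom::glance(x$fit, ...)

#' @export
print.narea_fit <- function(x, ...) {
  cat("<narea_fit> Narea ~ 0 + Ma + Vcmax25",
      if (x$include_n_fixer) "+ n_fixer", ", n =", x$n, "\n")
  print(coef(x))
  invisible(x)
}

#' Re-estimate the Rubisco nitrogen-allocation multiplier
#'
#' Computes structural nitrogen from observed Ma and Rubisco nitrogen from
#' observed Vcmax25 using the fixed allometries, then fits the
#' zero-intercept slope of metabolic nitrogen (`Narea - N_structure`) on
#' `N_rubisco`. This is the allocation multiplier of the two-step Narea
#' model.
#'
#' @param data A data frame with columns `narea`, `ma`, `vcmax25`.
#' @param constants A [leaf_constants()] list (supplies the structural and
#'   Rubisco allometries).
#' @return An object of class `"alloc_fit"`; `coef()` returns the single
#'   `alloc` slope.
#' @examples
#' d <- data.frame(ma = c(50, 80, 120), vcmax25 = c(30, 50, 70))
#' d$narea <- narea_two_step(d$ma, d$vcmax25, alloc = 7.2)
#' coef(fit_rubisco_allocation(d))
#' @export
fit_rubisco_allocation <- function(data, constants = leaf_constants()) {
  cst <- as_constants(constants)
  data <- as_tibble(data)
  cols <- c("narea", "ma", "vcmax25")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- drop_incomplete(data, cols, "fit_rubisco_allocation")
  if (nrow(data) < 1) abort("No complete records.")
  n_metab <- data$narea - cst$nstruct_coef * data$ma^cst$nstruct_exp
  n_rub <- cst$nrub_slope * data$vcmax25
  if (mean(n_metab < 0) > 0.5) {
    warn(paste0(
      "Data-quality warning: metabolic nitrogen (Narea - N_structure) is ",
      "negative in more than half of the records."
    ))
  }
  fit <- lm(n_metab ~ 0 + n_rub)
  structure(list(fit = fit, n = nrow(data)), class = "alloc_fit")
}

#' @export
coef.alloc_fit <- function(object, ...) {
  setNames(coef(object$fit), "alloc")
}

#' @export
tidy.alloc_fit <- function(x, ...) {
  out <- broom::tidy(x$fit, ...)
  out$term <- "alloc"
  out
}

#' @export
glance.alloc_fit <- function(x, ...) broom::glance(x$fit, ...)

#' @export
print.alloc_fit <- function(x, ...) {
  cat("<alloc_fit> (Narea - N_structure) ~ 0 + N_rubisco, n =", x$n, "\n")
  print(coef(x))
  invisible(x)
}
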