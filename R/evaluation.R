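#' Agreement statistics between observed and predicted site means
#'
#' Pearson correlation, root mean square error, R-squared and relative
#' RMSE between paired observed and predicted values. R-squared is
#' reported both as the squared Pearson correlation (the default
#' interpretation) and as the variance explained about the 1:1 line
#' (`1 - SS_resid / SS_total`), which penalises bias.
#'
#' @param data A data frame of paired site means.
#' @param observed,predicted Columns of `data` (tidy-eval) holding the
#'   observed and predicted values; no missing pairs allowed.
#' @return A one-row tibble: `n`, `r`, `rmse`, `r_squared`
#'   (squared Pearson), `r_squared_identity` (about the 1:1 line),
#'   `relative_rmse` (RMSE / mean observed). When the observed vector has
#'   zero variance `r` and both R-squareds are `NA` with a warning.
#' @examples
#' d <- data.frame(obs = c(1, 2, 3), pred = c(1.1, 2.2, 2.9))
#' agreement_stats(d, obs, pred)
#' @export
agreement_stats <- function(data, observed, predicted) {
  obs <- dplyr::pull(data, {{ observed }})
  pred <- dplyr::pull(data, {{ predicted }})
  if (length(obs) < 3) abort("At least 3 paired sites are required.")
  if (anyNA(obs) || anyNA(pred)) abort("Missing pairs are not allowed.")
  rmse <- sqrt(mean((pred - obs)^2))
  if (sd(obs) == 0) {
    warn("Observed vector has zero variance: correlation undefined.")
    r <- NA_real_
    r2 <- NA_real_
    r2_id <- NA_real_
  } else {
    r <- stats::cor(obs, pred)
    r2 <- r^2
    r2_id <- 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)
  }
  tibble(
    n = length(obs), r = r, rmse = rmse, r_squared = r2,
    r_squared_identity = r2_id,
    relative_rmse = rmse / mean(obs)
  )
}

#' Within-site and across-site coefficients of variation
#'
#' The coefficient of variation (sample sd / mean) of a trait computed on
#' species values within each site, and across sites on the site means.
#' Comparing the two shows whether a trait varies more between communities
#' than within them. Sites with fewer than 2 species are skipped with a
#' message.
#'
#' @param data A species-level trait table with a `site_id` column.
#' @param trait Column of `data` (tidy-eval) holding the trait values.
#' @return A list with `within` (tibble: `site_id`, `n`, `mean`, `cv`),
#'   `across` (across-site CV of the site means) and
#'   `n_sites_within_exceeds_across` (count of sites whose within-site CV
#'   exceeds the across-site CV).
#' @examples
#' sc <- transect_scenario(seed = 1)
#' traits <- generate_traits(generate_sites(sc), sc)
#' cv_within_across(traits, ma)$across
#' @export
cv_within_across <- function(data, trait) {
  data <- dplyr::filter(as_tibble(data), !is.na({{ trait }}))
  per_site <- dplyr::summarise(
    dplyr::group_by(data, .data$site_id),
    n = dplyr::n(),
    mean = mean({{ trait }}),
    cv = sd({{ trait }}) / mean({{ trait }}),
    .groups = "drop"
  )
  skipped <- per_site$site_id[per_site$n < 2]
  if (length(skipped)) {
    inform(paste0("cv_within_across: skipped single-species site(s): ",
                  paste(skipped, collapse = ", ")))
  }
  within <- dplyr::filter(per_site, .data$n >= 2)
  across <- sd(per_site$mean) / mean(per_site$mean)
  list(
    within = within,
    across = across,
    n_sites_within_exceeds_across = sum(within$cv > across)
  )
}

#' Statistical benchmark: multiple linear regression of traits on climate
#'
#' Fits, per trait, an ordinary multiple linear regression of site-mean
#' trait values on the same climate drivers the corresponding optimality
#' model uses, and reports its R-squared. This is the statistical benchmark
#' the optimality predictions are compared against: it is calibrated on the
#' data at hand, whereas the optimality models are not.
#'
#' @param data A site-level table holding site-mean trait columns together
#'   with the climate columns (`patm`, `tdj`, `tg`, `d0`, `r0`, `r_lai`,
#'   `f`, `alpha_p` as needed per trait).
#' @param traits Traits to benchmark; any of `"chi"`, `"vcmax25"`, `"ma"`,
#'   `"narea"`.
#' @return A tibble with one row per trait: `trait`, `r_squared`,
#'   `adj_r_squared`, `n`, `n_predictors`, and a list-column `fit` with
#'   the underlying `lm` objects.
#' @examples
#' sc <- transect_scenario(seed = 1)
#' sites <- generate_sites(sc)
#' traits <- generate_traits(sites, sc)
#' sm <- site_mean_traits(traits)
#' benchmark_regression(dplyr::left_join(sm, sites, by = "site_id"))
#' @export
benchmark_regression <- function(data,
                                 traits = c("chi", "vcmax25", "ma",
                                            "narea")) {
  data <- as_tibble(data)
  traits <- match.arg(traits, several.ok = TRUE)
  benchmark_drivers <- list(
    chi = c("patm", "tdj", "d0"),
    vcmax25 = c("patm", "tdj", "r0"),
    ma = c("tg", "r_lai", "f", "alpha_p"),
    narea = c("tg", "r0", "d0", "alpha_p")
  )
  purrr::map_dfr(traits, function(trait) {
    drivers <- benchmark_drivers[[trait]]
    cols <- c(trait, drivers)
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols)) {
      abort(paste0("`data` is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    d <- data[stats::complete.cases(data[cols]), cols]
    if (nrow(d) < length(drivers) + 2) {
      abort(paste0(
        "Overdetermined design for `", trait, "`: need at least ",
        length(drivers) + 2, " sites for ", length(drivers),
        " predictors."
      ))
    }
    fit <- lm(stats::reformulate(drivers, response = trait), data = d)
    sm <- summary(fit)
    tibble(trait = trait, r_squared = sm$r.squared,
           adj_r_squared = sm$adj.r.squared, n = nrow(d),
           n_predictors = length(drivers), fit = list(fit))
  })
}

#' Site-mean trait table from species-level records
#'
#' Averages species-level trait values per site, by default over the
#' deciduous, non-flagged component -- the fraction of the community the
#' trait models address. chi and Vcmax25 predictions also apply to
#' evergreen species, so those can be retained with
#' `deciduous_only = FALSE`.
#'
#' @param traits A species-level trait table (as from
#'   [generate_traits()] or [read_traits()]).
#' @param deciduous_only Keep only `leaf_habit == "deciduous"` records?
#' @return A tibble with one row per site and columns `site_id`,
#'   `n_species` and the site means of `ma`, `narea`, `vcmax25`, `chi`
#'   (whichever are present).
#' @export
site_mean_traits <- function(traits, deciduous_only = TRUE) {
  traits <- as_tibble(traits)
  if (deciduous_only && "leaf_habit" %in% names(traits)) {
    traits <- dplyr::filter(traits, .data$leaf_habit == "deciduous")
  }
  value_cols <- intersect(c("ma", "narea", "vcmax25", "chi"), names(traits))
  dplyr::summarise(
    dplyr::group_by(traits, .data$site_id),
    n_species = dplyr::n(),
    dplyr::across(dplyr::all_of(value_cols), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Observed-vs-predicted scatter with the 1:1 line
#'
#' @param data A data frame of paired site means.
#' @param observed,predicted Columns of `data` (tidy-eval).
#' @return A ggplot object.
#' @export
plot_agreement <- function(data, observed, predicted) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ observed }},
                                     y = {{ predicted }})) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed site mean", y = "predicted site mean") +
    ggplot2::theme_minimal()
}
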