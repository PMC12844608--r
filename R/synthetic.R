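#' Configuration of a synthetic replacement-series trial
#'
#' Describes a multi-site, multi-season randomized complete block trial of
#' a two-component winter catch crop mixture against its two pure stands,
#' at the yield scale typical of an Italian ryegrass / clover system: pure
#' grass around 5 t/ha, pure clover around 4 t/ha, sown 50:50 in the
#' mixture. The mixture component means are set through the relative
#' performances `kappa_ir` and `kappa_c` (`idm_i = sdm_i * z_i * kappa_i`
#' before noise), so `kappa_i` is exactly the expected partial RYT of
#' component i; the defaults 1.50 and 0.73 encode a strongly complementary
#' mixture. Yield noise is multiplicative log-normal at two levels:
#' between experimental units (site-years) and between blocks within a
#' unit.
#'
#' @param n_sites,n_seasons,n_blocks Trial dimensions (defaults 3, 2, 4).
#' @param mu_sdm_ir,mu_sdm_c Mean pure-stand dry-matter yields, t/ha
#'   (defaults 5.06 and 4.03).
#' @param kappa_ir,kappa_c True per-unit relative mixture performances
#'   (expected partial RYTs); scalars, or vectors of length
#'   `n_sites * n_seasons` to plant a per-unit structure.
#' @param z_ir,z_c Sown proportions in the mixture (default 0.5/0.5; must
#'   sum to 1).
#' @param cv_between_unit,cv_within_block Coefficients of variation of the
#'   two noise levels (defaults 0.10).
#' @param n_conc_ir,n_conc_c Mean nitrogen concentrations, g/kg dry matter
#'   (defaults 24 and 32: grasses dilute nitrogen more than legumes).
#' @param cv_n_conc Coefficient of variation of the nitrogen
#'   concentrations (default 0.05).
#' @param sowing_template,harvest_template Month-day templates
#'   (`"MM-DD"`) for the sowing (first calendar year of a season) and
#'   harvest (second year) dates.
#' @param first_year First calendar year of the first season.
#' @param seed RNG seed; identical seed and config give identical output.
#' @return A validated list of class `trial_config`.
#' @export
trial_config <- function(n_sites = 3, n_seasons = 2, n_blocks = 4,
                         mu_sdm_ir = 5.06, mu_sdm_c = 4.03,
                         kappa_ir = 1.50, kappa_c = 0.73,
                         z_ir = 0.5, z_c = 0.5,
                         cv_between_unit = 0.10, cv_within_block = 0.10,
                         n_conc_ir = 24, n_conc_c = 32, cv_n_conc = 0.05,
                         sowing_template = "08-27", harvest_template = "05-06",
                         first_year = 2019, seed = 1L) {
  n_units <- n_sites * n_seasons
  kappa_ir <- rep_len(kappa_ir, n_units)
  kappa_c <- rep_len(kappa_c, n_units)
  cfg <- structure(
    list(
      n_sites = n_sites, n_seasons = n_seasons, n_blocks = n_blocks,
      mu_sdm_ir = mu_sdm_ir, mu_sdm_c = mu_sdm_c,
      kappa_ir = kappa_ir, kappa_c = kappa_c,
      z_ir = z_ir, z_c = z_c,
      cv_between_unit = cv_between_unit, cv_within_block = cv_within_block,
      n_conc_ir = n_conc_ir, n_conc_c = n_conc_c, cv_n_conc = cv_n_conc,
      sowing_template = sowing_template, harvest_template = harvest_template,
      first_year = first_year, seed = seed
    ),
    class = "trial_config"
  )
  stopifnot(
    n_sites >= 1, n_seasons >= 1, n_blocks >= 1,
    mu_sdm_ir > 0, mu_sdm_c > 0, all(kappa_ir > 0), all(kappa_c > 0),
    cv_between_unit >= 0, cv_within_block >= 0, cv_n_conc >= 0,
    n_conc_ir > 0, n_conc_c > 0
  )
  if (abs(z_ir + z_c - 1) > 1e-9) {
    abort("z_ir + z_c must equal 1", class = "intercrop_validation_error")
  }
  cfg
}

#' Generate a synthetic trial with known ground truth
#'
#' Draws a complete set of plot records under a `trial_config`: for each
#' site-season unit, unit-level pure-stand means are drawn log-normally
#' around the configured means (CV `cv_between_unit`), the mixture
#' component means are fixed by the relative performances `kappa`, and
#' each block observation multiplies the unit mean by log-normal noise
#' with mean 1 (CV `cv_within_block`). Nitrogen concentrations are drawn
#' independently of yield around the component means. The ground truth
#' records the noise-free per-unit stand pairs on both bases together
#' with their exact index sets, so every downstream stage can be tested
#' against known values.
#'
#' @param config A [trial_config()].
#' @return A list with `records` (a `plot_records` tibble,
#'   `n_sites * n_seasons * n_blocks * 4` rows) and `truth` (list with
#'   `stand_pairs_dmy`, `stand_pairs_n`, `index_sets_dmy`,
#'   `index_sets_n`, and the `config`).
#' @export
generate_trial <- function(config = trial_config()) {
  cfg <- config
  set.seed(cfg$seed)
  sites <- sprintf("S%d", seq_len(cfg$n_sites))
  seasons <- vapply(seq_len(cfg$n_seasons), function(k) {
    paste0(cfg$first_year + k - 1, "-", cfg$first_year + k)
  }, "")
  blocks <- sprintf("B%d", seq_len(cfg$n_blocks))

  unit_grid <- expand.grid(site_id = sites, season_id = seasons,
                           stringsAsFactors = FALSE)
  unit_grid <- unit_grid[order(match(unit_grid$season_id, seasons),
                               match(unit_grid$site_id, sites)), ]
  n_units <- nrow(unit_grid)

  mu_ir <- rlnorm_cv(n_units, cfg$mu_sdm_ir, cfg$cv_between_unit)
  mu_c <- rlnorm_cv(n_units, cfg$mu_sdm_c, cfg$cv_between_unit)
  idm_ir_u <- mu_ir * cfg$z_ir * cfg$kappa_ir
  idm_c_u <- mu_c * cfg$z_c * cfg$kappa_c

  rec_rows <- vector("list", n_units)
  truth_rows <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    site <- unit_grid$site_id[u]
    season <- unit_grid$season_id[u]
    yr1 <- as.integer(substr(season, 1, 4))
    sow <- as.Date(paste0(yr1, "-", cfg$sowing_template))
    harv <- as.Date(paste0(yr1 + 1, "-", cfg$harvest_template))
    slots <- tibble(
      treatment = c("PURE_IR", "PURE_C", "MIX", "MIX"),
      component = c("IR", "C", "IR", "C"),
      mean_value = c(mu_ir[u], mu_c[u], idm_ir_u[u], idm_c_u[u]),
      sown = c(1, 1, cfg$z_ir, cfg$z_c),
      conc_mean = c(cfg$n_conc_ir, cfg$n_conc_c, cfg$n_conc_ir, cfg$n_conc_c)
    )
    block_rows <- lapply(blocks, function(b) {
      noise <- rlnorm_cv(nrow(slots), 1, cfg$cv_within_block)
      conc <- rlnorm_cv(nrow(slots), 1, cfg$cv_n_conc) * slots$conc_mean
      dmy <- slots$mean_value * noise
      tibble(
        site_id = site, season_id = season, block_id = b,
        treatment = slots$treatment, component = slots$component,
        dmy = dmy, n_conc = conc, n_uptake = dmy * conc,
        sown_proportion = slots$sown,
        sowing_date = sow, harvest_date = harv
      )
    })
    rec_rows[[u]] <- bind_rows(block_rows)
    days <- as.numeric(harv - sow)
    truth_rows[[u]] <- tibble(
      unit_id = paste(site, season, sep = ":"),
      sdm_ir = mu_ir[u], sdm_c = mu_c[u],
      idm_ir = idm_ir_u[u], idm_c = idm_c_u[u],
      z_ir = cfg$z_ir, z_c = cfg$z_c,
      d_ir = days, d_c = days, t_total = days
    )
  }
  records <- validate_plot_records(bind_rows(rec_rows))

  truth_pairs <- bind_rows(truth_rows)
  pairs_dmy <- dplyr::bind_cols(truth_pairs[, "unit_id"],
                                tibble(basis = "dmy"),
                                truth_pairs[, -1])
  class(pairs_dmy) <- c("stand_pairs", class(pairs_dmy))
  pairs_n <- pairs_dmy
  pairs_n$basis <- "n"
  pairs_n$sdm_ir <- truth_pairs$sdm_ir * cfg$n_conc_ir
  pairs_n$sdm_c <- truth_pairs$sdm_c * cfg$n_conc_c
  pairs_n$idm_ir <- truth_pairs$idm_ir * cfg$n_conc_ir
  pairs_n$idm_c <- truth_pairs$idm_c * cfg$n_conc_c

  index_sets <- function(pairs) {
    bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      dplyr::bind_cols(tibble(unit_id = pairs$unit_id[i]),
                       compute_index_set(pairs[i, ]))
    }))
  }
  list(
    records = records,
    truth = list(
      stand_pairs_dmy = pairs_dmy,
      stand_pairs_n = pairs_n,
      index_sets_dmy = index_sets(pairs_dmy),
      index_sets_n = index_sets(pairs_n),
      config = cfg
    )
  )
}

#' Deterministic single-unit reference fixture
#'
#' A noise-free single site-season unit whose unit means equal the
#' reference dry-matter yields of an Italian ryegrass / clover trial:
#' pure grass 5.06 t/ha, pure clover 4.03 t/ha, mixture components 3.79
#' and 1.48 t/ha at 50:50 sowing, sown 27 Aug 2019 and harvested
#' 6 May 2020. Block values are the unit mean times symmetric factors, so
#' block means recover the unit means to machine precision. Nitrogen
#' concentrations are synthetic constants (24 and 32 g/kg) included only
#' so the nitrogen-basis code paths run on the fixture.
#'
#' @param n_blocks Number of blocks (default 4).
#' @return A `plot_records` tibble with `4 * n_blocks` rows.
#' @export
generate_table1_fixture <- function(n_blocks = 4) {
  means <- tibble(
    treatment = c("PURE_IR", "PURE_C", "MIX", "MIX"),
    component = c("IR", "C", "IR", "C"),
    dmy = c(5.06, 4.03, 3.79, 1.48),
    sown = c(1, 1, 0.5, 0.5),
    conc = c(24, 32, 24, 32)
  )
  factors <- rep_len(c(0.98, 1.02, 0.99, 1.01), n_blocks)
  factors <- factors / mean(factors)
  rows <- lapply(seq_len(n_blocks), function(b) {
    dmy <- means$dmy * factors[b]
    tibble(
      site_id = "S1", season_id = "2019-2020", block_id = sprintf("B%d", b),
      treatment = means$treatment, component = means$component,
      dmy = dmy, n_conc = means$conc, n_uptake = dmy * means$conc,
      sown_proportion = means$sown,
      sowing_date = as.Date("2019-08-27"), harvest_date = as.Date("2020-05-06")
    )
  })
  validate_plot_records(bind_rows(rows))
}
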