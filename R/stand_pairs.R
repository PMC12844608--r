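#' Construct a single stand pair
#'
#' A stand pair is the per-experimental-unit quartet of performances that
#' every index formula consumes: the two pure-stand performances, the two
#' mixture-component performances, the sown proportions, and the durations
#' each component occupies the field. Performances are t/ha on the
#' dry-matter basis and kg/ha on the nitrogen-uptake basis.
#'
#' @param sdm_ir,sdm_c Pure-stand performance of the grass (IR) and clover
#'   (C) components.
#' @param idm_ir,idm_c Performance of each component inside the mixture.
#' @param z_ir,z_c Sown proportions of the two components in the mixture;
#'   must sum to 1 within `1e-9` unless `check_z = FALSE`.
#' @param d_ir,d_c Days each component occupies the field.
#' @param t_total Days the intercropping system occupies the field.
#' @param unit_id Identifier of the experimental unit.
#' @param basis `"dmy"` or `"n"`; which measurement the performances carry.
#' @param check_z Enforce `z_ir + z_c == 1`? Disable for non-replacement
#'   designs.
#' @return A one-row `stand_pairs` tibble.
#' @export
#' @examples
#' stand_pair(sdm_ir = 5.06, sdm_c = 4.03, idm_ir = 3.79, idm_c = 1.48)
stand_pair <- function(sdm_ir, sdm_c, idm_ir, idm_c,
                       z_ir = 0.5, z_c = 0.5,
                       d_ir = 253, d_c = 253, t_total = 253,
                       unit_id = "unit", basis = c("dmy", "n"),
                       check_z = TRUE) {
  basis <- match.arg(basis)
  perf <- c(sdm_ir = sdm_ir, sdm_c = sdm_c, idm_ir = idm_ir, idm_c = idm_c)
  if (any(!is.finite(perf)) || any(perf < 0)) {
    abort("performances must be finite and >= 0", class = "intercrop_validation_error")
  }
  if (check_z && abs(z_ir + z_c - 1) > 1e-9) {
    abort("sown proportions must sum to 1 (use check_z = FALSE to override)",
          class = "intercrop_validation_error")
  }
  if (!(d_ir > 0 && d_c > 0 && d_ir <= t_total && d_c <= t_total)) {
    abort("durations must satisfy 0 < d <= t_total", class = "intercrop_validation_error")
  }
  out <- tibble(
    unit_id = unit_id, basis = basis,
    sdm_ir = sdm_ir, sdm_c = sdm_c, idm_ir = idm_ir, idm_c = idm_c,
    z_ir = z_ir, z_c = z_c, d_ir = d_ir, d_c = d_c, t_total = t_total
  )
  class(out) <- c("stand_pairs", class(out))
  out
}

as_stand_pair <- function(pair) {
  if (is.data.frame(pair)) {
    if (nrow(pair) != 1L) {
      abort("expected a single stand pair (one row)", class = "intercrop_validation_error")
    }
    pair <- as.list(pair)
  }
  needed <- c("sdm_ir", "sdm_c", "idm_ir", "idm_c", "z_ir", "z_c")
  miss <- setdiff(needed, names(pair))
  if (length(miss) > 0) {
    abort(paste0("stand pair lacks field(s): ", paste(miss, collapse = ", ")),
          class = "intercrop_validation_error")
  }
  pair$basis <- pair$basis %||% "dmy"
  pair$d_ir <- pair$d_ir %||% 1
  pair$d_c <- pair$d_c %||% 1
  pair$t_total <- pair$t_total %||% max(pair$d_ir, pair$d_c)
  pair
}

#' Assemble per-unit stand pairs from plot records
#'
#' Averages plot records up to the experimental unit and pairs the
#' pure-stand and mixture performances of both components. Under
#' `aggregation = "unit_mean"` the unit is a site-by-season combination
#' (this trial's averaging unit); under `"block_mean"` it is a
#' site-by-season-by-block combination. Durations are taken as
#' `harvest_date - sowing_date` in days, averaged over the contributing
#' rows.
#'
#' On the nitrogen basis, `n_uptake` is used where present and otherwise
#' computed as `dmy * n_conc` (t/ha x g/kg = kg/ha). Units with incomplete
#' nitrogen data are excluded with a warning rather than imputed, since the
#' indices are ratios and imputation would bias them silently.
#'
#' @param records A `plot_records` tibble.
#' @param basis `"dmy"` (dry-matter yield, default) or `"n"`
#'   (nitrogen uptake).
#' @param aggregation `"unit_mean"` (default) or `"block_mean"`.
#' @return A `stand_pairs` tibble with one row per experimental unit.
#' @export
build_stand_pairs <- function(records, basis = c("dmy", "n"),
                              aggregation = c("unit_mean", "block_mean")) {
  basis <- match.arg(basis)
  aggregation <- match.arg(aggregation)
  df <- as_tibble(records)

  if (basis == "n") {
    has_uptake <- "n_uptake" %in% names(df) && any(!is.na(df$n_uptake))
    has_conc <- "n_conc" %in% names(df) && any(!is.na(df$n_conc))
    if (!has_uptake && !has_conc) {
      abort("nitrogen basis requested but records carry neither n_uptake nor n_conc",
            class = "intercrop_basis_error")
    }
    up <- if ("n_uptake" %in% names(df)) df$n_uptake else rep(NA_real_, nrow(df))
    fill <- is.na(up) & ("n_conc" %in% names(df)) & !is.na(df$n_conc %||% NA)
    up[fill] <- df$dmy[fill] * df$n_conc[fill]
    df$.value <- up
    incomplete <- unique(paste(df$site_id, df$season_id, sep = ":")[is.na(df$.value)])
    if (length(incomplete) > 0) {
      warn(paste0("unit(s) excluded from nitrogen basis (incomplete N data): ",
                  paste(incomplete, collapse = ", ")),
           class = "intercrop_basis_warning")
      df <- df[!paste(df$site_id, df$season_id, sep = ":") %in% incomplete, , drop = FALSE]
    }
  } else {
    df$.value <- df$dmy
  }
  if (nrow(df) == 0) {
    abort("no records left after basis filtering", class = "intercrop_basis_error")
  }

  keys <- c("site_id", "season_id", if (aggregation == "block_mean") "block_id")
  df$.unit <- do.call(paste, c(df[keys], sep = ":"))
  df$.days <- as.numeric(df$harvest_date - df$sowing_date)
  df$.slot <- paste(df$treatment, df$component, sep = ".")

  units <- unique(df$.unit)
  needed <- c("PURE_IR.IR", "PURE_C.C", "MIX.IR", "MIX.C")
  rows <- lapply(units, function(u) {
    sub <- df[df$.unit == u, , drop = FALSE]
    miss <- setdiff(needed, unique(sub$.slot))
    if (length(miss) > 0) {
      abort(paste0("unit ", u, " is incomplete; missing ", paste(miss, collapse = ", ")),
            class = "intercrop_incomplete_unit_error")
    }
    slot_mean <- function(slot, col) mean(sub[[col]][sub$.slot == slot])
    tibble(
      unit_id = u,
      site_id = sub$site_id[1], season_id = sub$season_id[1],
      basis = basis,
      sdm_ir = slot_mean("PURE_IR.IR", ".value"),
      sdm_c = slot_mean("PURE_C.C", ".value"),
      idm_ir = slot_mean("MIX.IR", ".value"),
      idm_c = slot_mean("MIX.C", ".value"),
      z_ir = slot_mean("MIX.IR", "sown_proportion"),
      z_c = slot_mean("MIX.C", "sown_proportion"),
      d_ir = slot_mean("MIX.IR", ".days"),
      d_c = slot_mean("MIX.C", ".days"),
      t_total = max(slot_mean("MIX.IR", ".days"), slot_mean("MIX.C", ".days"))
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("stand_pairs", class(out))
  out
}
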