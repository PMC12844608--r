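# Reference unit means of the grass/clover trial (t/ha, 50:50 sowing)
ref_pair <- function(basis = "dmy") {
  stand_pair(sdm_ir = 5.06, sdm_c = 4.03, idm_ir = 3.79, idm_c = 1.48,
             z_ir = 0.5, z_c = 0.5, d_ir = 253, d_c = 253, t_total = 253,
             unit_id = "ref", basis = basis)
}

# random valid stand pairs for property tests (fixed seed set by caller)
random_pairs <- function(n, z_equal = FALSE) {
  lapply(seq_len(n), function(i) {
    z_ir <- if (z_equal) 0.5 else runif(1, 0.1, 0.9)
    sdm_ir <- runif(1, 1, 10)
    sdm_c <- runif(1, 1, 10)
    # keep idm strictly inside (0, sdm) so every index is defined
    stand_pair(
      sdm_ir = sdm_ir, sdm_c = sdm_c,
      idm_ir = runif(1, 0.05, 0.95) * sdm_ir,
      idm_c = runif(1, 0.05, 0.95) * sdm_c,
      z_ir = z_ir, z_c = 1 - z_ir,
      d_ir = 200, d_c = 200, t_total = 200,
      unit_id = paste0("u", i)
    )
  })
}

# write a small well-formed plot-record CSV; returns the path
write_toy_csv <- function(path, dmy_override = NULL, drop_n = FALSE) {
  df <- data.frame(
    site_id = "S1", season_id = "2019-2020",
    block_id = c("B1", "B1", "B1", "B1", "B2", "B2"),
    treatment = c("PURE_IR", "PURE_C", "MIX", "MIX", "PURE_IR", "PURE_C"),
    component = c("IR", "C", "IR", "C", "IR", "C"),
    dmy = c(5.0, 4.0, 3.8, 1.5, 5.2, 3.9),
    n_conc = 25, n_uptake = c(5.0, 4.0, 3.8, 1.5, 5.2, 3.9) * 25,
    sown_proportion = c(1, 1, 0.5, 0.5, 1, 1),
    sowing_date = "2019-08-27", harvest_date = "2020-05-06"
  )
  if (!is.null(dmy_override)) {
    df$dmy[dmy_override$row] <- dmy_override$value
    if (is.numeric(dmy_override$value)) {
      df$n_uptake[dmy_override$row] <- dmy_override$value * 25
    } else {
      df$n_uptake[dmy_override$row] <- 0
    }
  }
  if (drop_n) df <- df[, setdiff(names(df), c("n_conc", "n_uptake"))]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
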