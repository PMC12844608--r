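#' Spearman rank correlation with exact permutation p-value
#'
#' Computes the Spearman rank correlation (midranks for ties) and a
#' two-sided p-value. At small sample sizes (`n <= exact_n_max`, default 8)
#' the p-value comes from the exact permutation null: all `n!` permutations
#' of one vector are enumerated and the p-value is the fraction with
#' `|rho|` at least the observed `|rho|`. Above the cutoff a t
#' approximation on `n - 2` degrees of freedom is used. Exactness matters
#' at the sample sizes of multi-environment trials (n around 6), where the
#' t approximation is unreliable and attainable p-values form a coarse
#' grid: at n = 6 the smallest two-sided p is 2/720 and the exact critical
#' values are |rho| >= 0.886 for p < 0.05 and |rho| >= 0.829 for p < 0.10.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, finite values.
#' @param exact_n_max Largest n for which the exact permutation null is
#'   enumerated (capped at 10; 8 by default).
#' @return A list with `rho`, `p` (two-sided), `n` and `method`
#'   (`"exact_permutation"` or `"t_approximation"`). A constant input
#'   vector yields `rho = NA`, `p = NA` with a warning (flagged, not an
#'   error).
#' @export
#' @examples
#' spearman_exact(1:6, c(2, 1, 4, 3, 6, 5))
spearman_exact <- function(x, y, exact_n_max = 8) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "intercrop_contract_error")
  }
  n <- length(x)
  if (n < 3) abort("need at least 3 observations", class = "intercrop_contract_error")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("x and y must be finite", class = "intercrop_contract_error")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warn("constant vector: rank correlation undefined",
         class = "intercrop_constant_vector_warning")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= min(exact_n_max, 10)) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # rho under each permutation of y against fixed x
    rho_perm <- as.vector(matrix(ryc[t(perms)], ncol = n, byrow = TRUE) %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Per-unit competition parameters of the two crops
#'
#' Assembles, from plot records, the per-experimental-unit parameter
#' vectors that the cross-crop correlation analysis relates: for each side
#' (IR and C) the mixture performance on both bases (`dmy`, `n`) and the
#' per-unit partial RYT, RCC, CR, aggressivity and AYL on both bases
#' (suffixes `_dmy` and `_n`).
#'
#' @param records A `plot_records` tibble covering at least 3 complete
#'   units with nitrogen data.
#' @param options An [index_options()] object passed to the index engine.
#' @return A list with tibbles `ir` and `c`, one row per unit, columns
#'   `unit_id`, `dmy`, `n`, `ryt_dmy`, `ryt_n`, `rcc_dmy`, `rcc_n`,
#'   `cr_dmy`, `cr_n`, `a_dmy`, `a_n`, `ayl_dmy`, `ayl_n`.
#' @export
unit_parameters <- function(records, options = index_options()) {
  pairs_dmy <- build_stand_pairs(records, basis = "dmy")
  pairs_n <- build_stand_pairs(records, basis = "n")
  per_dmy <- run_pipeline(pairs_dmy, options)$per_unit
  per_n <- run_pipeline(pairs_n, options)$per_unit
  stopifnot(identical(per_dmy$unit_id, per_n$unit_id))
  side <- function(suffix) {
    pick <- function(df, stem) df[[paste0(stem, "_", suffix)]]
    tibble(
      unit_id = per_dmy$unit_id,
      dmy = pairs_dmy[[paste0("idm_", suffix)]],
      n = pairs_n[[paste0("idm_", suffix)]],
      ryt_dmy = pick(per_dmy, "ryt"), ryt_n = pick(per_n, "ryt"),
      rcc_dmy = pick(per_dmy, "rcc"), rcc_n = pick(per_n, "rcc"),
      cr_dmy = pick(per_dmy, "cr"), cr_n = pick(per_n, "cr"),
      a_dmy = pick(per_dmy, "a"), a_n = pick(per_n, "a"),
      ayl_dmy = pick(per_dmy, "ayl"), ayl_n = pick(per_n, "ayl")
    )
  }
  list(ir = side("ir"), c = side("c"))
}

#' Cross-crop rank correlation matrix
#'
#' Correlates every C-side parameter (rows) with every IR-side parameter
#' (columns) across experimental units using [spearman_exact()], and
#' assigns the two significance tiers used for small multi-environment
#' trials: `"**"` for two-sided p < 0.05 and `"*"` for p < 0.10.
#'
#' @param ir_params,c_params Tibbles with a `unit_id` column and numeric
#'   parameter columns, e.g. from [unit_parameters()]. Units are aligned by
#'   `unit_id`.
#' @param exact_n_max Passed to [spearman_exact()].
#' @return A `correlation_matrix` list with matrices `rho`, `p`, `tier`
#'   (rows = C parameters, columns = IR parameters), the unit count `n`,
#'   and `row_params`/`col_params`. Constant parameters yield `NA`
#'   correlations with a warning.
#' @seealso [correlation_long()] for a tidy long-format view.
#' @export
build_correlation_matrix <- function(ir_params, c_params, exact_n_max = 8) {
  ir <- as_tibble(ir_params)
  cc <- as_tibble(c_params)
  if (!"unit_id" %in% names(ir) || !"unit_id" %in% names(cc)) {
    abort("both parameter tables need a unit_id column", class = "intercrop_contract_error")
  }
  cc <- cc[match(ir$unit_id, cc$unit_id), , drop = FALSE]
  if (anyNA(cc$unit_id)) abort("unit_id sets differ", class = "intercrop_contract_error")
  n <- nrow(ir)
  if (n < 3) abort("need at least 3 units", class = "intercrop_contract_error")
  col_params <- setdiff(names(ir), "unit_id")
  row_params <- setdiff(names(cc), "unit_id")
  drop_col <- col_params[vapply(col_params, function(p) anyNA(ir[[p]]), TRUE)]
  drop_row <- row_params[vapply(row_params, function(p) anyNA(cc[[p]]), TRUE)]
  if (length(c(drop_col, drop_row)) > 0) {
    warn(paste0("parameter(s) dropped (missing values): ",
                paste(c(drop_col, drop_row), collapse = ", ")),
         class = "intercrop_validation_warning")
    col_params <- setdiff(col_params, drop_col)
    row_params <- setdiff(row_params, drop_row)
  }
  rho <- p <- matrix(NA_real_, length(row_params), length(col_params),
                     dimnames = list(row_params, col_params))
  for (rp in row_params) {
    for (cp in col_params) {
      res <- spearman_exact(cc[[rp]], ir[[cp]], exact_n_max = exact_n_max)
      rho[rp, cp] <- res$rho
      p[rp, cp] <- res$p
    }
  }
  tier <- matrix("", nrow(rho), ncol(rho), dimnames = dimnames(rho))
  tier[!is.na(p) & p < 0.10] <- "*"
  tier[!is.na(p) & p < 0.05] <- "**"
  tier[is.na(p)] <- NA_character_
  structure(
    list(rho = rho, p = p, tier = tier, n = n,
         row_params = row_params, col_params = col_params),
    class = "correlation_matrix"
  )
}

#' Long-format view of a correlation matrix
#'
#' @param cm A `correlation_matrix` from [build_correlation_matrix()].
#' @return A tibble with columns `row_param`, `col_param`, `rho`, `p`,
#'   `n`, `tier`.
#' @export
correlation_long <- function(cm) {
  grid <- expand.grid(row_param = cm$row_params, col_param = cm$col_params,
                      stringsAsFactors = FALSE)
  tibble(
    row_param = grid$row_param,
    col_param = grid$col_param,
    rho = cm$rho[cbind(grid$row_param, grid$col_param)],
    p = cm$p[cbind(grid$row_param, grid$col_param)],
    n = cm$n,
    tier = cm$tier[cbind(grid$row_param, grid$col_param)]
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Cross-crop Spearman correlations (n =", x$n, "units)\n")
  cat("tiers: ** p < 0.05, * p < 0.10 (two-sided",
      if (x$n <= 8) "exact permutation" else "t approximation", "p)\n\n")
  shown <- matrix(paste0(formatC(x$rho, digits = 2, format = "f"), x$tier),
                  nrow(x$rho), ncol(x$rho), dimnames = dimnames(x$rho))
  shown[is.na(x$rho)] <- "NA"
  print(shown, quote = FALSE)
  invisible(x)
}
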