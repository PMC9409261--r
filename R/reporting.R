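#' Mean hydrogen-bond energy versus helix length
#'
#' Aggregates per-pair energies by model into mean and population standard
#' deviation, together with the helix-length proxies used for cooperativity
#' plots: the hydrogen-bond pair count `L` (the minimum length of the helix
#' in units of one helical H-bond increment) and `1/L^2`.
#'
#' @param energies Data frame with at least `model` and an energy column
#'   (`e_hb` or `e_mm`), one row per pair, e.g. from
#'   [hbond_energy_pipeline()] or [mm_hbond_energies()].
#' @return Data frame with `model`, `n_pairs`, `mean_e`, `sd_e`, `L`,
#'   `inv_L2`, ordered by `n_pairs`.
#' @export
energy_vs_length <- function(energies) {
  if (!is.data.frame(energies) || nrow(energies) == 0) {
    stop("helixhb: need a non-empty per-pair energy table", call. = FALSE)
  }
  ecol <- intersect(c("e_hb", "e_mm"), names(energies))[1]
  if (is.na(ecol)) stop("helixhb: no energy column (e_hb or e_mm) found", call. = FALSE)
  parts <- split(energies, energies$model)
  out <- do.call(rbind, lapply(parts, function(m) {
    e <- m[[ecol]]
    data.frame(model = m$model[1], n_pairs = length(e), mean_e = mean(e),
               sd_e = pop_sd(e), L = length(e), inv_L2 = 1 / length(e)^2,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$n_pairs), ]
  rownames(out) <- NULL
  out
}

#' Compare two matched sets of hydrogen-bond energies
#'
#' Pearson correlation, least-squares regression (`y ~ x`) and group
#' means +/- population standard deviation for two energy tables matched by
#' pair label — typically quantum-chemical energies (imported) against
#' molecular-mechanics energies (computed here).
#'
#' @param qm,mm Data frames with columns `pair` and an energy column
#'   (`e_hb`, `e_mm`, or `energy`).
#' @return List of class `comparison_stats`: `n`, `r`, `slope`,
#'   `intercept`, `mean_qm`, `sd_qm`, `mean_mm`, `sd_mm`. `mm` is `x`, `qm`
#'   is `y` in the regression.
#' @export
compare_qm_mm <- function(qm, mm) {
  getcol <- function(d) {
    ecol <- intersect(c("e_hb", "e_mm", "energy"), names(d))[1]
    if (is.na(ecol)) stop("helixhb: no energy column found", call. = FALSE)
    data.frame(pair = d$pair, e = d[[ecol]], stringsAsFactors = FALSE)
  }
  m <- merge(getcol(qm), getcol(mm), by = "pair", suffixes = c("_qm", "_mm"))
  if (nrow(m) < 3) {
    stop("helixhb: insufficient data, need at least 3 matched pairs", call. = FALSE)
  }
  fit <- stats::lm(e_qm ~ e_mm, data = m)
  structure(list(
    n = nrow(m),
    r = stats::cor(m$e_mm, m$e_qm),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    mean_qm = mean(m$e_qm), sd_qm = pop_sd(m$e_qm),
    mean_mm = mean(m$e_mm), sd_mm = pop_sd(m$e_mm)
  ), class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> n = %d pairs\n", x$n))
  cat(sprintf("  r = %.3f, fit: y = %.3f x + %.3f\n", x$r, x$slope, x$intercept))
  cat(sprintf("  means +/- sd: y %.2f +/- %.2f, x %.2f +/- %.2f kcal/mol\n",
              x$mean_qm, x$sd_qm, x$mean_mm, x$sd_mm))
  invisible(x)
}
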