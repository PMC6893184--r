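# Replicate-level summary statistics: genetic gain, gain ratios between
# recombination scenarios, and across-replicate aggregation with 95% CIs.

#' Genetic gain at a generation
#'
#' Difference between the population's mean genotypic value at generation
#' `g` and at generation 2 (the first generation subject to selection).
#' Because paired scenarios share the g = 2 genetic variance, gains are not
#' normalized.
#'
#' @param traj a trajectory data.frame for one replicate and scenario (with
#'   `generation` and `mean_G` columns).
#' @param g generation index (>= 2).
#' @return scalar gain in trait units.
#' @export
genetic_gain <- function(traj, g) {
  if (!g %in% traj$generation) stop("generation ", g, " not in trajectory")
  traj$mean_G[traj$generation == g] - traj$mean_G[traj$generation == 2]
}

#' Gain ratio (efficiency of modified recombination)
#'
#' Ratio of genetic gains between a modified-recombination scenario and the
#' normal one at the same generation. The headline estimator is the ratio of
#' across-replicate mean gains; the per-replicate paired ratios are also
#' returned as a diagnostic.
#'
#' @param gain_modified,gain_normal per-replicate gains under the modified
#'   and normal landscapes (paired by replicate when of equal length).
#' @return list of class `gain_ratio`: `ratio` (ratio of mean gains; `NA`
#'   with a warning when the mean normal gain is 0), `paired_ratios`,
#'   `mean_paired_ratio`.
#' @export
gain_ratio <- function(gain_modified, gain_normal) {
  mn <- mean(gain_normal)
  mm <- mean(gain_modified)
  if (mn == 0) {
    warning("undefined ratio: mean normal gain is 0")
    ratio <- NA_real_
  } else {
    ratio <- mm / mn
  }
  paired <- if (length(gain_modified) == length(gain_normal)) {
    ifelse(gain_normal == 0, NA_real_, gain_modified / gain_normal)
  } else NA_real_
  structure(list(ratio = ratio, paired_ratios = paired,
                 mean_paired_ratio = mean(paired, na.rm = TRUE)),
            class = "gain_ratio")
}

#' @export
print.gain_ratio <- function(x, ...) {
  cat(sprintf("<gain_ratio: %.4f (mean of paired ratios %.4f)>\n",
              x$ratio, x$mean_paired_ratio))
  invisible(x)
}

#' Aggregate per-replicate trajectories
#'
#' Across-replicate means and 95% confidence half-widths
#' (`1.96 * sd / sqrt(n)`) of the mean genotypic value, genetic variance and
#' gain, per scenario and generation.
#'
#' @param traj stacked trajectory data.frame with a `replicate` column (as
#'   produced by [run_experiment()]).
#' @return data.frame with one row per scenario x generation: means and
#'   `ci_*` half-widths, plus `n_replicates`.
#' @export
aggregate_replicates <- function(traj) {
  if (length(unique(traj$replicate)) < 2L) {
    stop("insufficient replicates: need at least 2")
  }
  key <- interaction(traj$scenario, traj$generation, drop = TRUE)
  agg <- function(v, f) tapply(v, key, f)
  ci <- function(v) 1.96 * tapply(v, key, sd) / sqrt(tapply(v, key, length))
  out <- data.frame(
    scenario = agg(as.character(traj$scenario), function(x) x[1L]),
    generation = agg(traj$generation, function(x) x[1L]),
    mean_G = agg(traj$mean_G, mean), ci_mean_G = ci(traj$mean_G),
    var_G = agg(traj$var_G, mean), ci_var_G = ci(traj$var_G),
    gain = agg(traj$gain, mean), ci_gain = ci(traj$gain),
    n_replicates = as.vector(agg(traj$gain, length)),
    row.names = NULL
  )
  out[order(out$scenario, out$generation), ]
}

#' Gain-ratio summary between scenarios
#'
#' For each modified scenario present in `traj`, computes the ratio of mean
#' gains against the `normal` scenario at each generation, with 95% CI
#' half-widths of the per-scenario mean gains.
#'
#' @param traj stacked trajectory data.frame with `replicate`, `scenario`,
#'   `generation`, `gain`.
#' @param normal name of the reference scenario.
#' @return data.frame: `scenario_pair`, `generation`, `mean_gain_normal`,
#'   `mean_gain_modified`, `gain_ratio`, `ci_normal`, `ci_modified`,
#'   `n_replicates`.
#' @export
summarize_gain_ratios <- function(traj, normal = "normal") {
  scen <- setdiff(unique(as.character(traj$scenario)), normal)
  gens <- sort(unique(traj$generation))
  base <- traj[traj$scenario == normal, ]
  rows <- list()
  for (s in scen) {
    mod <- traj[traj$scenario == s, ]
    for (g in gens) {
      gn <- base$gain[base$generation == g]
      gm <- mod$gain[mod$generation == g]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_pair = paste0(s, "/", normal), generation = g,
        mean_gain_normal = mean(gn), mean_gain_modified = mean(gm),
        gain_ratio = if (mean(gn) == 0) NA_real_ else mean(gm) / mean(gn),
        ci_normal = 1.96 * sd(gn) / sqrt(length(gn)),
        ci_modified = 1.96 * sd(gm) / sqrt(length(gm)),
        n_replicates = length(gn))
    }
  }
  do.call(rbind, rows)
}
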