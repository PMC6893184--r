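# Replicated paired-scenario experiments: the same trait architecture (QTL
# physical positions, amplitudes, founder phase) is run under each
# recombination landscape; only genetic coordinates and meiosis randomness
# differ between scenarios.

#' Experiment configuration
#'
#' @param species `"brapa"` or `"osativa"` preset for the synthetic genome.
#' @param scenarios landscape scenarios to run (paired within replicate).
#' @param n_replicates number of replicates.
#' @param base_seed integer; replicate r uses seed `base_seed + r` for its
#'   trait architecture and derived per-scenario streams for meioses.
#' @param n_qtl_per_chrom QTL per chromosome (one of 2, 10, 20, 50, 200,
#'   1000 in the reference designs).
#' @param phase_mode founder linkage phase: `"random"`, `"coupling"` or
#'   `"repulsion"`.
#' @param L coupling/repulsion characteristic length (cM).
#' @param scheme,pop_size,n_selected,n_generations,selection_mode,h2,recalibration,markers_per_chrom,interference,allow_selfing
#'   passed to [scheme_config()].
#' @param genome_config optional `syn_genome_config` overriding the species
#'   preset (e.g. custom pericentromere geometry).
#' @param sweep optional list `list(variable = <config field>, levels =
#'   <vector>)`; [run_experiment()] then repeats the design at each level.
#' @param out_dir optional output directory for CSV files.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(species = c("brapa", "osativa"),
                              scenarios = c("normal", "hyperrec", "boosted"),
                              n_replicates = 1000L, base_seed = 1L,
                              n_qtl_per_chrom = 200L, phase_mode = "random",
                              L = 5, scheme = "Fn", pop_size = 250L,
                              n_selected = 5L, n_generations = 20L,
                              selection_mode = "genomic", h2 = 0.5,
                              recalibration = "every_4",
                              markers_per_chrom = 1000L,
                              interference = FALSE, allow_selfing = FALSE,
                              genome_config = NULL, sweep = NULL,
                              out_dir = NULL) {
  species <- match.arg(species)
  stopifnot(all(scenarios %in% c("normal", "hyperrec", "boosted")))
  structure(
    list(species = species, scenarios = scenarios,
         n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed),
         n_qtl_per_chrom = as.integer(n_qtl_per_chrom),
         phase_mode = phase_mode, L = L, scheme = scheme,
         pop_size = as.integer(pop_size), n_selected = as.integer(n_selected),
         n_generations = as.integer(n_generations),
         selection_mode = selection_mode, h2 = h2,
         recalibration = recalibration,
         markers_per_chrom = as.integer(markers_per_chrom),
         interference = interference, allow_selfing = allow_selfing,
         genome_config = genome_config, sweep = sweep, out_dir = out_dir),
    class = "experiment_config"
  )
}

as_scheme_config <- function(ec) {
  scheme_config(scheme = ec$scheme, pop_size = ec$pop_size,
                n_selected = ec$n_selected,
                n_generations = ec$n_generations,
                selection_mode = ec$selection_mode, h2 = ec$h2,
                recalibration = ec$recalibration,
                markers_per_chrom = ec$markers_per_chrom,
                interference = ec$interference,
                allow_selfing = ec$allow_selfing)
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()].
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

# small rolling hash of the deparsed configuration, for output provenance
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# deterministic per-(replicate, scenario) seed below 2^31
scenario_seed <- function(rep_seed, scenario_index) {
  (rep_seed * 7L + scenario_index * 101L) %% 2147483647L
}

#' Run paired replicates of a selection program under several landscapes
#'
#' For each replicate, a trait architecture is drawn (QTL positions sampled
#' among genes, gamma amplitudes, founder phase assigned on normal-map
#' genetic distances) and the configured scheme is run once per scenario
#' with that shared architecture.
#'
#' @param ec an `experiment_config`.
#' @param genome optional pre-built `genome_spec` (otherwise generated from
#'   the species preset).
#' @param genes optional pre-built gene position list.
#' @return stacked trajectory data.frame with columns `replicate`, `seed`,
#'   `scenario`, `scheme`, `generation`, `mean_G`, `var_G`, `gain`,
#'   `n_fixed_qtl`, `gs_trained`, `config_hash`.
#' @export
run_paired_replicates <- function(ec, genome = NULL, genes = NULL) {
  if (is.null(genome)) {
    gc <- if (!is.null(ec$genome_config)) ec$genome_config
          else synthetic_genome_config(ec$species, seed = ec$base_seed)
    genome <- gen_landscape(gc)
    if (is.null(genes)) genes <- gen_gene_positions(gc)
  } else if (is.null(genes)) {
    stop("genes must be supplied alongside a pre-built genome")
  }
  sc <- as_scheme_config(ec)
  hash <- config_hash(ec[setdiff(names(ec), "out_dir")])
  out <- vector("list", ec$n_replicates * length(ec$scenarios))
  k <- 0L
  for (r in seq_len(ec$n_replicates)) {
    rep_seed <- ec$base_seed + r
    set.seed(rep_seed)
    trait <- make_trait_model(genome, genes,
                              n_qtl_per_chrom = ec$n_qtl_per_chrom,
                              phase_mode = ec$phase_mode, L = ec$L)
    for (si in seq_along(ec$scenarios)) {
      s <- ec$scenarios[si]
      set.seed(scenario_seed(rep_seed, si))
      traj <- run_scheme(sc, genome$landscapes[[s]], trait)
      traj$replicate <- r
      traj$seed <- rep_seed
      traj$config_hash <- hash
      k <- k + 1L
      out[[k]] <- traj
    }
  }
  do.call(rbind, out)
}

#' Run a configured experiment (with optional parameter sweep)
#'
#' Runs [run_paired_replicates()] at each sweep level (or once when no
#' sweep is configured), aggregates the trajectories and the gain ratios,
#' and optionally writes `trajectories.csv`, `summary.csv` and
#' `gain_ratios.csv` to `out_dir`.
#'
#' @param ec an `experiment_config`.
#' @return list with `trajectories` (per-replicate rows, with a `level`
#'   column when sweeping), `summary` (aggregated means and CIs) and
#'   `gain_ratios`.
#' @export
run_experiment <- function(ec) {
  stopifnot(inherits(ec, "experiment_config"))
  levels <- if (is.null(ec$sweep)) list(NULL) else as.list(ec$sweep$levels)
  traj_all <- list()
  for (lv in levels) {
    ec_lv <- ec
    if (!is.null(lv)) ec_lv[[ec$sweep$variable]] <- lv
    traj <- run_paired_replicates(ec_lv)
    traj$level <- if (is.null(lv)) NA else lv
    traj_all[[length(traj_all) + 1L]] <- traj
  }
  traj <- do.call(rbind, traj_all)
  by_level <- split(traj, if (all(is.na(traj$level))) rep(1, nrow(traj))
                          else traj$level)
  summ <- do.call(rbind, lapply(names(by_level), function(nm) {
    s <- aggregate_replicates(by_level[[nm]])
    s$level <- if (all(is.na(traj$level))) NA else nm
    s
  }))
  ratios <- do.call(rbind, lapply(names(by_level), function(nm) {
    r <- summarize_gain_ratios(by_level[[nm]])
    if (is.null(r)) return(NULL)
    r$level <- if (all(is.na(traj$level))) NA else nm
    r
  }))
  if (!is.null(ec$out_dir)) {
    dir.create(ec$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(traj, file.path(ec$out_dir, "trajectories.csv"),
              row.names = FALSE)
    write.csv(summ, file.path(ec$out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(ratios)) {
      write.csv(ratios, file.path(ec$out_dir, "gain_ratios.csv"),
                row.names = FALSE)
    }
  }
  list(trajectories = traj, summary = summ, gain_ratios = ratios)
}
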