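# Small in-code fixtures shared across test files.

# genome with uniform recombination (no cold region) on a few short
# chromosomes; fast to simulate and analytically transparent
uniform_genome <- function(n_chrom = 2L, GL = 100, GL_inc = 300, PL = 40,
                           genes_per_chrom = 500L, seed = 99L) {
  cfg <- synthetic_genome_config(
    GL_normal = rep(GL, n_chrom), GL_increased = rep(GL_inc, n_chrom),
    PL = PL, cold_rate_frac = 1, genes_per_chrom = genes_per_chrom,
    nu_normal = NULL, nu_boosted = NULL, seed = seed)
  list(config = cfg, genome = gen_landscape(cfg),
       genes = gen_gene_positions(cfg))
}

# hand-built trait: one list of genetic positions per chromosome with given
# amplitudes and founder-P1 signs, identical in every scenario
manual_trait <- function(pos_by_chrom, amp_by_chrom, sign_by_chrom) {
  scen <- list(normal = pos_by_chrom, hyperrec = pos_by_chrom,
               boosted = pos_by_chrom)
  signs <- list(normal = sign_by_chrom, hyperrec = sign_by_chrom,
                boosted = sign_by_chrom)
  structure(
    list(qtl_physical = pos_by_chrom, amplitude = amp_by_chrom,
         sign_P1 = signs, qtl_genetic = scen, phase_mode = "manual"),
    class = "trait_model")
}

# bare landscape stub for meiosis-level tests (only GL and nu are used)
bare_landscape <- function(GL, nu = NULL, scenario = "normal") {
  structure(list(scenario = scenario, GL = GL, nu = nu),
            class = "recombination_landscape")
}

# small, fast experiment configuration on a 2-chromosome genome
small_experiment <- function(..., n_replicates = 2L, base_seed = 11L) {
  gc <- synthetic_genome_config(
    GL_normal = c(60, 80), GL_increased = c(150, 200), PL = 30,
    genes_per_chrom = 300L, seed = 5L)
  experiment_config(
    "brapa", n_replicates = n_replicates, base_seed = base_seed,
    n_qtl_per_chrom = 10L, pop_size = 40L, n_selected = 4L,
    n_generations = 6L, markers_per_chrom = 50L, genome_config = gc, ...)
}
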