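# Synthetic genome generator: Marey maps with pericentromeric cold regions
# matching preset total genetic lengths, gene physical positions with reduced
# pericentromeric density, and trait architectures (QTL) sampled from them.
# This stands in for experimentally measured maps and annotations, which a
# user can instead supply via read_marey_map()/read_gff_genes().

#' Configuration of the synthetic genome generator
#'
#' Defaults follow the study conditions: per-chromosome normal and increased
#' genetic lengths from the species preset; a pericentromeric cold region
#' occupying the central 40% of each chromosome's physical span, with a
#' recombination rate of 2% of what a uniform map would have, and a relative
#' gene density of 30% of the chromosome arms.
#'
#' @param species `"brapa"` or `"osativa"` (sets chromosome number and
#'   Table-of-lengths defaults); ignored if `GL_normal` is supplied.
#' @param GL_normal,GL_increased per-chromosome genetic lengths in cM;
#'   `GL_increased` must exceed `GL_normal` everywhere.
#' @param chrom_ids chromosome labels.
#' @param PL per-chromosome mapped physical span in Mb (recycled). Only rate
#'   ratios matter downstream (simulation operates in genetic space).
#' @param pericentromere_center,pericentromere_width center and width of the
#'   cold region as fractions of the physical span.
#' @param cold_rate_frac recombination rate inside the pericentromere as a
#'   fraction of the chromosome-average rate, in `[0, 1)`.
#' @param gene_density_cold_frac relative gene density inside the
#'   pericentromere, in `[0, 1]`.
#' @param genes_per_chrom number of gene positions generated per chromosome.
#' @param nu_normal,nu_boosted optional per-chromosome gamma-interference
#'   shape parameters (>= 1) attached to the normal and boosted landscapes;
#'   defaults to the B. rapa preset values for that species, absent otherwise.
#' @param seed RNG seed used when generating gene positions.
#' @return list of class `syn_genome_config`.
#' @export
synthetic_genome_config <- function(species = c("brapa", "osativa"),
                                    GL_normal = NULL, GL_increased = NULL,
                                    chrom_ids = NULL, PL = 40,
                                    pericentromere_center = 0.5,
                                    pericentromere_width = 0.4,
                                    cold_rate_frac = 0.02,
                                    gene_density_cold_frac = 0.3,
                                    genes_per_chrom = 4000L,
                                    nu_normal = NULL, nu_boosted = NULL,
                                    seed = NULL) {
  species <- match.arg(species)
  preset <- species_lengths(species)
  if (is.null(GL_normal)) GL_normal <- preset$GL_normal
  if (is.null(GL_increased)) GL_increased <- preset$GL_increased
  n_chrom <- length(GL_normal)
  if (is.null(chrom_ids)) {
    chrom_ids <- if (n_chrom == length(preset$chrom_ids)) preset$chrom_ids
                 else sprintf("chr%02d", seq_len(n_chrom))
  }
  if (is.null(nu_normal)) nu_normal <- preset$nu_normal
  if (is.null(nu_boosted)) nu_boosted <- preset$nu_boosted
  # interference parameters only apply when the chromosome count matches
  if (!is.null(nu_normal) && length(nu_normal) != n_chrom) nu_normal <- NULL
  if (!is.null(nu_boosted) && length(nu_boosted) != n_chrom) nu_boosted <- NULL
  if (!is.null(nu_normal) && any(nu_normal < 1)) {
    stop("invalid interference parameter: nu must be >= 1")
  }
  stopifnot(
    length(GL_increased) == n_chrom,
    all(GL_increased > GL_normal),
    all(GL_normal > 0),
    pericentromere_width > 0, pericentromere_width < 1,
    cold_rate_frac >= 0, cold_rate_frac <= 1,
    gene_density_cold_frac >= 0, gene_density_cold_frac <= 1
  )
  structure(
    list(species = species, n_chrom = n_chrom, chrom_ids = chrom_ids,
         GL_normal = GL_normal, GL_increased = GL_increased,
         PL = rep_len(PL, n_chrom),
         pericentromere_center = pericentromere_center,
         pericentromere_width = pericentromere_width,
         cold_rate_frac = cold_rate_frac,
         gene_density_cold_frac = gene_density_cold_frac,
         genes_per_chrom = as.integer(genes_per_chrom),
         nu_normal = nu_normal, nu_boosted = nu_boosted, seed = seed),
    class = "syn_genome_config"
  )
}

#' Read a synthetic-genome configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_genome_config()].
#'
#' @param path YAML file path.
#' @return a `syn_genome_config`.
#' @export
read_genome_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(synthetic_genome_config, vals)
}

# cold-region physical bounds (Mb) for chromosome c
peri_bounds <- function(config, c) {
  half <- config$pericentromere_width / 2
  config$PL[c] * c(config$pericentromere_center - half,
                   config$pericentromere_center + half)
}

#' Generate the three recombination landscapes of a synthetic genome
#'
#' For each chromosome, builds a normal Marey map with a piecewise-constant
#' rate profile (cold pericentromere at `cold_rate_frac` times the uniform
#' rate, warm arms elsewhere) whose total genetic length equals `GL_normal`;
#' the increased landscapes are derived from it with [make_hyperrec()]
#' (multiplicative, shape-preserving) and [make_boosted()] (additive,
#' pericentromere-warming), both reaching `GL_increased` exactly. The
#' generator is deterministic given the configuration.
#'
#' @param config a `syn_genome_config`.
#' @return a `genome_spec`: list with `n_chrom`, `chrom_ids` and
#'   `landscapes`, the latter holding one `recombination_landscape` (fields
#'   `scenario`, `maps`, `GL`, `nu`) per scenario `normal`, `hyperrec`,
#'   `boosted`.
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "syn_genome_config"))
  maps_normal <- vector("list", config$n_chrom)
  for (c in seq_len(config$n_chrom)) {
    PL <- config$PL[c]
    GL <- config$GL_normal[c]
    w <- config$pericentromere_width
    cf <- config$cold_rate_frac
    bounds <- peri_bounds(config, c)
    # warm-arm rate solving (1 - w) * r + w * cf * r = GL / PL
    r_warm <- (GL / PL) / ((1 - w) + w * cf)
    r_cold <- cf * r_warm
    phys <- sort(unique(c(seq(0, PL, length.out = 201L), bounds)))
    rate <- ifelse(phys >= bounds[1L] & phys < bounds[2L], r_cold, r_warm)
    # cumulative genetic position; each interval uses the rate at its left
    # edge, so the step profile integrates exactly
    gen <- c(0, cumsum(rate[-length(phys)] * diff(phys)))
    maps_normal[[c]] <- fit_map(cbind(phys, gen), chrom = config$chrom_ids[c],
                                smooth = FALSE)
  }
  maps_hr <- mapply(make_hyperrec, maps_normal, config$GL_increased,
                    SIMPLIFY = FALSE)
  maps_bo <- mapply(make_boosted, maps_normal, config$GL_increased,
                    SIMPLIFY = FALSE)
  mk <- function(scenario, maps, nu) {
    structure(list(scenario = scenario, maps = maps,
                   GL = vapply(maps, `[[`, numeric(1), "GL"), nu = nu),
              class = "recombination_landscape")
  }
  structure(
    list(n_chrom = config$n_chrom, chrom_ids = config$chrom_ids,
         config = config,
         landscapes = list(
           normal = mk("normal", maps_normal, config$nu_normal),
           hyperrec = mk("hyperrec", maps_hr, NULL),
           boosted = mk("boosted", maps_bo, config$nu_boosted))),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec: %d chromosomes; GL normal %.1f cM, increased %.1f cM>\n",
              x$n_chrom, sum(x$landscapes$normal$GL),
              sum(x$landscapes$boosted$GL)))
  invisible(x)
}

#' Generate gene physical positions
#'
#' Samples gene positions along each chromosome with uniform density on the
#' arms and density reduced by `gene_density_cold_frac` inside the
#' pericentromere, emulating the reduced (but non-zero) gene content of
#' crossover-poor regions.
#'
#' @param config a `syn_genome_config`; its `seed`, when set, makes the gene
#'   complement reproducible.
#' @param genes_per_chrom number of genes per chromosome (default from
#'   config).
#' @return list (per chromosome) of sorted physical positions in Mb.
#' @export
gen_gene_positions <- function(config, genes_per_chrom = config$genes_per_chrom) {
  stopifnot(inherits(config, "syn_genome_config"), genes_per_chrom >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  lapply(seq_len(config$n_chrom), function(c) {
    PL <- config$PL[c]
    w <- config$pericentromere_width
    gf <- config$gene_density_cold_frac
    bounds <- peri_bounds(config, c)
    p_in <- (gf * w) / (gf * w + (1 - w))
    inside <- runif(genes_per_chrom) < p_in
    x <- numeric(genes_per_chrom)
    n_in <- sum(inside)
    x[inside] <- runif(n_in, bounds[1L], bounds[2L])
    # arms: two segments, mass proportional to length
    u <- runif(genes_per_chrom - n_in) * (PL - diff(bounds))
    x[!inside] <- ifelse(u < bounds[1L], u, u + diff(bounds))
    sort(x)
  })
}

#' Sample QTL physical positions among genes
#'
#' Draws `n_qtl_per_chrom` distinct gene positions uniformly without
#' replacement on each chromosome; QTL therefore track gene density.
#' Resampled independently for each replicate.
#'
#' @param gene_positions list (per chromosome) of gene physical positions.
#' @param n_qtl_per_chrom number of QTL per chromosome.
#' @return list (per chromosome) of sorted QTL physical positions (Mb).
#' @export
sample_qtl <- function(gene_positions, n_qtl_per_chrom) {
  lapply(gene_positions, function(g) {
    if (n_qtl_per_chrom > length(g)) {
      stop("insufficient genes: asked for ", n_qtl_per_chrom,
           " QTL but only ", length(g), " genes on a chromosome")
    }
    sort(sample(g, n_qtl_per_chrom))
  })
}

#' Draw QTL amplitudes from a gamma distribution
#'
#' Amplitudes are i.i.d. gamma with shape `k = 0.4` (an L-shaped
#' distribution: most QTL have weak effects) and scale `theta = 1.58`, chosen
#' so the amplitude variance `k * theta^2` is ~1. Each of the two alleles at
#' a QTL carries half the amplitude, with opposite signs in the two founders.
#'
#' @param n number of amplitudes.
#' @param k gamma shape.
#' @param theta gamma scale.
#' @return positive numeric vector of length `n`.
#' @export
draw_amplitudes <- function(n, k = 0.4, theta = 1.58) {
  stopifnot(n >= 1)
  rgamma(n, shape = k, scale = theta)
}

#' Assign founder allele signs with coupling or repulsion
#'
#' Walks along each chromosome's QTL in genetic-map order. The first QTL
#' gets a uniform random sign. For each subsequent QTL, the probability
#' `P = (1/2) * (1 - exp(-dx / L))` (with `dx` the genetic distance to the
#' previous QTL) governs the transition: under `coupling` it is the
#' probability that the sign *changes*, under `repulsion` the probability
#' that it *stays*. As `dx` grows or `L -> 0`, `P -> 1/2` and signs become
#' independent; `mode = "random"` assigns independent uniform signs.
#'
#' @param qtl_genetic list (per chromosome) of sorted QTL genetic positions
#'   (cM) -- conventionally on the normal map, so the founder phase is a
#'   property of the founders, shared by all landscape scenarios.
#' @param mode `"random"`, `"coupling"` or `"repulsion"`.
#' @param L characteristic genetic distance in cM (default 5).
#' @return list (per chromosome) of signs (+1/-1) for the founder-P1 allele.
#' @export
assign_phase <- function(qtl_genetic, mode = c("random", "coupling", "repulsion"),
                         L = 5) {
  mode <- match.arg(mode)
  lapply(qtl_genetic, function(pos) {
    n <- length(pos)
    if (n == 0L) return(integer(0))
    if (mode == "random") {
      return(sample(c(-1L, 1L), n, replace = TRUE))
    }
    dx <- diff(pos)
    if (any(dx < 0)) stop("unsorted input: QTL genetic positions must be sorted")
    P <- 0.5 * (1 - exp(-dx / L))
    s <- integer(n)
    s[1L] <- sample(c(-1L, 1L), 1L)
    flip <- if (mode == "coupling") runif(n - 1L) < P else runif(n - 1L) >= P
    for (i in seq_len(n - 1L)) {
      s[i + 1L] <- if (flip[i]) -s[i] else s[i]
    }
    s
  })
}

# deterministic phase walk given the uniforms: the same draws applied to
# different genetic coordinates yield maximally paired sign vectors
phase_walk <- function(pos, mode, L, u_first, u_steps) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  s <- integer(n)
  s[1L] <- if (u_first < 0.5) -1L else 1L
  if (n == 1L) return(s)
  P <- 0.5 * (1 - exp(-diff(pos) / L))
  flip <- if (mode == "coupling") u_steps < P else u_steps >= P
  for (i in seq_len(n - 1L)) s[i + 1L] <- if (flip[i]) -s[i] else s[i]
  s
}

#' Build a trait architecture shared across landscape scenarios
#'
#' Samples QTL physical positions among genes, draws gamma amplitudes, and
#' converts the (shared) physical positions to per-scenario genetic
#' positions. Physical positions and amplitudes are identical across
#' scenarios within one call. Under `phase_mode = "random"` the founder
#' signs are also identical across scenarios. Under coupling or repulsion,
#' the sign-transition probability depends on the genetic distance between
#' adjacent QTL, which differs between landscapes: the phase walk is
#' therefore run on each scenario's own genetic coordinates, reusing one
#' set of uniform draws per replicate so that scenarios remain maximally
#' paired (an expanded map weakens the founder phase exactly where the
#' transition probability crosses the shared draw).
#'
#' @param genome a `genome_spec`.
#' @param gene_positions list (per chromosome) of gene physical positions.
#' @param n_qtl_per_chrom QTL per chromosome.
#' @param phase_mode `"random"`, `"coupling"` or `"repulsion"`.
#' @param L coupling/repulsion characteristic length (cM).
#' @param k,theta gamma amplitude parameters.
#' @return object of class `trait_model`: `qtl_physical`, `amplitude`
#'   (per-chromosome lists), and per-scenario `qtl_genetic[[scenario]]`,
#'   `sign_P1[[scenario]]` per-chromosome lists.
#' @export
make_trait_model <- function(genome, gene_positions, n_qtl_per_chrom = 200L,
                             phase_mode = "random", L = 5,
                             k = 0.4, theta = 1.58) {
  stopifnot(inherits(genome, "genome_spec"),
            phase_mode %in% c("random", "coupling", "repulsion"))
  qtl_phys <- sample_qtl(gene_positions, n_qtl_per_chrom)
  amplitude <- lapply(qtl_phys, function(p) draw_amplitudes(length(p), k, theta))
  qtl_gen <- lapply(genome$landscapes, function(land) {
    lapply(seq_along(qtl_phys), function(c) {
      physical_to_genetic(land$maps[[c]], qtl_phys[[c]])
    })
  })
  if (phase_mode == "random") {
    signs <- lapply(qtl_phys, function(p) sample(c(-1L, 1L), length(p),
                                                 replace = TRUE))
    sign_P1 <- lapply(qtl_gen, function(g) signs)
  } else {
    draws <- lapply(qtl_phys, function(p) {
      list(first = runif(1), steps = runif(max(length(p) - 1L, 0L)))
    })
    sign_P1 <- lapply(qtl_gen, function(gen_by_chrom) {
      lapply(seq_along(gen_by_chrom), function(c) {
        phase_walk(gen_by_chrom[[c]], phase_mode, L,
                   draws[[c]]$first, draws[[c]]$steps)
      })
    })
  }
  structure(
    list(qtl_physical = qtl_phys, amplitude = amplitude, sign_P1 = sign_P1,
         qtl_genetic = qtl_gen, phase_mode = phase_mode),
    class = "trait_model"
  )
}

#' Total gain ceiling of a trait
#'
#' Sum of QTL amplitudes: the genotypic value of an individual homozygous
#' for the favorable allele at every QTL.
#'
#' @param trait a `trait_model`.
#' @return scalar, trait units.
#' @export
trait_ceiling <- function(trait) {
  sum(unlist(trait$amplitude))
}

#' Read gene physical positions from a GFF3 annotation
#'
#' Extracts features of type `gene` and returns their start positions in Mb
#' per chromosome (1-based inclusive GFF coordinates converted to the
#' internal 0-based Mb convention). Requires the rtracklayer package.
#'
#' @param path GFF3 file path.
#' @param chrom_ids optional character vector restricting and ordering the
#'   chromosomes.
#' @return named list (per chromosome) of sorted positions in Mb.
#' @export
read_gff_genes <- function(path, chrom_ids = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff_genes() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3", feature.type = "gene")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- (GenomicRanges::start(gr) - 1) / 1e6
  if (is.null(chrom_ids)) chrom_ids <- unique(chroms)
  out <- lapply(chrom_ids, function(id) sort(starts[chroms == id]))
  names(out) <- chrom_ids
  out
}
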