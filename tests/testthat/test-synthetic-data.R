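# Synthetic genome generator: landscapes, genes, QTL architectures.

test_that("generated landscapes match the preset totals", {
  gb <- gen_landscape(synthetic_genome_config("brapa"))
  expect_equal(gb$n_chrom, 10)
  expect_equal(sum(gb$landscapes$normal$GL), 821.7, tolerance = 1e-8)
  expect_equal(sum(gb$landscapes$boosted$GL), 2774.8, tolerance = 1e-6)
  expect_equal(sum(gb$landscapes$hyperrec$GL), 2774.8, tolerance = 1e-6)

  go <- gen_landscape(synthetic_genome_config("osativa"))
  expect_equal(go$n_chrom, 12)
  expect_equal(sum(go$landscapes$normal$GL), 1758.54, tolerance = 1e-8)
  # sum of the per-chromosome increased lengths (average ~475 cM/chromosome)
  expect_equal(sum(go$landscapes$boosted$GL), 5699.87, tolerance = 1e-6)
})

test_that("without a cold region the two transforms coincide", {
  g <- uniform_genome(n_chrom = 1L, GL = 100, GL_inc = 250)
  hr <- g$genome$landscapes$hyperrec$maps[[1]]
  bo <- g$genome$landscapes$boosted$maps[[1]]
  expect_lt(max(abs(hr$gen - bo$gen)), 1e-6)
})

test_that("gene density follows the pericentromere mixture", {
  cfg <- synthetic_genome_config(
    "brapa", GL_normal = 100, GL_increased = 300, PL = 40,
    gene_density_cold_frac = 0.3, genes_per_chrom = 10000L,
    nu_normal = NULL, nu_boosted = NULL, seed = 21L)
  genes <- gen_gene_positions(cfg)[[1]]
  inside <- genes >= 0.3 * 40 & genes < 0.7 * 40
  # mixture weight 0.3 * 0.4 / (0.3 * 0.4 + 0.6)
  p <- 0.12 / 0.72
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(inside) - p), 4 * se)

  cfg0 <- synthetic_genome_config(
    "brapa", GL_normal = 100, GL_increased = 300, PL = 40,
    gene_density_cold_frac = 0, genes_per_chrom = 5000L,
    nu_normal = NULL, nu_boosted = NULL, seed = 22L)
  g0 <- gen_gene_positions(cfg0)[[1]]
  expect_equal(sum(g0 >= 12 & g0 < 28), 0)

  cfg1 <- synthetic_genome_config(
    "brapa", GL_normal = 100, GL_increased = 300, PL = 40,
    gene_density_cold_frac = 1, genes_per_chrom = 10000L,
    nu_normal = NULL, nu_boosted = NULL, seed = 23L)
  g1 <- gen_gene_positions(cfg1)[[1]]
  expect_gt(suppressWarnings(ks.test(g1 / 40, "punif")$p.value), 0.01)
})

test_that("QTL are sampled among genes without replacement, tracking density", {
  set.seed(41)
  g <- uniform_genome(genes_per_chrom = 50L)
  all_qtl <- sample_qtl(g$genes, 50L)
  expect_equal(all_qtl, lapply(g$genes, sort))
  expect_error(sample_qtl(g$genes, 51L), "insufficient genes")

  sub <- sample_qtl(g$genes, 10L)
  expect_true(all(vapply(seq_along(sub), function(c) {
    all(sub[[c]] %in% g$genes[[c]]) && !anyDuplicated(sub[[c]])
  }, logical(1))))

  # over many draws the empirical QTL density matches gene density
  # (multinomial over 20 physical bins, chi-square oracle)
  cfg <- synthetic_genome_config(
    "brapa", GL_normal = 100, GL_increased = 300, PL = 40,
    gene_density_cold_frac = 0.3, genes_per_chrom = 2000L,
    nu_normal = NULL, nu_boosted = NULL, seed = 77L)
  genes <- gen_gene_positions(cfg)
  draws <- unlist(replicate(500, sample_qtl(genes, 20L)[[1]]))
  bins <- seq(0, 40, length.out = 21)
  obs <- table(cut(draws, bins))
  expected_p <- as.vector(table(cut(genes[[1]], bins))) / length(genes[[1]])
  expect_gt(suppressWarnings(chisq.test(obs, p = expected_p)$p.value), 0.01)
})

test_that("QTL amplitudes follow the gamma(0.4, 1.58) law", {
  expect_equal(0.4 * 1.58^2, 1, tolerance = 0.01) # amplitude variance ~ 1
  set.seed(8)
  a <- draw_amplitudes(1e6)
  expect_true(all(a > 0))
  expect_equal(mean(a), 0.4 * 1.58, tolerance = 0.005)
  expect_equal(var(a), 0.4 * 1.58^2, tolerance = 0.01)
})

test_that("coupling/repulsion phase assignment obeys the distance rule", {
  # co-located QTL: P = 0, deterministic transitions
  set.seed(91)
  pos0 <- list(c(10, 10, 10, 10))
  expect_length(unique(assign_phase(pos0, "coupling")[[1]]), 1L)
  expect_equal(abs(diff(assign_phase(pos0, "repulsion")[[1]])),
               rep(2L, 3L))

  # L -> Inf: coupling gives one sign per chromosome, repulsion alternates
  pos <- list(sort(runif(30, 0, 100)), sort(runif(30, 0, 100)))
  cp <- assign_phase(pos, "coupling", L = 1e12)
  expect_true(all(vapply(cp, function(s) length(unique(s)) == 1L,
                         logical(1))))
  rp <- assign_phase(pos, "repulsion", L = 1e12)
  expect_true(all(vapply(rp, function(s) all(abs(diff(s)) == 2L),
                         logical(1))))

  # dx = 5, L = 5: sign-change probability (1/2)(1 - e^-1) ~ 0.3161
  set.seed(92)
  n <- 20000
  flips <- vapply(seq_len(n), function(i) {
    s <- assign_phase(list(c(0, 5)), "coupling", L = 5)[[1]]
    s[1] != s[2]
  }, logical(1))
  p_hat <- mean(flips)
  p_true <- 0.5 * (1 - exp(-1))
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / n))

  expect_error(assign_phase(list(c(5, 1)), "coupling"), "unsorted")
})

test_that("trait architecture is shared across scenarios within a replicate", {
  g <- uniform_genome()
  set.seed(3)
  tr <- make_trait_model(g$genome, g$genes, 20L)
  expect_identical(tr$qtl_physical, lapply(tr$qtl_physical, sort))
  # same physical positions, amplitudes; genetic positions scale
  expect_length(tr$qtl_genetic, 3L)
  expect_equal(tr$qtl_genetic$hyperrec[[1]],
               tr$qtl_genetic$normal[[1]] * 3, tolerance = 1e-6)
  expect_true(all(unlist(tr$amplitude) > 0))
  expect_true(all(unlist(tr$sign_P1) %in% c(-1L, 1L)))
  # random phase: founder signs identical in every scenario
  expect_identical(tr$sign_P1$normal, tr$sign_P1$boosted)
  expect_identical(tr$sign_P1$normal, tr$sign_P1$hyperrec)
  expect_equal(trait_ceiling(tr), sum(unlist(tr$amplitude)))

  # coupling: the walk shares its draws but runs on each scenario's map,
  # so an expanded map can only weaken the phase, never rearrange it
  # arbitrarily; the first sign is always shared
  set.seed(4)
  trc <- make_trait_model(g$genome, g$genes, 20L, phase_mode = "coupling")
  firsts <- function(sg) vapply(sg, `[`, integer(1), 1L)
  expect_identical(firsts(trc$sign_P1$normal), firsts(trc$sign_P1$boosted))
  # tighter map (normal) has at least as many same-sign adjacent pairs
  runs <- function(sg) sum(vapply(sg, function(s) sum(diff(s) == 0L),
                                  integer(1)))
  expect_gte(runs(trc$sign_P1$normal), runs(trc$sign_P1$boosted))
})

test_that("F2 genetic variance matches the closed form n_QTL*k*theta^2*(1+k)/2", {
  g <- uniform_genome()
  land <- g$genome$landscapes$normal
  set.seed(13)
  n_rep <- 40L
  vars <- vapply(seq_len(n_rep), function(r) {
    tr <- make_trait_model(g$genome, g$genes, 50L) # 100 QTL genome-wide
    f2 <- self(f1_pop(land), land, n = 250L)
    var(genotypic_value(f2, tr, "normal"))
  }, numeric(1))
  expected <- 100 * 0.4 * 1.58^2 * 1.4 / 2 # ~ 69.9
  se <- sd(vars) / sqrt(n_rep)
  expect_lt(abs(mean(vars) - expected), 3 * se)
})

test_that("genome config YAML reader mirrors the constructor", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("species: brapa",
               "GL_normal: [50, 60]", "GL_increased: [150, 180]",
               "PL: 30", "cold_rate_frac: 0.05",
               "genes_per_chrom: 100", "seed: 4"), yml)
  cfg <- read_genome_config(yml)
  expect_s3_class(cfg, "syn_genome_config")
  expect_equal(cfg$GL_normal, c(50, 60))
  expect_equal(cfg$PL, c(30, 30))
  genome <- gen_landscape(cfg)
  expect_equal(sum(genome$landscapes$normal$GL), 110, tolerance = 1e-8)
})

test_that("GFF3 gene reader extracts positions in Mb", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1000001\t1005000\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t1000001\t1005000\t.\t+\t.\tID=m1;Parent=g1",
    "c1\tsrc\tgene\t2500001\t2501000\t.\t-\t.\tID=g2",
    "c2\tsrc\tgene\t500001\t501000\t.\t+\t.\tID=g3"), gff)
  genes <- read_gff_genes(gff)
  expect_named(genes, c("c1", "c2"))
  expect_equal(genes$c1, c(1.0, 2.5))
  expect_equal(genes$c2, 0.5)
})
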