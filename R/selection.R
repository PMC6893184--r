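# Quantitative-genetics layer and recurrent-selection schemes.

#' Scheme configuration
#'
#' Defaults are the reference design: 250 individuals, 5 selected (2%
#' selection pressure), 20 generations, genomic selection with RR-BLUP
#' recalibrated every fourth generation, heritability 0.5 (defined on the
#' first selected population), no crossover interference.
#'
#' @param scheme `"Fn"` (selection on heterozygous populations) or `"DH"`
#'   (alternating doubled-haploid panels and crossing generations).
#' @param pop_size population size per generation.
#' @param n_selected number of individuals kept by truncation selection.
#' @param n_generations last generation index (populations run g = 2 ..
#'   `n_generations`; g = 0, 1 are the founders and F1).
#' @param selection_mode `"genomic"` (GEBV) or `"phenotypic"`.
#' @param h2 trait heritability in (0, 1], defined in the g = 2 population.
#' @param recalibration `"every_4"`, `"every_2"` or `"F2_only"`: generations
#'   at which marker effects are (re)estimated.
#' @param markers_per_chrom neutral markers per chromosome used for genomic
#'   selection (1000 in the reference design; they can be thinned without
#'   materially changing gains).
#' @param interference use the gamma interference model with the landscape's
#'   per-chromosome `nu` values instead of the Haldane model.
#' @param allow_selfing allow an individual to be drawn as both parents of
#'   an offspring during random mating among the selected set.
#' @return list of class `scheme_config`.
#' @export
scheme_config <- function(scheme = c("Fn", "DH"), pop_size = 250L,
                          n_selected = 5L, n_generations = 20L,
                          selection_mode = c("genomic", "phenotypic"),
                          h2 = 0.5,
                          recalibration = c("every_4", "F2_only", "every_2"),
                          markers_per_chrom = 1000L,
                          interference = FALSE, allow_selfing = FALSE) {
  scheme <- match.arg(scheme)
  selection_mode <- match.arg(selection_mode)
  recalibration <- match.arg(recalibration)
  stopifnot(n_selected <= pop_size, n_selected >= 1L, n_generations >= 2L,
            h2 > 0, h2 <= 1)
  structure(
    list(scheme = scheme, pop_size = as.integer(pop_size),
         n_selected = as.integer(n_selected),
         n_generations = as.integer(n_generations),
         selection_mode = selection_mode, h2 = h2,
         recalibration = recalibration,
         markers_per_chrom = as.integer(markers_per_chrom),
         interference = interference, allow_selfing = allow_selfing),
    class = "scheme_config"
  )
}

# generations at which the genomic model is (re)trained
training_generations <- function(config) {
  switch(config$recalibration,
         F2_only = 2L,
         every_2 = seq(2L, config$n_generations, by = 2L),
         every_4 = seq(2L, config$n_generations, by = 4L))
}

# per-chromosome founder-P1 allelic effects (sign * amplitude / 2) and
# genetic positions for one scenario
trait_effects <- function(trait, scenario) {
  sg <- trait$sign_P1[[scenario]]
  list(pos = trait$qtl_genetic[[scenario]],
       eff = lapply(seq_along(trait$amplitude), function(c) {
         sg[[c]] * trait$amplitude[[c]] / 2
       }))
}

#' Genotypic values of a population
#'
#' Purely additive: the sum over QTL of the two carried allelic effects,
#' each allele contributing plus or minus half the QTL amplitude.
#'
#' @param pop an `rs_pop`.
#' @param trait a `trait_model`.
#' @param scenario landscape scenario whose genetic coordinates `pop` lives
#'   in (`"normal"`, `"hyperrec"` or `"boosted"`).
#' @return numeric vector, one genotypic value per individual.
#' @export
genotypic_value <- function(pop, trait, scenario = "normal") {
  te <- trait_effects(trait, scenario)
  D <- query_dosage(pop, te$pos)
  G <- numeric(pop$n)
  for (c in seq_along(D)) {
    G <- G + colSums(te$eff[[c]] * (2 - 2 * D[[c]]))
  }
  G
}

# genotypic values + count of fixed QTL from one dosage pass
trait_stats <- function(pop, te) {
  G <- numeric(pop$n)
  n_fixed <- 0L
  two_n <- 2L * pop$n
  for (c in seq_along(te$pos)) {
    D <- dosage_mat(pop, te$pos[[c]], c)        # loci x individuals
    G <- G + as.vector(crossprod(2 - 2 * D, te$eff[[c]]))
    s <- rowSums(D)
    n_fixed <- n_fixed + sum(s == 0L | s == two_n)
  }
  list(G = G, n_fixed = n_fixed)
}

#' Calibrate the environmental variance from the first selected population
#'
#' `V_E = var(G) * (1 - h2) / h2`, computed once in the g = 2 population and
#' then held fixed: later populations have different genetic variances and
#' therefore different realized heritabilities.
#'
#' @param f2_values genotypic values of the g = 2 population.
#' @param h2 target heritability in (0, 1].
#' @return list of class `trait_state` with `V_G_F2`, `V_E`, `h2`.
#' @export
calibrate_VE <- function(f2_values, h2) {
  stopifnot(length(f2_values) >= 2, h2 > 0, h2 <= 1)
  V_G <- var(f2_values)
  if (h2 < 1 && V_G <= 0) {
    stop("degenerate trait: zero genetic variance with h2 < 1")
  }
  structure(list(V_G_F2 = V_G, V_E = V_G * (1 - h2) / h2, h2 = h2),
            class = "trait_state")
}

#' Phenotypes: genotypic value plus normal environmental noise
#'
#' @param G genotypic values.
#' @param state a `trait_state` (from [calibrate_VE()]).
#' @return numeric vector `G + N(0, V_E)`.
#' @export
phenotype <- function(G, state) {
  if (state$V_E == 0) return(G)
  G + rnorm(length(G), 0, sqrt(state$V_E))
}

#' Genotype matrix at neutral markers
#'
#' One row per individual, one column per marker, coded -1 (homozygous for
#' the founder-P1 allele), +1 (homozygous P2), 0 (heterozygous).
#'
#' @param pop an `rs_pop`.
#' @param markers list (per chromosome) of marker genetic positions (cM).
#' @return integer matrix, individuals x markers.
#' @export
genotype_matrix <- function(pop, markers) {
  t(do.call(rbind, lapply(seq_along(markers), function(c) {
    dosage_mat(pop, markers[[c]], c)
  }))) - 1L
}

#' Fit an RR-BLUP genomic selection model
#'
#' Mixed model `Y = X beta + Z u + e` with `X` a column of ones, marker
#' effects `u ~ N(0, sigma_u^2 I)` and residuals `e ~ N(0, sigma_e^2 I)`.
#' The variance ratio `lambda = sigma_e^2 / sigma_u^2` is estimated by
#' restricted maximum likelihood through the spectral decomposition of the
#' marker covariance `Z Z'` projected orthogonally to the intercept; `beta`
#' and `u` are then the BLUE/BLUP solutions of the mixed-model equations at
#' the REML ratio. Monomorphic marker columns are permitted (their effects
#' shrink to zero).
#'
#' @param y phenotypes (length N >= 2, non-constant).
#' @param Z genotype matrix (N x n_markers) coded as in
#'   [genotype_matrix()].
#' @param trained_at generation index recorded in the model.
#' @return object of class `gs_model`: `beta`, `u`, `lambda`, `sigma_u2`,
#'   `sigma_e2`, `fitted`, `trained_at`, `n_markers`.
#' @export
fit_rrblup <- function(y, Z, trained_at = NA_integer_) {
  n <- length(y)
  stopifnot(n >= 2L, nrow(Z) == n)
  if (var(y) < .Machine$double.eps * 100) {
    stop("degenerate fit: phenotypes are constant")
  }
  K <- tcrossprod(Z)                      # N x N marker covariance
  Tm <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  Ks <- crossprod(Tm, K %*% Tm)
  eig <- eigen(Ks, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  eta <- as.vector(crossprod(eig$vectors, crossprod(Tm, y)))
  m <- n - 1L
  negll <- function(loglam) {
    dl <- d + exp(loglam)
    m * log(sum(eta^2 / dl)) + sum(log(dl))
  }
  opt <- optimize(negll, c(-25, 25), tol = 1e-8)
  # floor keeps the mixed-model solve well conditioned in the noiseless limit
  lam <- max(exp(opt$minimum), 1e-8 * (sum(diag(K)) / n + 1))
  sigma_u2 <- sum(eta^2 / (d + lam)) / m
  sigma_e2 <- lam * sigma_u2
  a <- solve(K + diag(lam, n), cbind(y, 1))
  beta <- sum(a[, 1L]) / sum(a[, 2L])
  w <- a[, 1L] - beta * a[, 2L]           # (K + lam I)^-1 (y - beta)
  u <- as.vector(crossprod(Z, w))
  structure(
    list(beta = beta, u = u, lambda = lam, sigma_u2 = sigma_u2,
         sigma_e2 = sigma_e2, fitted = as.vector(beta + K %*% w),
         trained_at = trained_at, n_markers = ncol(Z)),
    class = "gs_model"
  )
}

#' Genomic estimated breeding values
#'
#' `GEBV = beta + Z_g u` for a generation's genotype matrix `Z_g` on the
#' marker panel the model was trained on.
#'
#' @param model a `gs_model`.
#' @param Z genotype matrix of the target generation.
#' @return numeric vector of GEBVs.
#' @export
gebv <- function(model, Z) {
  if (ncol(Z) != model$n_markers) {
    stop("marker panel mismatch: model has ", model$n_markers,
         " markers, genotype matrix has ", ncol(Z))
  }
  as.vector(model$beta + Z %*% model$u)
}

#' Truncation selection
#'
#' Indices of the `n_keep` largest values; ties are broken uniformly at
#' random among tied candidates.
#'
#' @param values breeding values (phenotypes or GEBVs).
#' @param n_keep number of individuals to keep.
#' @return integer vector of selected indices.
#' @export
truncation_select <- function(values, n_keep) {
  stopifnot(n_keep <= length(values))
  order(values, sample.int(length(values)), decreasing = TRUE)[seq_len(n_keep)]
}

# ordered parent pairs drawn uniformly from the selected set; selfing
# excluded unless allowed (or unavoidable with a single selected parent)
sample_mating_pairs <- function(sel, n_offspring, allow_selfing = FALSE) {
  k <- length(sel)
  mothers <- sel[sample.int(k, n_offspring, replace = TRUE)]
  fathers <- sel[sample.int(k, n_offspring, replace = TRUE)]
  if (!allow_selfing && k > 1L) {
    clash <- which(mothers == fathers)
    while (length(clash) > 0L) {
      fathers[clash] <- sel[sample.int(k, length(clash), replace = TRUE)]
      clash <- clash[mothers[clash] == fathers[clash]]
    }
  }
  list(mothers = mothers, fathers = fathers)
}

# strip nu when interference is off so reproduction uses the Haldane model
landscape_for_run <- function(landscape, config) {
  if (!config$interference) {
    landscape$nu <- NULL
  } else if (is.null(landscape$nu)) {
    stop("interference requested but the '", landscape$scenario,
         "' landscape carries no nu values")
  } else if (any(landscape$nu < 1)) {
    stop("invalid interference parameter: nu must be >= 1")
  }
  landscape
}

# shared per-generation selection criterion logic; environment-mutating
# pieces are kept explicit by returning the (possibly retrained) model
selection_criterion <- function(config, g, G, pop, markers, state, model) {
  trained <- FALSE
  if (config$selection_mode == "phenotypic") {
    crit <- phenotype(G, state)
  } else {
    Z <- genotype_matrix(pop, markers)
    if (g %in% training_generations(config)) {
      y <- phenotype(G, state)
      model <- fit_rrblup(y, Z, trained_at = g)
      trained <- TRUE
      crit <- model$fitted
    } else {
      crit <- gebv(model, Z)
    }
  }
  list(crit = crit, model = model, trained = trained)
}

new_trajectory <- function(rows, scenario, scheme) {
  traj <- do.call(rbind, rows)
  traj$scenario <- scenario
  traj$scheme <- scheme
  class(traj) <- c("rs_trajectory", "data.frame")
  traj
}

#' Run the Fn recurrent-selection scheme
#'
#' Founders P1 and P2 (g = 0) are crossed to an F1 (g = 1), which is selfed
#' to a population of `pop_size` F2 individuals (g = 2). Each later
#' generation applies truncation selection on the configured breeding value
#' followed by random mating among the selected individuals (ordered pairs
#' of distinct parents) producing `pop_size` offspring.
#'
#' @param config a `scheme_config` with `scheme = "Fn"`.
#' @param landscape a `recombination_landscape`.
#' @param trait a `trait_model` built on the same genome.
#' @return a `rs_trajectory` data.frame with one row per generation
#'   (g = 2 .. `n_generations`): `generation`, `mean_G`, `var_G`, `gain`,
#'   `n_fixed_qtl`, `gs_trained`, `scenario`, `scheme`.
#' @export
run_fn_scheme <- function(config, landscape, trait) {
  stopifnot(config$scheme == "Fn")
  land <- landscape_for_run(landscape, config)
  te <- trait_effects(trait, landscape$scenario)
  markers <- lapply(land$GL, place_neutral_markers,
                    n = config$markers_per_chrom)
  N <- config$pop_size

  f1 <- f1_pop(land)
  pop <- reproduce_pop(f1, rep(1L, N), rep(1L, N), land)  # selfing the F1
  st <- trait_stats(pop, te)
  state <- calibrate_VE(st$G, config$h2)
  model <- NULL
  mean_g2 <- mean(st$G)

  rows <- vector("list", config$n_generations - 1L)
  for (g in 2:config$n_generations) {
    trained_now <- FALSE
    if (g < config$n_generations) {
      selres <- selection_criterion(config, g, st$G, pop, markers, state,
                                    model)
      model <- selres$model
      trained_now <- selres$trained
      sel <- truncation_select(selres$crit, config$n_selected)
      pairs <- sample_mating_pairs(sel, N, config$allow_selfing)
      new_pop_ <- reproduce_pop(pop, pairs$mothers, pairs$fathers, land)
    }
    rows[[g - 1L]] <- data.frame(
      generation = g, mean_G = mean(st$G), var_G = var(st$G),
      gain = mean(st$G) - mean_g2, n_fixed_qtl = st$n_fixed,
      gs_trained = as.integer(trained_now))
    if (g < config$n_generations) {
      pop <- new_pop_
      st <- trait_stats(pop, te)
    }
  }
  new_trajectory(rows, landscape$scenario, "Fn")
}

#' Run the doubled-haploid recurrent-selection scheme
#'
#' The F1 produces `pop_size` doubled haploids (g = 2). At each even
#' (homozygous DH) generation the best `n_selected` individuals are selected
#' and crossed at random (ordered pairs of distinct parents) to produce
#' `pop_size` heterozygotes (odd generations); each heterozygote then yields
#' exactly one DH. Selection and, under genomic selection, model training
#' happen on the homozygous panels only.
#'
#' @inheritParams run_fn_scheme
#' @return a `rs_trajectory` (see [run_fn_scheme()]).
#' @export
run_dh_scheme <- function(config, landscape, trait) {
  stopifnot(config$scheme == "DH")
  land <- landscape_for_run(landscape, config)
  te <- trait_effects(trait, landscape$scenario)
  markers <- lapply(land$GL, place_neutral_markers,
                    n = config$markers_per_chrom)
  N <- config$pop_size

  f1 <- f1_pop(land)
  pop <- make_dh(f1, land, idx = rep(1L, N))
  st <- trait_stats(pop, te)
  state <- calibrate_VE(st$G, config$h2)
  model <- NULL
  mean_g2 <- mean(st$G)

  rows <- vector("list", config$n_generations - 1L)
  for (g in 2:config$n_generations) {
    trained_now <- FALSE
    if (g < config$n_generations) {
      if (g %% 2L == 0L) {
        selres <- selection_criterion(config, g, st$G, pop, markers, state,
                                      model)
        model <- selres$model
        trained_now <- selres$trained
        sel <- truncation_select(selres$crit, config$n_selected)
        pairs <- sample_mating_pairs(sel, N, config$allow_selfing)
        new_pop_ <- reproduce_pop(pop, pairs$mothers, pairs$fathers, land)
      } else {
        new_pop_ <- make_dh(pop, land)
      }
    }
    rows[[g - 1L]] <- data.frame(
      generation = g, mean_G = mean(st$G), var_G = var(st$G),
      gain = mean(st$G) - mean_g2, n_fixed_qtl = st$n_fixed,
      gs_trained = as.integer(trained_now))
    if (g < config$n_generations) {
      pop <- new_pop_
      st <- trait_stats(pop, te)
    }
  }
  new_trajectory(rows, landscape$scenario, "DH")
}

#' Run the configured selection scheme
#'
#' Dispatches to [run_fn_scheme()] or [run_dh_scheme()].
#'
#' @inheritParams run_fn_scheme
#' @export
run_scheme <- function(config, landscape, trait) {
  if (config$scheme == "Fn") run_fn_scheme(config, landscape, trait)
  else run_dh_scheme(config, landscape, trait)
}
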