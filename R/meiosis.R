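# Crossover simulation and gamete formation. Crossovers are generated
# directly in genetic (cM) space at the gamete scale: 1 crossover per 100 cM
# on average, by definition of genetic distance.

#' Crossover positions under the Haldane (no-interference) model
#'
#' The crossover count is Poisson with mean `GL / 100` and positions are
#' i.i.d. uniform on `[0, GL]` -- equivalent to exponential inter-crossover
#' distances with mean 100 cM.
#'
#' @param GL chromosome genetic length in cM (>= 0).
#' @return sorted numeric vector of crossover positions in cM.
#' @export
draw_crossovers_haldane <- function(GL) {
  stopifnot(GL >= 0)
  n <- rpois(1L, GL / 100)
  sort(runif(n, 0, GL))
}

#' Crossover positions under the single-pathway gamma interference model
#'
#' Inter-crossover distances follow a gamma distribution with shape `nu` and
#' mean 100 cM (at the gamete scale). `nu = 1` recovers the Haldane model;
#' larger `nu` makes crossovers repel each other. The renewal process is made
#' stationary by drawing the first position from the equilibrium
#' (length-biased residual) distribution -- a uniform fraction of a
#' gamma(`nu + 1`) interval -- so the marginal crossover density is uniform
#' and the expected count is `GL / 100` for every `nu`.
#'
#' @param GL chromosome genetic length in cM (>= 0).
#' @param nu interference shape parameter (>= 1).
#' @return sorted numeric vector of crossover positions in cM.
#' @export
draw_crossovers_gamma <- function(GL, nu) {
  if (nu < 1) stop("invalid interference parameter: nu must be >= 1")
  stopifnot(GL >= 0)
  b <- draw_xo_batch(1L, GL, nu)
  b$pos
}

# Batched crossover draws for n meioses on one chromosome.
# Returns list(counts, pos) with pos the concatenation of the per-meiosis
# position vectors (sorted within each meiosis for the gamma model;
# unsorted for Haldane -- the C++ merge sorts them).
draw_xo_batch <- function(n, GL, nu = NULL) {
  if (GL <= 0) {
    return(list(counts = integer(n), pos = numeric(0)))
  }
  if (is.null(nu) || identical(nu, 1) || identical(nu, 1L)) {
    counts <- rpois(n, GL / 100)
    return(list(counts = counts, pos = runif(sum(counts), 0, GL)))
  }
  scale <- 100 / nu
  # first event from the stationary residual distribution
  cur <- runif(n) * rgamma(n, shape = nu + 1, scale = scale)
  pos <- vector("list", n)
  active <- which(cur < GL)
  while (length(active) > 0L) {
    for (i in active) pos[[i]] <- c(pos[[i]], cur[i])
    cur[active] <- cur[active] + rgamma(length(active), shape = nu,
                                        scale = scale)
    active <- active[cur[active] < GL]
  }
  counts <- lengths(pos)
  list(counts = counts, pos = unlist(pos, use.names = FALSE))
}

# ---- populations of individuals ------------------------------------------

# A population is a list:
#   n      - number of individuals
#   GL     - per-chromosome genetic lengths (cM)
#   chrom  - per chromosome: list(br = list of 2n numeric breakpoint vectors,
#            start = integer vector of 2n origins at position 0)
# Gametes 2i-1 and 2i belong to individual i (maternal, paternal).

new_pop <- function(GL, br_by_chrom, start_by_chrom) {
  structure(
    list(n = length(start_by_chrom[[1L]]) %/% 2L, GL = GL,
         chrom = lapply(seq_along(GL), function(c) {
           list(br = br_by_chrom[[c]], start = start_by_chrom[[c]])
         })),
    class = "rs_pop"
  )
}

#' @export
print.rs_pop <- function(x, ...) {
  cat(sprintf("<rs_pop: %d individuals, %d chromosomes (%.1f cM total)>\n",
              x$n, length(x$GL), sum(x$GL)))
  invisible(x)
}

#' Founder and F1 populations
#'
#' `founder_pop()` creates fully homozygous founders (origin `0` for P1,
#' `1` for P2); `f1_pop()` creates the P1 x P2 hybrid whose two gametes are
#' intact parental chromosomes.
#'
#' @param landscape a `recombination_landscape` (or anything with a `GL`
#'   field giving per-chromosome genetic lengths).
#' @param origin 0 for founder P1, 1 for P2.
#' @param n number of identical individuals.
#' @return an `rs_pop`.
#' @export
founder_pop <- function(landscape, origin = 0L, n = 1L) {
  GL <- landscape$GL
  br <- lapply(GL, function(g) rep(list(numeric(0)), 2L * n))
  st <- lapply(GL, function(g) rep(as.integer(origin), 2L * n))
  new_pop(GL, br, st)
}

#' @rdname founder_pop
#' @export
f1_pop <- function(landscape, n = 1L) {
  GL <- landscape$GL
  br <- lapply(GL, function(g) rep(list(numeric(0)), 2L * n))
  st <- lapply(GL, function(g) rep(c(0L, 1L), n))
  new_pop(GL, br, st)
}

# Core reproduction: offspring i is formed from one meiosis of
# mothers[i] and one of fathers[i] (indices into pop's individuals).
reproduce_pop <- function(pop, mothers, fathers, landscape) {
  noff <- length(mothers)
  stopifnot(length(fathers) == noff)
  interference <- !is.null(landscape$nu)
  GL <- pop$GL
  br_out <- vector("list", length(GL))
  st_out <- vector("list", length(GL))
  for (c in seq_along(GL)) {
    nu <- if (interference) landscape$nu[c] else NULL
    xo <- draw_xo_batch(2L * noff, GL[c], nu)
    parents <- c(mothers, fathers)
    choice <- sample(c(0L, 1L), 2L * noff, replace = TRUE)
    res <- cpp_meiose_pop(pop$chrom[[c]]$br, pop$chrom[[c]]$start,
                          2L * parents - 1L, 2L * parents,
                          xo$pos, as.integer(xo$counts), choice)
    # meioses 1..noff are maternal gametes, noff+1..2noff paternal;
    # interleave so gametes 2i-1, 2i belong to offspring i
    ord <- as.vector(rbind(seq_len(noff), noff + seq_len(noff)))
    br_out[[c]] <- res$br[ord]
    st_out[[c]] <- res$start[ord]
  }
  new_pop(GL, br_out, st_out)
}

#' Gamete formation, selfing, crossing, doubled haploids
#'
#' `make_gamete()` performs one meiosis of individual `i` of `pop`: per
#' chromosome it draws crossovers (Haldane, or gamma renewal when the
#' landscape carries `nu`), picks a uniformly random starting parental
#' gamete, and alternates between the parent's two gametes at each
#' crossover. `cross()` produces `n` offspring of two (single-individual)
#' parents; `self()` uses two independent meioses of the same parent;
#' `make_dh()` doubles one gamete per individual into a fully homozygous
#' doubled haploid.
#'
#' @param pop an `rs_pop`.
#' @param landscape a `recombination_landscape`.
#' @param i individual index.
#' @return `make_gamete()`: list per chromosome of `list(br, start)`;
#'   the others: an `rs_pop`.
#' @export
make_gamete <- function(pop, landscape, i = 1L) {
  stopifnot(i >= 1L, i <= pop$n)
  interference <- !is.null(landscape$nu)
  lapply(seq_along(pop$GL), function(c) {
    nu <- if (interference) landscape$nu[c] else NULL
    xo <- draw_xo_batch(1L, pop$GL[c], nu)
    res <- cpp_meiose_pop(pop$chrom[[c]]$br, pop$chrom[[c]]$start,
                          2L * i - 1L, 2L * i,
                          xo$pos, as.integer(xo$counts),
                          sample(c(0L, 1L), 1L))
    list(br = res$br[[1L]], start = res$start[1L])
  })
}

#' @rdname make_gamete
#' @param p,p1,p2 single-individual populations (parents).
#' @param n number of offspring.
#' @export
cross <- function(p1, p2, landscape, n = 1L) {
  stopifnot(p1$n == 1L, p2$n == 1L)
  combined <- combine_pops(p1, p2)
  reproduce_pop(combined, rep(1L, n), rep(2L, n), landscape)
}

#' @rdname make_gamete
#' @export
self <- function(p, landscape, n = 1L) {
  stopifnot(p$n == 1L)
  reproduce_pop(p, rep(1L, n), rep(1L, n), landscape)
}

#' @rdname make_gamete
#' @param idx individual indices used for the doubled haploids (one DH per
#'   entry; default one per individual of `pop`).
#' @export
make_dh <- function(pop, landscape, idx = seq_len(pop$n)) {
  noff <- length(idx)
  interference <- !is.null(landscape$nu)
  GL <- pop$GL
  br_out <- vector("list", length(GL))
  st_out <- vector("list", length(GL))
  for (c in seq_along(GL)) {
    nu <- if (interference) landscape$nu[c] else NULL
    xo <- draw_xo_batch(noff, GL[c], nu)
    res <- cpp_meiose_pop(pop$chrom[[c]]$br, pop$chrom[[c]]$start,
                          2L * idx - 1L, 2L * idx,
                          xo$pos, as.integer(xo$counts),
                          sample(c(0L, 1L), noff, replace = TRUE))
    ord <- rep(seq_len(noff), each = 2L)
    br_out[[c]] <- res$br[ord]
    st_out[[c]] <- res$start[ord]
  }
  new_pop(GL, br_out, st_out)
}

# concatenate two populations defined on the same genome
combine_pops <- function(a, b) {
  stopifnot(identical(a$GL, b$GL))
  GL <- a$GL
  br <- lapply(seq_along(GL), function(c) {
    c(a$chrom[[c]]$br, b$chrom[[c]]$br)
  })
  st <- lapply(seq_along(GL), function(c) {
    c(a$chrom[[c]]$start, b$chrom[[c]]$start)
  })
  new_pop(GL, br, st)
}

# subset individuals
subset_pop <- function(pop, idx) {
  g <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  GL <- pop$GL
  br <- lapply(seq_along(GL), function(c) pop$chrom[[c]]$br[g])
  st <- lapply(seq_along(GL), function(c) pop$chrom[[c]]$start[g])
  new_pop(GL, br, st)
}

#' Founder-origin dosages at arbitrary genetic positions
#'
#' For each chromosome, returns the per-individual count (0, 1 or 2) of
#' founder-P2 alleles at each queried genetic position. A locus belongs to
#' the half-open segment `[b, b')` that contains it.
#'
#' @param pop an `rs_pop`.
#' @param positions list (per chromosome) of genetic positions in cM.
#' @return list (per chromosome) of integer matrices, positions x
#'   individuals.
#' @export
query_dosage <- function(pop, positions) {
  lapply(seq_along(pop$GL), function(c) {
    dosage_mat(pop, positions[[c]], c)
  })
}

# positions x individuals dosage matrix for one chromosome (positions must
# be sorted; markers and QTL positions always are)
dosage_mat <- function(pop, pos, c) {
  if (is.unsorted(pos)) pos <- sort(pos)
  cpp_dosage_pop(pop$chrom[[c]]$br, pop$chrom[[c]]$start, pos)
}

# breakpoints/starts of one individual's gametes as a readable data.frame
#' Dump the founder-origin segments of one individual (debug helper)
#'
#' @param pop an `rs_pop`.
#' @param i individual index.
#' @return data.frame with chrom, gamete, segment start/end (cM), origin.
#' @export
segments_of <- function(pop, i = 1L) {
  rows <- list()
  for (c in seq_along(pop$GL)) {
    for (g in 1:2) {
      gi <- 2L * (i - 1L) + g
      br <- pop$chrom[[c]]$br[[gi]]
      st <- pop$chrom[[c]]$start[gi]
      edges <- c(0, br, pop$GL[c])
      seg_origin <- (st + seq_len(length(edges) - 1L) - 1L) %% 2L
      orig <- c("P1", "P2")[seg_origin + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = c, gamete = g, start_cM = edges[-length(edges)],
        end_cM = edges[-1L], origin = orig)
    }
  }
  do.call(rbind, rows)
}
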