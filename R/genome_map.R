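# Marey maps: monotone physical (Mb) -> genetic (cM) interpolants, stored as
# genetic positions on a fixed physical grid so that the additive (boosted)
# transform is exact and the local rate is an auditable finite difference.

GRID_STEP_MB <- 0.1

#' Fit a monotone Marey map from marker positions
#'
#' Fits the relationship between physical position (Mb) and genetic position
#' (cM) on one chromosome. Marker genetic positions are optionally smoothed
#' with a smoothing spline (to remove noise in experimental maps), projected
#' onto the monotone cone by isotonic regression, and linearly interpolated
#' onto a fixed 0.1 Mb grid. The fitted map is anchored so that the first
#' mapped physical position has genetic position 0; its total genetic length
#' `GL` is the fitted value at the last mapped position.
#'
#' @param markers two-column data.frame or matrix: physical position in Mb
#'   (strictly increasing) and genetic position in cM (non-decreasing up to
#'   noise). At least 3 markers.
#' @param chrom chromosome label.
#' @param smooth logical; smooth with [stats::smooth.spline()] before the
#'   isotonic projection. Automatically skipped when there are fewer than 10
#'   markers. Use `FALSE` for noise-free (e.g. synthetic) maps.
#' @param spar smoothing parameter passed to [stats::smooth.spline()].
#' @return an object of class `chrom_map` with fields `chrom`, `grid`
#'   (physical Mb), `gen` (genetic cM at grid points), `GL` (total genetic
#'   length, cM), `PL` (mapped physical span, Mb).
#' @examples
#' m <- fit_map(cbind(c(0, 10, 20), c(0, 10, 20)))
#' physical_to_genetic(m, 5) # 5 cM
#' @export
fit_map <- function(markers, chrom = "chr", smooth = TRUE, spar = 0.1) {
  markers <- as.matrix(markers)
  if (nrow(markers) < 3L) {
    stop("invalid map: need at least 3 markers, got ", nrow(markers))
  }
  phys <- as.numeric(markers[, 1])
  gen <- as.numeric(markers[, 2])
  if (any(diff(phys) <= 0)) {
    stop("invalid map: physical positions must be strictly increasing")
  }
  if (smooth && length(phys) >= 10L) {
    fitted <- predict(smooth.spline(phys, gen, spar = spar), phys)$y
  } else {
    fitted <- gen
  }
  # monotone projection; large decreases in the raw data (beyond what
  # smoothing absorbs) indicate an inconsistent map
  iso <- isoreg(phys, fitted)$yf
  drop_max <- max(c(0, -diff(gen)))
  if (!smooth && drop_max > 1e-8) {
    stop("inconsistent map: genetic positions decrease by ", signif(drop_max, 3),
         " cM and smoothing is disabled")
  }
  grid <- seq(phys[1L], phys[length(phys)], by = GRID_STEP_MB)
  if (grid[length(grid)] < phys[length(phys)]) {
    grid <- c(grid, phys[length(phys)])
  }
  gg <- approx(phys, iso, xout = grid, ties = "ordered")$y
  gg <- cummax(gg - gg[1L])  # anchor at 0; guard fp monotonicity
  structure(
    list(chrom = chrom, grid = grid, gen = gg,
         GL = gg[length(gg)], PL = grid[length(grid)] - grid[1L]),
    class = "chrom_map"
  )
}

#' @export
print.chrom_map <- function(x, ...) {
  cat(sprintf("<chrom_map %s: %.2f Mb mapped, %.2f cM (%.2f cM/Mb avg)>\n",
              x$chrom, x$PL, x$GL, x$GL / x$PL))
  invisible(x)
}

#' Convert physical to genetic positions on a fitted map
#'
#' @param map a `chrom_map`.
#' @param x physical positions in Mb; must lie within the mapped range
#'   (positions outside the range of the genetic map are rejected because the
#'   physical-to-genetic relation is unknown there).
#' @return genetic positions in cM (non-decreasing in `x`).
#' @export
physical_to_genetic <- function(map, x) {
  stopifnot(inherits(map, "chrom_map"))
  rng <- range(map$grid)
  if (any(x < rng[1L] - 1e-9 | x > rng[2L] + 1e-9)) {
    stop("out of range: physical position outside the mapped interval [",
         rng[1L], ", ", rng[2L], "] Mb")
  }
  approx(map$grid, map$gen, xout = pmin(pmax(x, rng[1L]), rng[2L]),
         ties = "ordered")$y
}

#' Additive ("boosted") landscape transform
#'
#' Adds a spatially constant rate `(GL_target - GL) / PL` (cM/Mb) to the
#' local recombination rate everywhere along the chromosome, so that the
#' total genetic length becomes `GL_target`. Formerly crossover-poor regions
#' (rate ~ 0) acquire a positive rate: this emulates the pericentromere
#' warming observed in allotriploid hybrids.
#'
#' @param map a `chrom_map`.
#' @param GL_target new total genetic length in cM; must exceed `map$GL`.
#' @return a new `chrom_map`.
#' @export
make_boosted <- function(map, GL_target) {
  stopifnot(inherits(map, "chrom_map"))
  if (GL_target <= map$GL) {
    stop("invalid target: GL_target (", GL_target,
         ") must exceed the current genetic length (", map$GL, ")")
  }
  add <- (GL_target - map$GL) / map$PL
  gen <- map$gen + add * (map$grid - map$grid[1L])
  structure(
    list(chrom = map$chrom, grid = map$grid, gen = gen,
         GL = gen[length(gen)], PL = map$PL),
    class = "chrom_map"
  )
}

#' Multiplicative ("HyperRec") landscape transform
#'
#' Scales genetic positions by `GL_target / GL`, preserving the shape of the
#' recombination landscape exactly (cold regions stay cold): the profile of
#' the normalized Marey map is unchanged. This emulates global recombination
#' increases from anti-crossover-gene knockouts.
#'
#' @inheritParams make_boosted
#' @return a new `chrom_map`.
#' @export
make_hyperrec <- function(map, GL_target) {
  stopifnot(inherits(map, "chrom_map"))
  if (GL_target <= map$GL) {
    stop("invalid target: GL_target (", GL_target,
         ") must exceed the current genetic length (", map$GL, ")")
  }
  gen <- map$gen * (GL_target / map$GL)
  structure(
    list(chrom = map$chrom, grid = map$grid, gen = gen,
         GL = gen[length(gen)], PL = map$PL),
    class = "chrom_map"
  )
}

#' Equally spaced neutral marker positions
#'
#' Neutral (trait-silent) biallelic markers are placed equally spaced in
#' genetic distance, the spacing being `GL / (n - 1)` so that markers sit at
#' 0, GL/(n-1), ..., GL. The marker count is held constant when the genetic
#' length changes with the landscape.
#'
#' @param GL total genetic length of the chromosome (cM), > 0.
#' @param n number of markers (default 1000), >= 2.
#' @return numeric vector of `n` genetic positions in cM.
#' @export
place_neutral_markers <- function(GL, n = 1000L) {
  if (n < 2L) stop("invalid count: need at least 2 markers")
  stopifnot(GL > 0)
  seq(0, GL, length.out = n)
}

#' Read Marey maps from a TSV file
#'
#' Expects a tab-separated file with header columns `chrom`, `physical_Mb`,
#' `genetic_cM`; one file describes one landscape scenario.
#'
#' @param path file path.
#' @param smooth,spar passed to [fit_map()] (real maps are noisy; smoothing
#'   defaults on).
#' @return named list of `chrom_map`, one per chromosome, in file order.
#' @export
read_marey_map <- function(path, smooth = TRUE, spar = 0.1) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "physical_Mb", "genetic_cM")
  if (!all(need %in% names(d))) {
    stop("marker map file must have columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(d$chrom)
  maps <- lapply(ids, function(id) {
    sub <- d[d$chrom == id, ]
    sub <- sub[order(sub$physical_Mb), ]
    fit_map(cbind(sub$physical_Mb, sub$genetic_cM), chrom = id,
            smooth = smooth, spar = spar)
  })
  names(maps) <- ids
  maps
}

#' Write a fitted landscape to TSV for inspection
#'
#' Emits one row per grid point with the local rate as a finite difference,
#' columns `chrom`, `grid_Mb`, `genetic_cM`, `rate_cM_per_Mb`.
#'
#' @param maps a `chrom_map` or list of them.
#' @param path output file path.
#' @export
write_landscape <- function(maps, path) {
  if (inherits(maps, "chrom_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    rate <- c(diff(m$gen) / diff(m$grid), NA_real_)
    data.frame(chrom = m$chrom, grid_Mb = m$grid, genetic_cM = m$gen,
               rate_cM_per_Mb = rate)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Local recombination rate on the map grid
#'
#' Finite-difference derivative of the Marey map on its physical grid;
#' returned at interval midpoints.
#'
#' @param map a `chrom_map`.
#' @return data.frame with `mid_Mb` and `rate_cM_per_Mb`.
#' @export
map_rate <- function(map) {
  stopifnot(inherits(map, "chrom_map"))
  data.frame(mid_Mb = (map$grid[-1L] + map$grid[-length(map$grid)]) / 2,
             rate_cM_per_Mb = diff(map$gen) / diff(map$grid))
}
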