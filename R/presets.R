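# Species presets: per-chromosome genetic lengths (cM) under normal and
# increased recombination, and gamma-interference nu values estimated in the
# B. rapa diploid (normal) and allotriploid (boosted) hybrids.

#' Genetic-length and interference presets
#'
#' Per-chromosome total genetic lengths (cM) under normal recombination and
#' under the increased-recombination landscapes (the multiplicative HyperRec
#' and additive boosted transforms are constructed to reach the same
#' per-chromosome total), for a 10-chromosome *Brassica rapa*-like genome and
#' a 12-chromosome *Oryza sativa*-like genome. `nu` values (gamma-model
#' interference shape, one per chromosome) are available for the B. rapa
#' preset: `nu_normal` from the diploid, `nu_boosted` from the allotriploid.
#'
#' @param species `"brapa"` or `"osativa"`.
#' @return list with `chrom_ids`, `GL_normal`, `GL_increased`, and (for
#'   `brapa`) `nu_normal`, `nu_boosted`.
#' @export
species_lengths <- function(species = c("brapa", "osativa")) {
  species <- match.arg(species)
  if (species == "brapa") {
    list(
      species = "brapa",
      chrom_ids = sprintf("A%02d", 1:10),
      GL_normal = c(92.9, 78, 102.9, 56.2, 95.4, 105.7, 74.1, 56.8, 103.9,
                    55.8),
      GL_increased = c(265.2, 260.7, 396.3, 206.5, 263.3, 300.9, 318.3,
                       225.8, 394.7, 143.1),
      nu_normal = c(6.97, 6.139, 7.207, 18.576, 12.934, 8.814, 13.001,
                    12.185, 4.895, 63.778),
      nu_boosted = c(1.887, 1.479, 2.392, 1.946, 2.263, 3.084, 1.64, 2.036,
                     2.418, 2.362)
    )
  } else {
    list(
      species = "osativa",
      chrom_ids = sprintf("chr%02d", 1:12),
      GL_normal = c(210.27, 174.83, 156.30, 132.72, 143.97, 172.68, 144.15,
                    128.42, 120.45, 100.87, 137.74, 136.14),
      GL_increased = c(650.68, 504.69, 482.42, 468.98, 435.66, 479.01,
                       429.28, 424.03, 496.54, 372.00, 472.26, 484.32)
    )
  }
}
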