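# The canonical study conditions: a 13-population European-origin cohort
# analogue with a Scandinavian/North-Central/Mediterranean layout, one
# strongly drifted north-eastern outlier population (FIN) and one small
# population (SWE) reserved for held-out assignment experiments.

#' Geographic panel of the default European-style study populations
#'
#' Country-midpoint coordinates for the 13 simulated populations (North
#' Italy is anchored on Verona).
#'
#' @return A [geo_panel()] with 13 rows.
#' @export
study_geo_panel <- function() {
  geo_panel(
    population = c("CZE", "DEU", "ESP", "FIN", "FRA", "GRC", "ITN",
                   "NLD", "NOR", "POL", "ITS", "SWE", "GBR"),
    latitude  = c(49.8, 51.0, 40.0, 64.0, 46.0, 39.0, 45.4,
                  52.2, 61.0, 52.0, 40.9, 62.0, 54.0),
    longitude = c(15.5, 10.0, -4.0, 26.0,  2.0, 22.0, 11.0,
                   5.3,  8.7, 19.0, 14.3, 15.0, -2.0))
}

#' Default study simulation configuration
#'
#' The conditions the package's end-to-end experiments run under: 13
#' European-style populations whose per-population drift parameters,
#' sample sizes and geographic clines were fixed once so that (i)
#' genome-wide pairwise Fst spans roughly 0-0.014 with the FIN analogue as
#' the clear outlier, (ii) geographically close North-Central populations
#' fall below the 0.001 indistinctness threshold, and (iii) a ~1% tail of
#' selection-like clinal loci provides the strongly differentiated
#' markers from which small AIM panels draw their power.  See the methods
#' vignette for the full rationale.
#'
#' @param seed root seed for the simulation.
#' @param n_snps marker count (default 5000; must stay divisible by
#'   `ld_block_size`).
#' @param ld_block_size,ld_flip_prob LD-block structure (defaults: blocks
#'   of 5 with flip probability 0.02, i.e. `r^2 ~ 0.92` to the block lead).
#' @param missing_rate uniform missingness (default 1%).
#' @return A [sim_config()].
#' @export
study_config <- function(seed = 1L, n_snps = 5000L, ld_block_size = 5L,
                         ld_flip_prob = 0.02, missing_rate = 0.01) {
  geo <- study_geo_panel()
  sizes <- c(CZE = 72, DEU = 120, ESP = 110, FIN = 120, FRA = 115,
             GRC = 70, ITN = 110, NLD = 120, NOR = 82, POL = 105,
             ITS = 75, SWE = 39, GBR = 110)
  # Balding-Nichols F per population: North-Central block barely drifted,
  # Mediterranean mildly, FIN strongly (the Table-3-style outlier), SWE in
  # between (and later held out of the reference).
  fst <- c(CZE = 3e-4, DEU = 3e-4, ESP = 1e-3, FIN = 8e-3, FRA = 3e-4,
           GRC = 1e-3, ITN = 1e-3, NLD = 3e-4, NOR = 6e-4, POL = 6e-4,
           ITS = 1e-3, SWE = 2e-3, GBR = 3e-4)
  # Population-private loci in two strength classes: a couple of strong
  # near-private markers per population (the low-mean-MAF marker class
  # single-marker informativeness rewards) plus several moderate ones
  # that give each population a principal-component axis with localized
  # loadings.  GBR gets none, so with its low drift the GBR pairs with
  # the other North-Central populations fall below the 0.001
  # indistinctness threshold (the hub pattern of the cohort this design
  # emulates); FIN gets none either -- the outlier's differentiation is
  # genome-wide drift, which principal components see but single-marker
  # informativeness undervalues.
  pops_priv <- c("ESP", "GRC", "ITN", "ITS", "POL", "NOR", "SWE",
                 "CZE", "DEU", "FRA", "NLD")
  priv <- rbind(
    data.frame(population = pops_priv, n = 2L,
               delta_min = 0.40, delta_max = 0.55),
    data.frame(population = pops_priv, n = 6L,
               delta_min = 0.18, delta_max = 0.32))
  sim_config(n_populations = 13L,
             samples_per_pop = sizes[geo$population],
             n_snps = n_snps,
             fst_per_pop = fst[geo$population],
             cline_strength = c(0.008, 0.008),
             geo = geo,
             ld_block_size = ld_block_size,
             ld_flip_prob = ld_flip_prob,
             missing_rate = missing_rate,
             selection_prop = 0.01,
             selection_gradient = c(0.03, 0.12),
             private_loci = priv,
             private_delta = c(0.40, 0.55),
             private_base = c(0.01, 0.05),
             seed = seed)
}

#' Compact marker-set-contrast configuration
#'
#' A nine-population scenario used for the AIM-versus-PCAIM validation
#' experiments.  One strongly drifted outlier population (FIN analogue)
#' differentiates by genome-wide drift alone -- no private marker tail --
#' so single-marker informativeness undervalues it while its
#' principal-component axis is the strongest in the spectrum.  Six
#' background populations without private tails (two Scandinavian
#' neighbours plus a weakly drifted North-Central block) dilute the
#' outlier's per-population informativeness weight and absorb its
#' nearest-neighbour votes, reproducing the asymmetry between the two
#' marker sets: informativeness-ranked panels misassign the outlier into
#' the background, PCA-weighted panels resolve it.  Two query
#' populations carry private marker tails.  Pairwise Fst stays
#' in the 0-0.014 range.  The small population count keeps each
#' population's axis within the leading components and the
#' nearest-neighbour vote ladder away from fragmentation, so 25-marker
#' panels operate in the regime the larger cohort only reaches at chip
#' scale.
#'
#' @param seed root seed.
#' @param n_snps marker count (default 8000).
#' @return A [sim_config()].
#' @export
contrast_config <- function(seed = 1L, n_snps = 8000L) {
  geo <- geo_panel(
    population = c("FIN", "NOR", "SWE", "CZE", "NLD", "GBR", "POL",
                   "DEU", "ESP"),
    latitude  = c(64.0, 61.0, 62.0, 49.8, 52.2, 54.0, 52.0, 51.0, 40.0),
    longitude = c(26.0,  8.7, 15.0, 15.5,  5.3, -2.0, 19.0, 10.0, -4.0))
  # background population sizes leave at most 10 samples outside the
  # 70-sample reference, so (as in the emulated study's validation rule)
  # they serve as reference background but are not scored as queries;
  # their number dilutes the outlier's per-population informativeness
  # weight the way the cohort's 13 populations did
  sizes <- c(FIN = 120, NOR = 80, SWE = 78, CZE = 80, NLD = 78,
             GBR = 80, POL = 78, DEU = 120, ESP = 115)
  fst <- c(FIN = 1.2e-2, NOR = 6e-4, SWE = 6e-4, CZE = 3e-4, NLD = 3e-4,
           GBR = 3e-4, POL = 6e-4, DEU = 3e-4, ESP = 1e-3)
  pops_priv <- c("DEU", "ESP")
  priv <- rbind(
    data.frame(population = pops_priv, n = 4L,
               delta_min = 0.35, delta_max = 0.50),
    data.frame(population = pops_priv, n = 8L,
               delta_min = 0.20, delta_max = 0.35))
  # no LD blocks here: strong synthetic LD inflates the noise eigenvalue
  # bulk and buries the population axes this scenario is about
  sim_config(n_populations = 9L,
             samples_per_pop = sizes[geo$population],
             n_snps = n_snps,
             fst_per_pop = fst[geo$population],
             cline_strength = c(0.008, 0.008),
             geo = geo,
             ld_block_size = 1L,
             ld_flip_prob = 0,
             missing_rate = 0.01,
             selection_prop = 0.01,
             selection_gradient = c(0.05, 0.15),
             private_loci = priv,
             private_delta = c(0.40, 0.55),
             private_base = c(0.01, 0.05),
             seed = seed)
}

#' Label of the outlier population in the default study design
#' @return `"FIN"`.
#' @export
study_outlier_pop <- function() "FIN"

#' Label of the held-out population in the default study design
#' @return `"SWE"`.
#' @export
study_heldout_pop <- function() "SWE"
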