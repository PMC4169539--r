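# Multi-population genotype simulator: Balding-Nichols differentiation
# around an ancestral frequency, additive geographic clines, optional
# selection-like loci with amplified locus-specific clines, LD blocks by
# copy-with-flip, and uniform missingness.  All randomness flows from one
# root seed through named substreams.

#' Simulation configuration
#'
#' Defines the statistical conditions a simulated cohort is drawn under.
#' Defaults (via [study_config()]) emulate a European-origin GWAS cohort:
#' 13 populations with Table-scale sample sizes, genome-wide pairwise Fst
#' in the 0-0.014 range with one strongly drifted outlier population,
#' latitudinal/longitudinal allele-frequency clines, and a small fraction
#' of selection-like loci carrying much steeper, locus-specific clines.
#'
#' @param n_populations number of populations (>= 2).
#' @param samples_per_pop integer vector of per-population sample counts.
#' @param n_snps number of SNPs; must be divisible by `ld_block_size`.
#' @param fst_per_pop per-population Balding-Nichols parameter F, in (0,1).
#'   The expected pairwise Hudson Fst between populations i and j (without
#'   cline or selection contributions) is `(F_i + F_j) / 2`.
#' @param cline_strength length-2 numeric: frequency shift per 1000 km of
#'   (latitudinal, longitudinal) displacement from the geographic centroid,
#'   applied additively to every SNP.
#' @param geo a [geo_panel()] with one row per population, in the same
#'   order as `samples_per_pop`.
#' @param ld_block_size SNPs per LD block (1 = no LD).  Within a block all
#'   genotypes are copies of the block's first SNP with per-haplotype
#'   allele flips, giving `r^2 ~ (1 - 2 * ld_flip_prob)^2` between a member
#'   and the block source.
#' @param ld_flip_prob per-haplotype flip probability in `[0, 0.5]`.
#' @param missing_rate uniform missing-genotype rate in `[0, 1)`.
#' @param selection_prop fraction of LD blocks whose lead SNP carries a
#'   selection-like amplified cline (locus-specific random bearing);
#'   0 disables.
#' @param selection_gradient length-2 numeric range (per 1000 km) from
#'   which each selection locus draws its cline amplitude.
#' @param selection_bearing length-2 range (degrees from north) for the
#'   per-locus cline bearing; the default `c(-25, 25)` keeps selection
#'   clines predominantly latitudinal, the dominant orientation of the
#'   classic European selection gradients.  Use `c(0, 360)` for isotropic
#'   bearings.
#' @param private_loci population-private loci: markers near-absent
#'   everywhere except one population, where the frequency is elevated.
#'   Either a named integer vector (population -> count, elevation drawn
#'   from `private_delta`) or a data.frame with columns `population`, `n`,
#'   `delta_min`, `delta_max` allowing several strength classes per
#'   population.  These emulate the low-mean-MAF, single-population
#'   markers real ancestry-informative panels are rich in.  `NULL`
#'   disables.
#' @param private_delta length-2 default range for the private-population
#'   frequency elevation (vector form of `private_loci`).
#' @param private_base length-2 range for the background frequency of
#'   private loci.
#' @param seed root integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_populations, samples_per_pop, n_snps, fst_per_pop,
                       cline_strength = c(0, 0), geo = NULL,
                       ld_block_size = 1L, ld_flip_prob = 0,
                       missing_rate = 0, selection_prop = 0,
                       selection_gradient = c(0.05, 0.25),
                       selection_bearing = c(-25, 25),
                       private_loci = NULL, private_delta = c(0.35, 0.55),
                       private_base = c(0.01, 0.05), seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              samples_per_pop = as.integer(samples_per_pop),
              n_snps = as.integer(n_snps),
              fst_per_pop = as.numeric(fst_per_pop),
              cline_strength = as.numeric(cline_strength),
              geo = geo,
              ld_block_size = as.integer(ld_block_size),
              ld_flip_prob = as.numeric(ld_flip_prob),
              missing_rate = as.numeric(missing_rate),
              selection_prop = as.numeric(selection_prop),
              selection_gradient = as.numeric(selection_gradient),
              selection_bearing = as.numeric(selection_bearing),
              private_loci = private_loci,
              private_delta = as.numeric(private_delta),
              private_base = as.numeric(private_base),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_populations < 2L)
    stop("at least 2 populations are required")
  if (length(cfg$samples_per_pop) != cfg$n_populations)
    stop("samples_per_pop must have one entry per population")
  if (length(cfg$fst_per_pop) != cfg$n_populations)
    stop("fst_per_pop must have one entry per population")
  if (any(cfg$fst_per_pop <= 0) || any(cfg$fst_per_pop >= 1))
    stop("fst_per_pop entries must lie strictly in (0, 1)")
  if (length(cfg$cline_strength) != 2L)
    stop("cline_strength must be a (latitudinal, longitudinal) pair")
  if (is.null(cfg$geo))
    stop("a geo panel is required")
  if (!inherits(cfg$geo, "geo_panel") ||
      nrow(cfg$geo) != cfg$n_populations)
    stop("geo must be a geo_panel with one row per population")
  if (cfg$ld_block_size < 1L || cfg$n_snps %% cfg$ld_block_size != 0L)
    stop("n_snps must be divisible by ld_block_size")
  if (cfg$ld_flip_prob < 0 || cfg$ld_flip_prob > 0.5)
    stop("ld_flip_prob must lie in [0, 0.5]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$selection_prop < 0 || cfg$selection_prop > 1)
    stop("selection_prop must lie in [0, 1]")
  if (!is.null(cfg$private_loci)) {
    pl <- .private_spec(cfg)
    if (!all(pl$population %in% cfg$geo$population))
      stop("private_loci must refer to known populations")
  }
  invisible(cfg)
}

# normalize the private-locus spec to a per-locus data.frame
.private_spec <- function(cfg) {
  pl <- cfg$private_loci
  if (is.null(pl)) return(NULL)
  if (is.data.frame(pl)) {
    stopifnot(all(c("population", "n", "delta_min", "delta_max") %in%
                    names(pl)))
  } else {
    if (is.null(names(pl))) stop("private_loci vector must be named")
    pl <- data.frame(population = names(pl), n = as.integer(pl),
                     delta_min = cfg$private_delta[1],
                     delta_max = cfg$private_delta[2],
                     stringsAsFactors = FALSE)
  }
  pl <- pl[pl$n > 0, , drop = FALSE]
  data.frame(population = rep(pl$population, pl$n),
             delta_min = rep(pl$delta_min, pl$n),
             delta_max = rep(pl$delta_max, pl$n),
             stringsAsFactors = FALSE)
}

#' Simulate per-population allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); population frequencies
#' are Balding-Nichols Beta draws around them
#' (`Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`, so `Var(p_i) = F p0 (1-p0)`), then
#' shifted additively by the geographic cline (and, for selection loci, by
#' a locus-specific amplified cline at a random bearing), and clipped to
#' `[0.005, 0.995]` to avoid fixation.  Population-private loci, when
#' configured, are then overwritten with a low background frequency
#' everywhere except the owning population, emulating the near-private
#' low-mean-MAF markers real AIM panels contain.  Deterministic given the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `freq_model`: list with `ancestral_freq`
#'   (length `n_snps`), `pop_freq` (`n_populations x n_snps`),
#'   `selection_idx` (SNP indices of selection-like loci) and `geo_xy`
#'   (local-km population coordinates used for the clines).
#' @export
simulate_frequencies <- function(cfg) {
  validate_sim_config(cfg)
  K <- cfg$n_populations
  m <- cfg$n_snps
  xy <- equirect_xy(cfg$geo)    # km offsets from the panel centroid
  with_seed(derive_seed(cfg$seed, "frequencies"), {
    p0 <- runif(m, 0.05, 0.95)
    FF <- cfg$fst_per_pop
    pf <- matrix(NA_real_, K, m,
                 dimnames = list(cfg$geo$population, NULL))
    for (i in seq_len(K)) {
      pf[i, ] <- rbeta(m, p0 * (1 - FF[i]) / FF[i],
                       (1 - p0) * (1 - FF[i]) / FF[i])
    }
    shift <- (cfg$cline_strength[1] * xy[, "y"] +
              cfg$cline_strength[2] * xy[, "x"]) / 1000
    pf <- pf + shift
    sel_idx <- integer(0)
    if (cfg$selection_prop > 0) {
      # selection loci live on LD-block lead SNPs so the amplified signal
      # survives the block-copy genotype model
      leads <- seq.int(1L, m, by = cfg$ld_block_size)
      n_sel <- round(cfg$selection_prop * length(leads))
      if (n_sel > 0) {
        sel_idx <- sort(sample(leads, n_sel))
        bearing <- runif(n_sel, cfg$selection_bearing[1],
                         cfg$selection_bearing[2]) * pi / 180
        amp <- runif(n_sel, cfg$selection_gradient[1],
                     cfg$selection_gradient[2])
        # projection of each population onto the locus bearing, km -> Mm
        proj <- outer(xy[, "y"], cos(bearing)) + outer(xy[, "x"], sin(bearing))
        pf[, sel_idx] <- pf[, sel_idx] + proj %*% diag(amp, n_sel) / 1000
      }
    }
    priv_idx <- integer(0)
    priv_owner <- character(0)
    spec <- .private_spec(cfg)
    if (!is.null(spec) && nrow(spec)) {
      leads <- seq.int(1L, m, by = cfg$ld_block_size)
      avail <- setdiff(leads, sel_idx)
      n_priv <- nrow(spec)
      if (n_priv > length(avail))
        stop("not enough LD-block leads for the requested private loci")
      ord <- sample(avail, n_priv)
      o <- order(ord)
      priv_idx <- ord[o]
      spec <- spec[o, , drop = FALSE]
      priv_owner <- spec$population
      base <- runif(n_priv, cfg$private_base[1], cfg$private_base[2])
      delta <- spec$delta_min + runif(n_priv) *
        (spec$delta_max - spec$delta_min)
      pf[, priv_idx] <- rep(base, each = K)
      p0[priv_idx] <- base
      own_row <- match(priv_owner, cfg$geo$population)
      pf[cbind(own_row, priv_idx)] <- base + delta
    }
    pf <- pmin(pmax(pf, 0.005), 0.995)
    structure(list(ancestral_freq = p0, pop_freq = pf,
                   selection_idx = sel_idx,
                   private_idx = priv_idx, private_owner = priv_owner,
                   geo_xy = xy),
              class = "freq_model")
  })
}

# draw allele flips on a dosage vector: each of the 2 haplotypes flips
# independently with probability f
.flip_dosages <- function(g, f) {
  if (f <= 0) return(g)
  g - rbinom(length(g), g, f) + rbinom(length(g), 2L - g, f)
}

#' Simulate genotypes from a frequency model
#'
#' Within each LD block a latent `Binomial(2, p)` dosage is drawn once per
#' sample from the block's lead SNP and copied to the other members with
#' independent per-haplotype allele flips (probability `ld_flip_prob`),
#' giving `r^2 ~ (1 - 2 flip)^2` with the lead.  Missing genotypes are then
#' inserted uniformly at `missing_rate`.  Deterministic given the config
#' seed.
#'
#' @param fm a [simulate_frequencies()] result consistent with `cfg`.
#' @param cfg a [sim_config()].
#' @return A [geno_dataset()] with populations labelled from the geo panel
#'   and SNPs laid out on chromosomes 1-22 at 50 kb spacing.
#' @export
simulate_genotypes <- function(fm, cfg) {
  validate_sim_config(cfg)
  stopifnot(inherits(fm, "freq_model"))
  if (ncol(fm$pop_freq) != cfg$n_snps ||
      nrow(fm$pop_freq) != cfg$n_populations)
    stop("frequency model inconsistent with config")
  K <- cfg$n_populations
  m <- cfg$n_snps
  bs <- cfg$ld_block_size
  nb <- m %/% bs
  leads <- seq.int(1L, m, by = bs)
  n_tot <- sum(cfg$samples_per_pop)
  pops <- rep(cfg$geo$population, cfg$samples_per_pop)

  with_seed(derive_seed(cfg$seed, "genotypes"), {
    dos <- matrix(0L, n_tot, m)
    row0 <- 0L
    for (i in seq_len(K)) {
      ni <- cfg$samples_per_pop[i]
      if (ni == 0L) next
      latent <- matrix(rbinom(ni * nb, 2L, rep(fm$pop_freq[i, leads],
                                               each = ni)),
                       ni, nb)
      rows <- row0 + seq_len(ni)
      for (b in seq_len(bs)) {
        cols <- leads + (b - 1L)
        g <- latent
        if (b > 1L) g <- matrix(.flip_dosages(as.integer(latent),
                                              cfg$ld_flip_prob), ni, nb)
        dos[rows, cols] <- g
      }
      # private loci are modelled as young, untagged variants: they do not
      # propagate through their LD block, so the block's other members are
      # redrawn independently from their own frequencies
      if (length(fm$private_idx) && bs > 1L) {
        pb <- match(fm$private_idx, leads)
        pb <- pb[!is.na(pb)]
        for (b in 2L:bs) {
          cols <- leads[pb] + (b - 1L)
          dos[rows, cols] <- matrix(
            rbinom(ni * length(cols), 2L,
                   rep(fm$pop_freq[i, cols], each = ni)),
            ni, length(cols))
        }
      }
      row0 <- row0 + ni
    }
    if (cfg$missing_rate > 0) {
      dos[runif(length(dos)) < cfg$missing_rate] <- NA_integer_
    }
    snps <- .default_snp_map(m, cfg$ld_block_size)
    ids <- sprintf("%s_%04d", pops, stats::ave(seq_len(n_tot), pops,
                                               FUN = seq_along))
    geno_dataset(dos, ids, pops, snps)
  })
}

# SNP map: markers spread over chromosomes 1..22 contiguously, 50 kb
# apart; LD blocks never straddle a chromosome boundary
.default_snp_map <- function(m, block = 1L) {
  nb <- ceiling(m / block)
  blocks_per_chr <- ceiling(nb / 22)
  chr_block <- pmin(22L, 1L + (seq_len(nb) - 1L) %/% blocks_per_chr)
  chr <- as.character(rep(chr_block, each = block, length.out = m))
  within_chr <- stats::ave(seq_len(m), chr, FUN = seq_along)
  data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
             chromosome = chr,
             position_bp = 1L + (within_chr - 1L) * 50000L,
             allele_ref = "A", allele_alt = "G",
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_frequencies()] then
#' [simulate_genotypes()].
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` ([geno_dataset()]), `freq_model` and `geo`.
#' @export
simulate_dataset <- function(cfg) {
  fm <- simulate_frequencies(cfg)
  list(dataset = simulate_genotypes(fm, cfg), freq_model = fm,
       geo = cfg$geo)
}

#' Split a cohort into harmonized reference, test and held-out sets
#'
#' Populations with fewer than `reference_size` samples (or listed in
#' `held_out_pops`) contribute nothing to the reference; every retained
#' population contributes exactly `reference_size` samples drawn at
#' random.  Remaining samples enter the test set only for populations with
#' more than `min_test` samples left over.  Held-out populations appear
#' only in the held-out set.  The three outputs are sample-disjoint.
#'
#' @param ds a [geno_dataset()] with population labels.
#' @param reference_size harmonized per-population reference count.
#' @param min_test a population enters the test set only when more than
#'   this many samples remain outside the reference.
#' @param held_out_pops population labels set aside entirely (e.g. to play
#'   the role of a previously unseen population).
#' @param seed integer seed for the random reference draw.
#' @return list of `geno_dataset`s: `reference`, `test`, `heldout`.
#' @export
make_study_design <- function(ds, reference_size = 70L, min_test = 10L,
                              held_out_pops = character(0), seed = 1L) {
  stopifnot(inherits(ds, "geno_dataset"), reference_size >= 1L)
  pops <- ds$populations
  if (anyNA(pops)) stop("all samples must be labelled")
  tab <- table(pops[!(pops %in% held_out_pops)])
  eligible <- names(tab)[tab >= reference_size]
  if (!length(eligible))
    stop("no population has ", reference_size, " samples for the reference")
  with_seed(seed, {
    ref_idx <- integer(0); test_idx <- integer(0)
    for (p in sort(unique(pops))) {
      if (p %in% held_out_pops) next
      idx <- which(pops == p)
      if (p %in% eligible) {
        take <- sort(sample(idx, reference_size))
        rest <- setdiff(idx, take)
        ref_idx <- c(ref_idx, take)
      } else {
        rest <- idx
      }
      if (length(rest) > min_test) test_idx <- c(test_idx, rest)
    }
    held_idx <- which(pops %in% held_out_pops)
    list(reference = subset_genotypes(ds, samples = sort(ref_idx)),
         test = subset_genotypes(ds, samples = sort(test_idx)),
         heldout = subset_genotypes(ds, samples = sort(held_idx)))
  })
}

#' Simulate an admixed or mixed-origin cohort
#'
#' Builds a cohort from two source populations of a frequency model.
#' With `per_sample_admixture = FALSE` each sample is drawn wholly from
#' one source, with the sources appearing in proportions `prop` (a
#' mixed-origin cohort).  With `per_sample_admixture = TRUE` each sample
#' gets its own mixing weight `w ~ Uniform(0, 1)` and draws every genotype
#' from `w p_A + (1 - w) p_B` (a two-way admixed cohort).
#'
#' @param fm a [simulate_frequencies()] result.
#' @param cfg the [sim_config()] the model was built from.
#' @param pops length-2 character: source population labels.
#' @param n cohort size.
#' @param prop length-2 source proportions (ignored when
#'   `per_sample_admixture = TRUE`).
#' @param per_sample_admixture draw a per-sample uniform mixing weight
#'   instead of whole-sample origins.
#' @param label population label for the cohort samples.
#' @param seed integer seed.
#' @return A [geno_dataset()]; the true per-sample origin (or mixing
#'   weight) is attached as attribute `"truth"`.
#' @export
simulate_mixture_cohort <- function(fm, cfg, pops, n, prop = c(0.5, 0.5),
                                    per_sample_admixture = FALSE,
                                    label = "MIX", seed = 1L) {
  stopifnot(inherits(fm, "freq_model"), length(pops) == 2L)
  ia <- match(pops, rownames(fm$pop_freq))
  if (anyNA(ia)) stop("unknown source populations")
  m <- cfg$n_snps
  with_seed(derive_seed(seed, "mixture"), {
    if (per_sample_admixture) {
      w <- runif(n)
      truth <- w
    } else {
      origin <- sample(rep(pops, round(n * prop / sum(prop)))[seq_len(n)])
      w <- as.numeric(origin == pops[1])
      truth <- origin
    }
    p <- outer(w, fm$pop_freq[ia[1], ]) + outer(1 - w, fm$pop_freq[ia[2], ])
    dos <- matrix(rbinom(n * m, 2L, p), n, m)
    ds <- geno_dataset(dos, sprintf("%s_%04d", label, seq_len(n)),
                       rep(label, n), .default_snp_map(m))
    attr(ds, "truth") <- truth
    ds
  })
}
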