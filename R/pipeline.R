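# End-to-end pipeline: simulate -> design split -> PCA/TW -> geographic
# concordance -> Fst -> AIMs (+ leave-one-out stability) -> PCAIMs ->
# assignment curves -> held-out profile, with per-stage caching keyed by a
# config hash and per-stage seeds derived from one root seed.

PIPELINE_STAGES <- c("simulate", "design", "pca", "geo", "fst", "aims",
                     "pcaims", "assign")

#' Default pipeline configuration
#'
#' The demo study: the [study_config()] cohort at 5000 SNPs, a 70-per-
#' population harmonized reference with the SWE analogue held out, PCA
#' with Tracy-Widom component selection, 1000-permutation geographic
#' tests, AIM/PCAIM ranking and 25-marker assignment curves.
#'
#' @param seed root seed.
#' @return nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       sim = list(n_snps = 5000L, ld_block_size = 5L, ld_flip_prob = 0.02,
                  missing_rate = 0.01, populations = NULL),
       design = list(reference_size = 70L, min_test = 10L,
                     held_out = study_heldout_pop()),
       pca = list(n_pcs = 10L),
       geo = list(n_perm = 1000L),
       aims = list(maf = 0.01, r2 = 0.8, window_bp = 1e6),
       pcaims = list(window_bp = 1e6, n_pcs = 10L),
       assign = list(k = 5L,
                     marker_counts = c(10L, 25L, 50L, 100L, 250L, 500L),
                     top = 25L))
}

# materialize a sim_config from the pipeline config
.pipeline_sim_config <- function(config) {
  s <- config$sim
  if (is.null(s$populations)) {
    study_config(seed = config$seed, n_snps = s$n_snps %||% 5000L,
                 ld_block_size = s$ld_block_size %||% 5L,
                 ld_flip_prob = s$ld_flip_prob %||% 0.02,
                 missing_rate = s$missing_rate %||% 0.01)
  } else {
    p <- s$populations
    sim_config(n_populations = length(p$name),
               samples_per_pop = p$size,
               n_snps = s$n_snps,
               fst_per_pop = p$fst,
               cline_strength = s$cline_strength %||% c(0, 0),
               geo = geo_panel(p$name, p$latitude, p$longitude),
               ld_block_size = s$ld_block_size %||% 1L,
               ld_flip_prob = s$ld_flip_prob %||% 0,
               missing_rate = s$missing_rate %||% 0,
               selection_prop = s$selection_prop %||% 0,
               selection_gradient = s$selection_gradient %||% c(0.05, 0.25),
               seed = config$seed)
  }
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing every stage's outputs
#' under `out_dir` and a JSON manifest (config hash, per-stage seeds,
#' outputs and wall-clock) at the end.  With `resume = TRUE`, stages whose
#' outputs already exist under a matching config hash are reloaded from
#' disk instead of recomputed; any recomputed stage forces recomputation
#' of everything downstream.  All randomness derives from `config$seed`
#' through per-stage substreams, so reruns are bit-identical.
#'
#' @param config a config list ([default_pipeline_config()]), or the path
#'   to a YAML file holding one.
#' @param out_dir output directory (created if needed).
#' @param resume reuse cached stage outputs when valid (default TRUE).
#' @return the manifest, invisibly; stage results are in attribute
#'   `"state"`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "aimsel_run", resume = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must carry a root seed")
  def <- default_pipeline_config(config$seed)
  for (nm in names(def)) {
    config[[nm]] <- if (is.list(def[[nm]]))
      modifyList(def[[nm]], config[[nm]] %||% list()) else
      config[[nm]] %||% def[[nm]]
  }
  scfg <- .pipeline_sim_config(config)   # validates population count etc.
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_hash <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path)$config_hash else NULL
  cache_ok <- resume && identical(old_hash, hash)

  state <- new.env(parent = emptyenv())
  manifest <- list(config_hash = hash,
                   tool_version = as.character(utils::packageVersion("aimsel")),
                   root_seed = config$seed, stages = list())
  dirty <- FALSE                       # once TRUE, downstream must rerun

  run_stage <- function(name, outputs, compute, load) {
    paths <- file.path(out_dir, outputs)
    cached <- cache_ok && !dirty && all(file.exists(paths))
    t0 <- proc.time()[["elapsed"]]
    if (cached) {
      load(paths)
      status <- "cached"
    } else {
      dirty <<- TRUE
      compute(paths)
      status <- "computed"
    }
    manifest$stages[[name]] <<- list(
      status = status, outputs = as.list(outputs),
      seed = derive_seed(config$seed, name),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    if (!all(file.exists(paths)))
      stop("stage '", name, "' failed to produce its outputs")
  }

  ## -- simulate ----------------------------------------------------------
  run_stage("simulate",
            c("cohort.bed", "cohort.bim", "cohort.fam", "cohort.panel.tsv",
              "cohort.geo.tsv"),
    compute = function(paths) {
      sim <- simulate_dataset(scfg)
      state$cohort <- sim$dataset
      state$geo <- sim$geo
      write_genotypes(sim$dataset, file.path(out_dir, "cohort"),
                      format = "plink1")
      write_geo_panel(sim$geo, file.path(out_dir, "cohort.geo.tsv"))
    },
    load = function(paths) {
      state$cohort <- read_genotypes(file.path(out_dir, "cohort"),
                                     format = "plink1")
      state$geo <- read_geo_panel(file.path(out_dir, "cohort.geo.tsv"))
    })

  ## -- design split ------------------------------------------------------
  run_stage("design",
            as.vector(outer(c("reference", "test", "heldout"),
                            c(".bed", ".bim", ".fam", ".panel.tsv"),
                            paste0)),
    compute = function(paths) {
      d <- make_study_design(state$cohort,
                             reference_size = config$design$reference_size,
                             min_test = config$design$min_test,
                             held_out_pops = config$design$held_out,
                             seed = derive_seed(config$seed, "design"))
      state$design <- d
      for (part in names(d))
        write_genotypes(d[[part]], file.path(out_dir, part),
                        format = "plink1")
    },
    load = function(paths) {
      state$design <- lapply(setNames(nm = c("reference", "test", "heldout")),
                             function(part)
                               read_genotypes(file.path(out_dir, part),
                                              format = "plink1"))
    })

  ## -- PCA + Tracy-Widom -------------------------------------------------
  run_stage("pca", c("pca_scores.tsv", "pca_eigen_tw.tsv",
                     "pca_loadings.tsv", "pca_eigen_full.tsv"),
    compute = function(paths) {
      pca <- genotype_pca(state$design$reference,
                          n_pcs = config$pca$n_pcs)
      state$pca <- pca
      .write_tsv(data.frame(sample_id = rownames(pca$scores),
                            population = state$design$reference$populations,
                            round(pca$scores, 6)), paths[1])
      .write_tsv(data.frame(component = seq_along(pca$eigenvalues),
                            eigenvalue = round(pca$eigenvalues, 6),
                            variance_fraction =
                              round(pca$variance_fraction, 6),
                            tw_stat = round(pca$tw_stats, 4),
                            tw_pvalue = signif(pca$tw_pvalues, 6)),
                 paths[2])
      .write_tsv(data.frame(snp_id = rownames(pca$loadings),
                            round(pca$loadings, 6)), paths[3])
      .write_tsv(data.frame(eigenvalue = pca$eigenvalues_full), paths[4])
    },
    load = function(paths) {
      sc <- read.table(paths[1], header = TRUE, sep = "\t")
      ei <- read.table(paths[2], header = TRUE, sep = "\t")
      lo <- read.table(paths[3], header = TRUE, sep = "\t")
      ev_full <- read.table(paths[4], header = TRUE, sep = "\t")$eigenvalue
      scores <- as.matrix(sc[, -(1:2)])
      rownames(scores) <- sc$sample_id
      loadings <- as.matrix(lo[, -1])
      rownames(loadings) <- lo$snp_id
      state$pca <- structure(
        list(scores = scores, loadings = loadings,
             eigenvalues = ei$eigenvalue,
             variance_fraction = ei$variance_fraction,
             eigenvalues_full = ev_full, n_samples = nrow(scores),
             n_snps = nrow(loadings), tw_stats = ei$tw_stat,
             tw_pvalues = ei$tw_pvalue),
        class = "pca_result")
    })

  ## -- geographic concordance -------------------------------------------
  run_stage("geo", "geo_concordance.json",
    compute = function(paths) {
      cent <- population_centroids(state$pca,
                                   state$design$reference$populations,
                                   state$geo, m = 2L)
      rep_ <- concordance_report(cent, n_perm = config$geo$n_perm,
                                 seed = derive_seed(config$seed, "geo"))
      state$concordance <- rep_
      jsonlite::write_json(
        list(pc1_lat_rho = rep_$spearman$pc1_lat$rho,
             pc1_lat_p = rep_$spearman$pc1_lat$p,
             pc2_lon_rho = rep_$spearman$pc2_lon$rho,
             pc2_lon_p = rep_$spearman$pc2_lon$p,
             best_angle_deg = rep_$best_angle$angle_deg,
             best_angle_rho = rep_$best_angle$rho,
             mantel_r = rep_$mantel$r, mantel_p = rep_$mantel$p,
             procrustes_t = rep_$procrustes$t,
             procrustes_p = rep_$procrustes$p,
             n_permutations = rep_$n_permutations),
        paths[1], auto_unbox = TRUE, digits = NA)
    },
    load = function(paths) {
      state$concordance <- jsonlite::read_json(paths[1], simplifyVector = TRUE)
    })

  ## -- Fst ---------------------------------------------------------------
  run_stage("fst", c("fst_matrix.tsv", "fst_matrix_full.tsv",
                     "fst_pairs.json", "fst_vs_km.json"),
    compute = function(paths) {
      pool <- bind_genotypes(state$design$reference, state$design$test)
      fm <- pairwise_fst(allele_frequencies(pool))
      state$fst <- fm
      ind <- indistinct_groups(fm)
      state$indistinct <- ind
      .write_tsv(data.frame(population = fm$populations,
                            round(fm$fst, 3)), paths[1])
      .write_tsv(data.frame(population = fm$populations, fm$fst), paths[2])
      jsonlite::write_json(list(threshold = fm$indistinct_threshold,
                                pairs = ind$pairs,
                                components = as.list(ind$components)),
                           paths[3], auto_unbox = TRUE, digits = NA)
      fk <- fst_vs_distance(fm, state$geo,
                            n_perm = config$geo$n_perm,
                            seed = derive_seed(config$seed, "fst_km"))
      state$fst_km <- fk
      jsonlite::write_json(list(r_squared = fk$r_squared,
                                mantel_r = fk$mantel_r,
                                mantel_p = fk$mantel_p),
                           paths[4], auto_unbox = TRUE, digits = NA)
    },
    load = function(paths) {
      full <- read.table(paths[2], header = TRUE, sep = "\t")
      fst <- as.matrix(full[, -1])
      dimnames(fst) <- list(full$population, full$population)
      pj <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
      state$fst <- structure(list(populations = full$population, fst = fst,
                                  indistinct_threshold = pj$threshold),
                             class = "fst_matrix")
      pairs <- as.data.frame(pj$pairs)
      state$indistinct <- list(pairs = pairs,
                               components = unlist(pj$components))
      state$fst_km <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
    })

  ## -- AIMs + leave-one-population-out stability -------------------------
  run_stage("aims", c("aims.tsv", "aims_lopo.tsv"),
    compute = function(paths) {
      rk <- rank_aims(state$design$reference,
                      maf_threshold = config$aims$maf,
                      r2_threshold = config$aims$r2,
                      window_bp = config$aims$window_bp)
      state$aims <- rk
      .write_tsv(rk$table, paths[1])
      lopo <- lopo_stability(state$design$reference,
                             maf_threshold = config$aims$maf)
      state$lopo <- lopo
      .write_tsv(lopo, paths[2])
    },
    load = function(paths) {
      state$aims <- marker_ranking(read.table(paths[1], header = TRUE,
                                              sep = "\t",
                                              stringsAsFactors = FALSE,
                                              colClasses =
                                                c(chromosome = "character")),
                                   method = "informativeness")
      state$lopo <- read.table(paths[2], header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    })

  ## -- PCAIMs ------------------------------------------------------------
  run_stage("pcaims", c("pcaims.tsv", "pcaims_pruned.tsv"),
    compute = function(paths) {
      # pipeline default: sum weights across all extracted components
      rk <- pcaim_scores(state$pca, snps = state$design$reference$snps,
                         n_pcs = min(config$pcaims$n_pcs,
                                     ncol(state$pca$loadings)))
      state$pcaims_unpruned <- rk
      pruned <- prune_clusters(rk, window_bp = config$pcaims$window_bp)
      state$pcaims <- pruned
      .write_tsv(rk$table, paths[1])
      .write_tsv(pruned$table, paths[2])
    },
    load = function(paths) {
      rd <- function(p) marker_ranking(
        read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(chromosome = "character")),
        method = "pcaim")
      state$pcaims_unpruned <- rd(paths[1])
      state$pcaims <- rd(paths[2])
    })

  ## -- assignment --------------------------------------------------------
  run_stage("assign", c("accuracy_aims.tsv", "accuracy_pcaims.tsv",
                        "heldout_profile.tsv"),
    compute = function(paths) {
      counts <- config$assign$marker_counts
      counts_ok <- function(rk)
        counts[counts <= nrow(rk$table)]
      pairs <- state$indistinct$pairs
      acc_a <- accuracy_curve(state$design$reference, state$design$test,
                              state$aims,
                              marker_counts = counts_ok(state$aims),
                              k = config$assign$k,
                              indistinct_pairs = pairs)
      acc_p <- accuracy_curve(state$design$reference, state$design$test,
                              state$pcaims,
                              marker_counts = counts_ok(state$pcaims),
                              k = config$assign$k,
                              indistinct_pairs = pairs)
      state$accuracy <- list(aims = acc_a, pcaims = acc_p)
      .write_tsv(acc_a, paths[1])
      .write_tsv(acc_p, paths[2])
      prof <- list()
      if (length(state$design$heldout$sample_ids)) {
        for (ms in c("aims", "pcaims")) {
          fr <- nearest_population_profile(
            state$design$reference, state$design$heldout,
            k = config$assign$k,
            markers = top_markers(state[[ms]],
                                  min(config$assign$top,
                                      nrow(state[[ms]]$table))))
          prof[[ms]] <- data.frame(marker_set = ms,
                                   population = names(fr),
                                   fraction = as.numeric(fr))
        }
      }
      state$heldout_profile <- do.call(rbind, prof)
      .write_tsv(state$heldout_profile %||%
                   data.frame(marker_set = character(0),
                              population = character(0),
                              fraction = numeric(0)), paths[3])
    },
    load = function(paths) {
      state$accuracy <- list(
        aims = read.table(paths[1], header = TRUE, sep = "\t"),
        pcaims = read.table(paths[2], header = TRUE, sep = "\t"))
      state$heldout_profile <- read.table(paths[3], header = TRUE,
                                          sep = "\t")
    })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(manifest, "state") <- state
  invisible(manifest)
}
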