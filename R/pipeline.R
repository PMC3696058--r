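#' Full-analysis run configuration
#'
#' Collects every input path, model setting and Monte-Carlo size of the
#' pipeline.  Defaults follow the standard workflow settings: 10,000
#' permutation/bootstrap replicates, a minimum of 5 individuals per
#' locality, network base weight 90, TN93 distances with gamma shape 0.5.
#'
#' @param fasta Path to the aligned FASTA file, or a character vector of
#'   two paths for a two-locus analysis (concatenated after an inner join
#'   on individual ids).
#' @param popmap Path to the population map (TSV/CSV).
#' @param out_dir Output directory.
#' @param loci Optional locus labels matching `fasta`.
#' @param min_n Minimum individuals per locality for population-level
#'   statistics (default 5).
#' @param model,gamma_shape Substitution model for distances (default
#'   TN93 with gamma shape 0.5).
#' @param groupings Named list of named character vectors (locality ->
#'   group) defining the AMOVA grouping schemes; the first one also
#'   partitions the demographic analyses.
#' @param n_perm Permutation replicates for Phi_ST/AMOVA (default 10000).
#' @param n_boot Parametric-bootstrap replicates for the mismatch SSD
#'   test and tau CI (default 10000).
#' @param n_null Neutral simulations behind the neutrality-test p-values
#'   (default 1000).
#' @param base_weight,epsilon,passes Median-joining network settings.
#' @param k_max,runs,replicates Haplogroup-clustering search schedule.
#' @param generation_time,divergence_rate,halve_rate Expansion-dating
#'   settings (years, % per site per Myr, halving convention).
#' @param stages Character vector of stages to run, any of `"diversity"`,
#'   `"structure"`, `"network"`, `"haplogroups"`, `"demography"`.
#' @param seed Global seed, fanned out to independent per-stage seeds.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, popmap, out_dir, loci = NULL, min_n = 5,
                       model = "TN93", gamma_shape = 0.5,
                       groupings = NULL, n_perm = 10000, n_boot = 10000,
                       n_null = 1000, base_weight = 90, epsilon = 0,
                       passes = 2, k_max = 22, runs = 10, replicates = 6,
                       generation_time = 2, divergence_rate = 0.52,
                       halve_rate = FALSE,
                       stages = c("diversity", "structure", "network",
                                  "haplogroups", "demography"),
                       seed = 1L) {
  for (f in c(fasta, popmap))
    if (!file.exists(f)) stop("input file not found: ", f)
  structure(list(fasta = fasta, popmap = popmap, out_dir = out_dir,
                 loci = loci, min_n = min_n, model = model,
                 gamma_shape = gamma_shape, groupings = groupings,
                 n_perm = n_perm, n_boot = n_boot, n_null = n_null,
                 base_weight = base_weight, epsilon = epsilon,
                 passes = passes, k_max = k_max, runs = runs,
                 replicates = replicates,
                 generation_time = generation_time,
                 divergence_rate = divergence_rate,
                 halve_rate = halve_rate, stages = stages,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [run_config()]; `groupings` is a mapping of scheme name to a
#'   locality->group mapping.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$groupings))
    y$groupings <- lapply(y$groupings, function(g) unlist(g))
  do.call(run_config, y)
}

write_csv_out <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow: load and validate the alignment(s)
#' and population map, remove gap/N columns, apply the minimum-sample
#' filter for population-level statistics, then compute diversity tables,
#' pairwise Phi_ST with FDR correction, AMOVA for every configured
#' grouping, the reweighted median-joining network, haplogroup clustering
#' and frequencies, and the mismatch/neutrality/dating demographic
#' analyses (pooled and per group of the first grouping scheme).  All
#' tables are written under `cfg$out_dir` together with a JSON manifest
#' (settings, per-stage seeds, session info) sufficient to re-run the
#' analysis bit-identically.  A failing stage is reported with its name;
#' the remaining stages still run.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with every in-memory result plus `errors`
#'   (named list of stage failures, empty on success).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(errors = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # --- load ------------------------------------------------------------
  alns <- lapply(seq_along(cfg$fasta), function(i)
    read_fasta_alignment(cfg$fasta[i], locus = cfg$loci[i]))
  aln <- if (length(alns) == 2L) concatenate_loci(alns[[1]], alns[[2]])
         else alns[[1]]
  dropped <- attr(aln, "dropped")
  if (length(dropped))
    message("concatenation dropped ", length(dropped),
            " individual(s) missing a locus")
  aln <- drop_gap_sites(aln)
  pm <- read_population_map(cfg$popmap)
  res$aln <- aln
  res$pm <- pm
  ht <- collapse_haplotypes(aln, pm)
  res$haplotypes <- ht
  write_haplotype_table(ht, file.path(cfg$out_dir, "haplotypes.csv"))

  # --- diversity -------------------------------------------------------
  if ("diversity" %in% cfg$stages) run_stage("diversity", {
    res$diversity <- diversity_summary(aln, pm)
    write_csv_out(res$diversity, cfg$out_dir, "diversity.csv")
  })

  # --- population structure -------------------------------------------
  if ("structure" %in% cfg$stages) run_stage("structure", {
    filt <- filter_min_sample_size(pm, aln, min_n = cfg$min_n)
    mcfg <- subst_model_config(cfg$model, gamma_shape = cfg$gamma_shape)
    d <- pairwise_distance_matrix(filt$aln, mcfg,
                                  on_saturation = "p_fallback")
    res$phi_st <- pairwise_phi_st(d, filt$pm, n_perm = cfg$n_perm,
                                  seed = stage_seed(cfg$seed, "phi_st"),
                                  min_n = cfg$min_n)
    utils::write.csv(res$phi_st$phi_st,
                     file.path(cfg$out_dir, "phi_st.csv"))
    utils::write.csv(res$phi_st$p_adj,
                     file.path(cfg$out_dir, "phi_st_p_adj.csv"))
    res$amova <- list()
    for (g in names(cfg$groupings)) {
      scheme <- grouping_scheme(g, cfg$groupings[[g]])
      am <- amova(d, filt$pm, scheme, n_perm = cfg$n_perm,
                  seed = stage_seed(cfg$seed, paste0("amova_", g)))
      res$amova[[g]] <- am
      write_amova_csv(am, file.path(cfg$out_dir,
                                    paste0("amova_", g, ".csv")))
    }
    if (is.null(cfg$groupings)) {
      am <- amova(d, filt$pm, NULL, n_perm = cfg$n_perm,
                  seed = stage_seed(cfg$seed, "amova"))
      res$amova <- list(populations = am)
      write_amova_csv(am, file.path(cfg$out_dir, "amova_populations.csv"))
    }
  })

  # --- haplotype network ----------------------------------------------
  if ("network" %in% cfg$stages) run_stage("network", {
    net <- build_network_with_reweighting(ht, epsilon = cfg$epsilon,
                                          base_weight = cfg$base_weight,
                                          passes = cfg$passes)
    res$network <- net
    write_network(net,
                  graphml = file.path(cfg$out_dir, "network.graphml"),
                  edgelist = file.path(cfg$out_dir, "network_edges.tsv"))
    write_csv_out(data.frame(site = seq_along(net$weights$weights),
                             weight = net$weights$weights),
                  cfg$out_dir, "site_weights.csv")
  })

  # --- haplogroup clustering ------------------------------------------
  if ("haplogroups" %in% cfg$stages) run_stage("haplogroups", {
    model <- cluster_haplotypes(ht, k_max = cfg$k_max, runs = cfg$runs,
                                replicates = cfg$replicates,
                                seed = stage_seed(cfg$seed, "haplogroups"))
    res$clusters <- model
    labels <- assign_haplogroups(model, ht)
    res$haplogroup_freq <- haplogroup_frequencies(labels, pm)
    write_csv_out(data.frame(haplotype_id = names(model$assignment),
                             cluster = model$assignment),
                  cfg$out_dir, "haplogroup_assignment.csv")
    utils::write.csv(res$haplogroup_freq,
                     file.path(cfg$out_dir, "haplogroup_frequencies.csv"))
  })

  # --- historical demography ------------------------------------------
  if ("demography" %in% cfg$stages) run_stage("demography", {
    groups <- list(all = rownames(aln))
    if (length(cfg$groupings)) {
      gmap <- cfg$groupings[[1]]
      loc <- popmap_localities(pm, rownames(aln))
      for (g in unique(gmap)) {
        ids <- rownames(aln)[loc %in% names(gmap)[gmap == g]]
        if (length(ids) >= 4L) groups[[g]] <- ids
      }
    }
    res$demography <- list()
    for (g in names(groups)) {
      sub <- structure(unclass(aln)[groups[[g]], , drop = FALSE],
                       class = "aln")
      n <- nrow(sub)
      obs <- mismatch_observed(sub)
      fit <- fit_sudden_expansion(obs, n = n,
                                  seed = stage_seed(cfg$seed,
                                                    paste0("fit_", g)))
      fit$ssd_p <- ssd_pvalue(fit, B = cfg$n_boot,
                              seed = stage_seed(cfg$seed,
                                                paste0("ssd_", g)))
      fit$tau_ci <- tau_confidence_interval(fit, B = cfg$n_boot,
                                            seed = stage_seed(cfg$seed,
                                                              paste0("ci_", g)))
      tj <- tajimas_d(sub, n_null = cfg$n_null,
                      seed = stage_seed(cfg$seed, paste0("tajima_", g)))
      fs <- fus_fs(sub, n_null = cfg$n_null,
                   seed = stage_seed(cfg$seed, paste0("fs_", g)))
      dating <- time_since_expansion(fit$tau, fit$tau_ci, s = ncol(sub),
                                     generation_time = cfg$generation_time,
                                     divergence_rate = cfg$divergence_rate,
                                     halve_rate = cfg$halve_rate)
      res$demography[[g]] <- list(fit = fit, tajima = tj, fs = fs,
                                  dating = dating)
      write_csv_out(data.frame(
        differences = seq_along(obs) - 1L,
        observed_count = obs,
        observed_freq = obs / sum(obs),
        expected_freq = fit$expected[seq_along(obs)]),
        cfg$out_dir, paste0("mismatch_", g, ".csv"))
      jsonlite::write_json(list(
        group = g, n = n, tau = fit$tau, theta0 = fit$theta0,
        theta1 = fit$theta1, ssd = fit$ssd, ssd_p = fit$ssd_p,
        tau_ci = as.numeric(fit$tau_ci),
        tajima_d = tj$D, tajima_p = tj$p, fu_fs = fs$Fs, fu_fs_p = fs$p,
        t_years = dating$t_years,
        t_years_ci = as.numeric(dating$ci_years)),
        file.path(cfg$out_dir, paste0("demography_", g, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  })

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "haplostruct",
    version = as.character(utils::packageVersion("haplostruct")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(cfg),
    analysed_sites = ncol(aln),
    n_individuals = nrow(aln),
    n_haplotypes = nrow(ht$haplotypes),
    errors = res$errors)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
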