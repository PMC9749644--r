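# End-to-end pipeline driver: simulate -> qc -> mine -> permute ->
# evaluate -> architecture -> annotate -> stratify -> gwas -> replicate,
# with one global seed, stage toggles, and a run manifest.

#' Default pipeline configuration
#'
#' A nested list that can be edited, saved as YAML, and passed to
#' [run_pipeline()]. Every stage seed is derived from the single global
#' `seed` (stage index i uses `derive_seed(seed, i)`), so one seed
#' reproduces the whole run byte-for-byte.
#'
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, qc = TRUE, mine = TRUE, permute = TRUE,
                  evaluate = TRUE, architecture = TRUE, annotate = TRUE,
                  stratify = TRUE, gwas = TRUE, replicate = FALSE),
    cohort = list(
      n_cases = 500, control_ratio = 2, n_snps = 100,
      maf_range = c(0.05, 0.5),
      planted = list(
        list(snp_ids = c("rs00001", "rs00002", "rs00003"),
             genotype_states = c(1, 1, 0), target_or = 3.7,
             target_case_prevalence = 0.15,
             covariate_effects = list(stress_event = 0.8),
             biomarker_shifts = list(lactate = 0.5)))),
    paths = list(),   # external inputs when simulate is disabled:
                      # genotypes, covariates, gene_model
    qc = list(maf_min = 0.01, snp_missing_max = 0.05,
              sample_missing_max = 0.05, hwe_p_min = 1e-6,
              autosomes_only = TRUE),
    mining = list(max_order = 5, p_max = 0.05, min_case_prevalence = 0.05,
                  search_mode = "greedy_stochastic", n_random_starts = 100),
    validation = list(n_perm = 500, fdr_alpha = 0.05,
                      p1000_significance_fraction = 0.05),
    evaluation = list(critical_min = 2, n_folds = 5, n_trees = 500),
    architecture = list(method = "modularity"),
    annotation = list(upstream_window = 2000, downstream_window = 500),
    gwas = list(test = "allelic_chisq", genome_wide_alpha = 5e-8),
    replication = list(n_cases = 500)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a `pipeline_config` list.
#' @return the configuration (read) / `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  merged <- utils::modifyList(base, cfg)
  # modifyList cannot merge the unnamed planted-signature list; the file's
  # list replaces the default wholesale
  if (!is.null(cfg$cohort) && !is.null(cfg$cohort$planted)) {
    merged$cohort$planted <- cfg$cohort$planted
  }
  class(merged) <- "pipeline_config"
  merged
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

planted_from_config <- function(lst) {
  lapply(lst, function(p) {
    do.call(planted_signature, p)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order under `outdir`,
#' writing per-stage artifacts (TSV/JSON) and a `manifest.json` recording
#' the configuration fingerprint, the global seed, per-stage record
#' counts and timings. Re-running with an identical configuration
#' reproduces identical outputs. A stage failure stops the run with the
#' failing stage named; artifacts of completed stages are retained.
#'
#' @param config a `pipeline_config` list, or the path of a YAML file.
#' @param outdir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(
    config_hash = fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                           digits = NA)),
    seed = seed,
    package_version = as.character(utils::packageVersion("combsig")),
    r_version = R.version.string,
    stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, idx, enabled, fn) {
    if (!isTRUE(enabled)) {
      manifest$stages[[name]] <<- list(enabled = FALSE)
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(derive_seed(seed, idx)), error = function(e) {
      manifest$stages[[name]] <<- list(enabled = TRUE, status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, outdir)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(
      list(enabled = TRUE, status = "ok",
           seconds = round(proc.time()[["elapsed"]] - t0, 2)),
      res)
    invisible()
  }

  run_stage("simulate", 1L, config$stages$simulate, function(s) {
    spec <- cohort_spec(
      n_cases = config$cohort$n_cases,
      control_ratio = config$cohort$control_ratio %||% 2,
      n_snps = config$cohort$n_snps,
      maf_range = unlist(config$cohort$maf_range %||% c(0.05, 0.5)),
      planted = planted_from_config(config$cohort$planted %||% list()),
      missing_rate = config$cohort$missing_rate %||% 0,
      seed = s)
    cohort <- generate_cohort(spec)
    write_cohort(cohort, file.path(outdir, "cohort"))
    state$cohort <- cohort
    state$g <- cohort$genotypes
    state$covariates <- cohort$covariates
    state$gene_model <- cohort$gene_model
    list(n_samples = nrow(state$g$genotypes), n_snps = ncol(state$g$genotypes))
  })
  if (!isTRUE(config$stages$simulate)) {
    abort_if(is.null(config$paths$genotypes),
             "simulate disabled and no input genotype path configured")
    state$g <- read_genotypes(config$paths$genotypes)
    if (!is.null(config$paths$covariates)) {
      state$covariates <- read_covariates(config$paths$covariates)
    }
    if (!is.null(config$paths$gene_model)) {
      state$gene_model <- read_gene_model(config$paths$gene_model)
    }
  }

  run_stage("qc", 2L, config$stages$qc, function(s) {
    qc <- qc_filter(state$g, do.call(qc_params, config$qc))
    state$g <- qc$genotypes
    jsonlite::write_json(qc$report, file.path(outdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    qc$report[c("n_samples_out", "n_snps_out")]
  })

  run_stage("mine", 3L, config$stages$mine, function(s) {
    mp <- do.call(mining_params, c(config$mining, list(seed = s)))
    state$mining <- mp
    state$mined <- mine_signatures(state$g, mp)
    write_signatures(state$mined, file.path(outdir, "signatures.tsv"))
    write_signatures_json(state$mined, file.path(outdir, "signatures.json"))
    list(n_signatures = length(state$mined))
  })

  run_stage("permute", 4L, config$stages$permute, function(s) {
    vp <- do.call(validation_params, c(config$validation, list(seed = s)))
    rep <- compute_p1000(state$mined, state$g, vp, state$mining)
    state$validated <- validate_signatures(state$mined, rep, vp)
    write_permutation_report(rep, file.path(outdir, "permutation_report.tsv"))
    write_signatures(state$validated, file.path(outdir, "validated_signatures.tsv"))
    write_signatures_json(state$validated,
                          file.path(outdir, "validated_signatures.json"))
    list(n_validated = length(state$validated))
  })
  if (is.null(state$validated)) state$validated <- state$mined

  run_stage("evaluate", 5L, config$stages$evaluate, function(s) {
    if (length(state$validated) == 0) return(list(n_critical = 0))
    crit <- tryCatch(
      find_critical_snps(state$validated,
                         config$evaluation$critical_min %||% 2),
      error = function(e) character(0))
    if (length(crit) == 0) return(list(n_critical = 0))
    scores <- score_critical_snps(state$g, crit,
                                  n_folds = config$evaluation$n_folds %||% 5,
                                  n_trees = config$evaluation$n_trees %||% 500,
                                  seed = s)
    state$critical <- crit
    state$scores <- scores
    tab <- critical_snp_table(state$validated, scores)
    data.table::fwrite(tab, file.path(outdir, "critical_snps.tsv"), sep = "\t")
    list(n_critical = length(crit),
         cv_accuracy = attr(scores, "cv_accuracy"))
  })

  run_stage("architecture", 6L, config$stages$architecture, function(s) {
    if (length(state$validated) == 0) return(list(n_communities = 0))
    graph <- build_architecture(state$validated)
    memb <- detect_communities(graph,
                               method = config$architecture$method %||% "modularity",
                               seed = s)
    sig_comm <- signature_communities(state$validated, memb)
    cstats <- community_stats(state$validated, sig_comm, state$g)
    state$communities <- cstats
    state$sig_comm <- sig_comm
    write_architecture(graph, file.path(outdir, "architecture_edges.tsv"))
    data.table::fwrite(as.data.frame(cstats),
                       file.path(outdir, "communities.tsv"), sep = "\t")
    if (nrow(cstats) >= 2) {
      om <- overlap_matrix(cstats)
      data.table::fwrite(data.table::as.data.table(om, keep.rownames = "community"),
                         file.path(outdir, "community_overlap.tsv"), sep = "\t")
    }
    list(n_communities = nrow(cstats),
         cases_represented = cases_represented(state$validated, state$g))
  })

  run_stage("annotate", 7L, config$stages$annotate, function(s) {
    if (length(state$validated) == 0 || is.null(state$gene_model)) {
      return(list(n_assigned = 0))
    }
    ap <- annotation_params(config$annotation$upstream_window %||% 2000,
                            config$annotation$downstream_window %||% 500)
    ann <- annotate_signatures(state$validated, state$g, state$gene_model, ap)
    data.table::fwrite(ann$assignments,
                       file.path(outdir, "gene_assignments.tsv"), sep = "\t")
    if (!is.null(state$scores)) {
      pri <- prioritize_genes(state$scores, ann$assignments)
      data.table::fwrite(pri, file.path(outdir, "gene_priorities.tsv"),
                         sep = "\t")
    }
    list(n_assigned = length(unique(ann$assignments$snp_id)),
         n_unassigned = length(ann$unassigned))
  })

  run_stage("stratify", 8L, config$stages$stratify, function(s) {
    if (is.null(state$covariates)) return(list(n_profiles = 0))
    n_prof <- 0
    if (!is.null(state$communities)) {
      sets <- attr(state$communities, "case_sets")
      all_cases <- sum(state$g$labels == "case")
      profs <- list()
      for (cid in names(sets)) {
        if (length(sets[[cid]]) == 0 || length(sets[[cid]]) >= all_cases) next
        pr <- profile_subgroup(sets[[cid]], state$covariates)
        if (nrow(pr) > 0) profs[[cid]] <- cbind(community = cid, pr)
      }
      if (length(profs) > 0) {
        data.table::fwrite(do.call(rbind, profs),
                           file.path(outdir, "community_profiles.tsv"),
                           sep = "\t")
        n_prof <- length(profs)
      }
    }
    bin <- names(Filter(function(x) is.numeric(x) && all(x %in% c(0, 1, NA)),
                        state$covariates[setdiff(names(state$covariates),
                                                 c("sample_id", "status"))]))
    if (length(bin) > 0) {
      groups <- list(cases = state$covariates$sample_id[state$covariates$status == "case"],
                     controls = state$covariates$sample_id[state$covariates$status == "control"])
      forest <- covariate_forest(state$covariates, groups, bin, seed = s)
      data.table::fwrite(forest, file.path(outdir, "covariate_forest.tsv"),
                         sep = "\t")
    }
    list(n_profiles = n_prof)
  })

  run_stage("gwas", 9L, config$stages$gwas, function(s) {
    gw <- single_snp_gwas(state$g, test = config$gwas$test %||% "allelic_chisq",
                          genome_wide_alpha = config$gwas$genome_wide_alpha %||% 5e-8)
    data.table::fwrite(gw, file.path(outdir, "gwas.tsv"), sep = "\t")
    list(n_significant = sum(gw$significant))
  })

  run_stage("replicate", 10L, config$stages$replicate, function(s) {
    abort_if(is.null(state$critical) || length(state$critical) == 0,
             "replication requires critical SNPs from the evaluate stage")
    spec <- cohort_spec(
      n_cases = config$replication$n_cases %||% config$cohort$n_cases,
      control_ratio = config$cohort$control_ratio %||% 2,
      n_snps = config$cohort$n_snps,
      maf_range = unlist(config$cohort$maf_range %||% c(0.05, 0.5)),
      planted = planted_from_config(config$cohort$planted %||% list()),
      seed = s)
    cohort2 <- generate_cohort(spec)
    mp <- do.call(mining_params,
                  c(config$mining, list(seed = derive_seed(s, 1L))))
    vp <- do.call(validation_params,
                  c(config$validation, list(seed = derive_seed(s, 2L))))
    rep <- replicate_in_cohort(state$critical, cohort2$genotypes, mp, vp)
    jsonlite::write_json(
      list(replicated = rep$replicated, untestable = rep$untestable,
           tested = rep$tested),
      file.path(outdir, "replication.json"), auto_unbox = TRUE, digits = NA)
    list(n_replicated = length(rep$replicated))
  })

  write_manifest(manifest, outdir)
  invisible(manifest)
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}
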