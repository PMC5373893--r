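pipeline_stages <- c("simulate", "de_proteome", "de_transcriptome",
                     "de_secretome", "network", "integrate", "progression",
                     "risk", "report")

#' Assemble (or load) a pipeline configuration
#'
#' A pipeline configuration holds the stage selection, seeds, thresholds
#' and output directory for [run_pipeline()]. It can be given as a list or
#' loaded from a YAML file. Thresholds default to the analysis settings:
#' proteome FDR 0.10, transcript FDR 0.10, network edge q 0.20,
#' family-wise 0.05, risk categories 5% and 7.5%.
#'
#' @param config A named list or path to a YAML file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "`config` must be a list or a YAML path")
  defaults <- list(
    stages = pipeline_stages,
    seed = 1L,
    outdir = "plaqomics_output",
    thresholds = list(proteome_fdr = 0.10, transcript_fdr = 0.10,
                      network_q = 0.20, family_wise = 0.05,
                      risk_categories = c(0.05, 0.075)),
    sim = list()
  )
  cfg <- utils::modifyList(defaults, config)
  unknown <- setdiff(cfg$stages, pipeline_stages)
  if (length(unknown) > 0) {
    plaq_abort(paste("unknown pipeline stage(s):",
                     paste(unknown, collapse = ", ")))
  }
  th <- unlist(cfg$thresholds[c("proteome_fdr", "transcript_fdr",
                                "network_q", "family_wise")])
  assert_that(all(th > 0 & th <= 1), "thresholds must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the discovery-to-validation pipeline on simulated inputs
#'
#' Executes the selected stages in order on seed-controlled synthetic
#' data: spectral-count DE per fraction, transcript DE, paired secretome
#' testing, coexpression network, cross-omics candidate integration,
#' ultrasound progression classification, and incremental risk prediction.
#' Every stage writes its table to `outdir` and the run ends with a
#' machine-readable log (package version, seeds, thresholds). Inputs are
#' never mutated; reruns with the same config are byte-identical.
#'
#' @param config A [pipeline_config()] (list or YAML path accepted).
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  th <- cfg$thresholds
  res <- list()
  want <- function(s) s %in% cfg$stages

  sim_args <- utils::modifyList(
    list(n_proteins = 150L, de_fraction = 0.1, fold_change = 3,
         n_genes = 400L, effect_size = 1.5, n_subjects = 400L), cfg$sim)

  if (want("simulate") || want("de_proteome") || want("network") ||
      want("integrate")) {
    res$proteome <- list(
      NaCl = simulate_spectral_counts(proteome_sim_config(
        seed = seed, n_proteins = sim_args$n_proteins,
        de_fraction = sim_args$de_fraction,
        fold_change = sim_args$fold_change), fraction = "NaCl"),
      GuHCl = simulate_spectral_counts(proteome_sim_config(
        seed = seed + 1L, n_proteins = sim_args$n_proteins,
        de_fraction = sim_args$de_fraction,
        fold_change = sim_args$fold_change), fraction = "GuHCl")
    )
    if (want("simulate")) {
      write_count_matrix(res$proteome$NaCl$matrix,
                         file.path(cfg$outdir, "counts_nacl.tsv"))
      write_count_matrix(res$proteome$GuHCl$matrix,
                         file.path(cfg$outdir, "counts_guhcl.tsv"))
    }
  }
  if (want("de_proteome") || want("network") || want("integrate")) {
    res$de_proteome <- purrr::map(res$proteome, function(p) {
      run_spectral_de(p$matrix, fdr_threshold = th$proteome_fdr,
                      seed = seed)
    })
    purrr::iwalk(res$de_proteome, function(de, frac) {
      readr::write_tsv(tibble::as_tibble(de),
                       file.path(cfg$outdir,
                                 paste0("de_proteome_", tolower(frac),
                                        ".tsv")))
    })
  }
  if (want("de_transcriptome") || want("integrate")) {
    tr <- simulate_transcriptome(seed = seed, n_genes = sim_args$n_genes,
                                 de_fraction = sim_args$de_fraction,
                                 effect_size = sim_args$effect_size)
    res$de_transcriptome <- moderated_two_group_de(
      tr$matrix, fdr_threshold = th$transcript_fdr)
    readr::write_tsv(tibble::as_tibble(res$de_transcriptome),
                     file.path(cfg$outdir, "de_transcriptome.tsv"))
  }
  if (want("de_secretome") || want("integrate")) {
    sec <- simulate_secretome(seed = seed, shifted_proteins = "SEC1",
                              shift = 2)
    res$de_secretome <- paired_bonferroni_test(sec, alpha = th$family_wise)
    readr::write_tsv(tibble::as_tibble(res$de_secretome),
                     file.path(cfg$outdir, "de_secretome.tsv"))
  }
  if (want("network")) {
    de <- res$de_proteome$NaCl
    imp <- attr(de, "imputation")
    nsaf <- compute_nsaf(imp$imputed_matrix)
    res$network <- build_network(nsaf, de, q_threshold = th$network_q)
    readr::write_tsv(res$network$edges,
                     file.path(cfg$outdir, "network_edges.tsv"))
    readr::write_tsv(res$network$nodes,
                     file.path(cfg$outdir, "network_nodes.tsv"))
  }
  if (want("integrate")) {
    prot_lists <- purrr::map(res$de_proteome,
                             ~ .x$protein_id[.x$significant])
    union_tab <- de_union(prot_lists)
    transcript_hits <- res$de_transcriptome$gene_id[
      res$de_transcriptome$significant]
    secretome_hits <- res$de_secretome$protein_id[
      res$de_secretome$significant]
    res$candidates <- select_candidates(
      union_tab, intersect_de(union_tab, transcript_hits), secretome_hits)
    readr::write_csv(tibble::as_tibble(res$candidates),
                     file.path(cfg$outdir, "candidates.csv"))
  }
  if (want("progression") || want("risk")) {
    cohort_sim <- simulate_cohort(cohort_sim_config(
      seed = seed, n_subjects = sim_args$n_subjects))
    res$cohort <- cohort_sim
    if (want("simulate")) {
      write_cohort(cohort_sim$cohort, file.path(cfg$outdir, "cohort.csv"))
    }
  }
  if (want("progression")) {
    exams <- res$cohort$exams
    res$progression <- classify_progression(
      exams[exams$visit == "baseline", ],
      exams[exams$visit == "followup", ])
    readr::write_csv(res$progression,
                     file.path(cfg$outdir, "progression_calls.csv"))
  }
  if (want("risk")) {
    cohort <- standardize_biomarkers(res$cohort$cohort,
                                     paste0("bm", 1:4))
    res$risk <- compare_risk_models(
      cohort, outcome = "advanced",
      base_terms = c("age", "sex", "ldl", "hdl", "hypertension",
                     "pack_years"),
      added_terms = paste0("bm", 1:4, "_z"),
      type = "logistic", categories = th$risk_categories)
    readr::write_csv(tibble::as_tibble(res$risk),
                     file.path(cfg$outdir, "risk_increment.csv"))
  }
  if (want("report")) {
    log <- list(
      package = "plaqomics",
      version = as.character(utils::packageVersion("plaqomics")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      thresholds = th,
      stages = cfg$stages,
      timestamp = "deterministic"
    )
    jsonlite::write_json(log, file.path(cfg$outdir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
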