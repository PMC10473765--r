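# Orchestration: a validated config drives the full analysis in stages
# (cohorts -> QC/harmonization -> standardized sex effects -> homolog
# alignment -> robust cross-species correlations -> similarity scores ->
# transcriptional similarity -> gene-subset nulls), writing plain-text
# outputs stamped with the config hash and seed.

pipeline_defaults <- list(
  q_level = 0.05,
  euler_threshold = -200,
  bend_constant = 0.2,
  n_resamples = 10000L,
  include_ttv = TRUE,
  zscore_ttv = FALSE,
  one_per_family = FALSE,
  compartments = c("all", "cortical", "non_cortical"),
  seed = 1L,
  synthetic = FALSE,
  region_map = NULL,
  human_subjects = NULL,
  mouse_subjects = NULL,
  human_expression = NULL,
  mouse_expression = NULL,
  homolog_map = NULL,
  gene_subsets = NULL
)

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills defaults (q level 0.05,
#' Euler threshold -200, bend constant 0.2, 10000 resamples), checks types,
#' ranges, and the existence of any input paths, and aggregates all
#' problems into a single error. Unknown keys produce a warning, not an
#' error.
#'
#' @param config Path to a YAML file, or a named list of settings.
#' @return The validated config (list of class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  unknown <- setdiff(names(config), names(pipeline_defaults))
  if (length(unknown) > 0)
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults,
                           config[intersect(names(config),
                                            names(pipeline_defaults))])
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$q_level) && cfg$q_level > 0 && cfg$q_level < 1,
      "q_level must be in (0, 1)")
  chk(is.numeric(cfg$bend_constant) && cfg$bend_constant > 0 &&
        cfg$bend_constant <= 0.5, "bend_constant must be in (0, 0.5]")
  chk(is.numeric(cfg$n_resamples) && cfg$n_resamples >= 1,
      "n_resamples must be >= 1")
  chk(is.numeric(cfg$euler_threshold), "euler_threshold must be numeric")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  chk(all(cfg$compartments %in% c("all", "cortical", "non_cortical")),
      "compartments must be among all/cortical/non_cortical")
  for (key in c("region_map", "human_subjects", "mouse_subjects",
                "human_expression", "mouse_expression", "homolog_map")) {
    if (!is.null(cfg[[key]]))
      chk(file.exists(cfg[[key]]),
          paste0(key, " path does not exist: ", cfg[[key]]))
  }
  if (!is.null(cfg$gene_subsets)) {
    chk(is.list(cfg$gene_subsets) && !is.null(names(cfg$gene_subsets)),
        "gene_subsets must be a named list of files")
  }
  if (length(errs) > 0)
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cfg$n_resamples <- as.integer(cfg$n_resamples)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# Tiny stable FNV-1a hash of the canonical YAML form of the config,
# stamped on every output so runs are traceable to their settings.
#' @keywords internal
#' @noRd
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg[order(names(unclass(cfg)))]))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @keywords internal
#' @noRd
write_stamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published-table demo analysis
#'
#' Runs the cross-species congruence stage on the built-in table of 60
#' published paired effect sizes: the robust correlation over all regions
#' and within each compartment, the anatomical similarity scores, and the
#' quadrant classification. Needs no subject-level data.
#'
#' @param bend_constant Bending proportion, default 0.2.
#' @return A list of class `table1_demo`: `correlations` (named list of
#'   `cor_result` for all/cortical/non_cortical), `scores`, `quadrants`,
#'   `pairs`.
#' @examples
#' demo <- run_table1_demo()
#' demo$correlations$all
#' @export
run_table1_demo <- function(bend_constant = 0.2) {
  pairs <- builtin_pair_table()
  comps <- c("all", "cortical", "non_cortical")
  correlations <- lapply(stats::setNames(comps, comps), function(cp)
    cross_species_effect_correlation(pairs, cp, bend_constant))
  structure(
    list(correlations = correlations,
         scores = anatomical_similarity_scores(pairs),
         quadrants = quadrant_classification(pairs),
         pairs = pairs),
    class = "table1_demo")
}

#' @export
print.table1_demo <- function(x, ...) {
  cat("Cross-species congruence of published paired sex effects\n")
  for (cp in names(x$correlations)) {
    cr <- x$correlations[[cp]]
    cat(sprintf("  %-12s r = %.3f (p = %.3f, n = %d)\n", cp, cr$r, cr$p,
                cr$n))
  }
  qt <- table(x$quadrants$quadrant)
  cat("  quadrants:", paste(names(qt), qt, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
read_subject_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

#' @keywords internal
#' @noRd
read_expression_matrix <- function(path, species) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  new_region_gene_matrix(mat, species = species)
}

#' Run the full analysis pipeline
#'
#' Executes every stage the configuration enables and writes plain-text
#' outputs to `outdir`: per-species effect-size and variance-test tables,
#' the homologous pair table, robust cross-species correlations for each
#' requested compartment with and without the TTV covariate, anatomical
#' (and where expression data exist, transcriptional) similarity scores,
#' gene-subset null distributions, and a machine-readable `summary.yaml`.
#' Subject tables come from `human_subjects` / `mouse_subjects` paths, or
#' are simulated from the default cohort specs when `synthetic: true`;
#' with neither, the pipeline runs in demo mode on the built-in published
#' table. Expression stages run only when both expression matrices and a
#' homolog map are supplied (or synthesized); otherwise they are skipped
#' and logged. Identical config and seed give byte-identical outputs.
#'
#' @param config A [validate_config()] result, YAML path, or settings list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  seed <- cfg$seed
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  cat(sprintf("# pipeline run, config_hash=%s seed=%d\n", hash, seed),
      file = log_path)
  logf("package sexcongr %s, R %s",
       as.character(utils::packageVersion("sexcongr")),
       paste(R.version$major, R.version$minor, sep = "."))

  map <- if (is.null(cfg$region_map)) load_homologous_regions()
         else load_homologous_regions(cfg$region_map)
  summary <- list(config_hash = hash, seed = seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage '%s' FAILED: %s", name, conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  have_subjects <- !is.null(cfg$human_subjects) ||
    !is.null(cfg$mouse_subjects) || isTRUE(cfg$synthetic)

  if (have_subjects) {
    cohorts <- stage("load_cohorts", {
      if (isTRUE(cfg$synthetic)) {
        logf("simulating default human and mouse cohorts (seed %d)", seed)
        list(human = simulate_cohort(cohort_spec("human", seed = seed)),
             mouse = simulate_cohort(cohort_spec("mouse", seed = seed + 1L)))
      } else {
        list(human = read_subject_table(cfg$human_subjects),
             mouse = read_subject_table(cfg$mouse_subjects))
      }
    })
    effects <- list()
    for (sp in c("human", "mouse")) {
      effects[[sp]] <- stage(paste0("effects_", sp), {
        tab <- cohorts[[sp]]
        if (sp == "human") {
          tab <- apply_qc_exclusions(tab, cfg$euler_threshold)
          if (isTRUE(cfg$one_per_family) && "family_id" %in% names(tab))
            tab <- subset_one_per_family(tab, seed)
          qc_col <- "euler"
        } else {
          if ("batch" %in% names(tab) &&
              nlevels(droplevels(factor(tab$batch))) > 1L)
            tab <- harmonize_batches(tab)
          qc_col <- if ("strain" %in% names(tab)) "strain" else NULL
        }
        res <- list()
        for (ttv in unique(c(cfg$include_ttv, FALSE))) {
          fit <- fit_sex_effects(tab, q_level = cfg$q_level,
                                 include_ttv = ttv, qc_col = qc_col,
                                 zscore_ttv = cfg$zscore_ttv)
          res[[if (ttv) "with_ttv" else "no_ttv"]] <- fit
          write_stamped(as.data.frame(fit),
                        file.path(outdir, sprintf("effects_%s_%s.tsv", sp,
                                  if (ttv) "with_ttv" else "no_ttv")),
                        hash, seed)
        }
        res$ttv_fit <- fit_sex_effect(tab, "ttv", qc_col = qc_col)
        cov_cols <- intersect(c("ttv", "age", qc_col), names(tab))
        resid <- residualize(tab, cov_cols)
        lev <- do.call(rbind, lapply(colnames(resid), function(rg) {
          vt <- levene_variance_test(resid[, rg], tab$sex)
          data.frame(region = rg, F = vt$F, p = vt$p)
        }))
        lev$q <- fdr_adjust(lev$p, cfg$q_level)$q
        write_stamped(lev, file.path(outdir,
                                     sprintf("variance_%s.tsv", sp)),
                      hash, seed)
        res$variance <- lev
        res
      })
    }
    key <- if (cfg$include_ttv) "with_ttv" else "no_ttv"
    pairs <- stage("align_homologs",
                   align_homologs(effects$human[[key]],
                                  effects$mouse[[key]], map))
    summary$ttv_beta_human <- effects$human$ttv_fit$beta_sex
    summary$ttv_beta_mouse <- effects$mouse$ttv_fit$beta_sex
    summary$pct_significant_human <-
      summarize_sex_bias(effects$human[[key]])$pct_significant
    summary$pct_significant_mouse <-
      summarize_sex_bias(effects$mouse[[key]])$pct_significant
    pairs_no_ttv <- stage("align_homologs_no_ttv",
                          align_homologs(effects$human$no_ttv,
                                         effects$mouse$no_ttv, map))
  } else {
    logf("no subject-level inputs: running on the built-in published table")
    pairs <- builtin_pair_table()
    pairs_no_ttv <- NULL
  }
  write_stamped(as.data.frame(pairs), file.path(outdir, "pair_table.tsv"),
                hash, seed)

  for (cp in cfg$compartments) {
    cr <- stage(paste0("congruence_", cp),
                cross_species_effect_correlation(pairs, cp,
                                                 cfg$bend_constant))
    summary[[paste0("congruence_r_", cp)]] <- cr$r
    summary[[paste0("congruence_p_", cp)]] <- cr$p
    if (!is.null(pairs_no_ttv)) {
      crn <- cross_species_effect_correlation(pairs_no_ttv, cp,
                                              cfg$bend_constant)
      summary[[paste0("congruence_r_", cp, "_no_ttv")]] <- crn$r
    }
  }

  scores <- stage("similarity_scores", anatomical_similarity_scores(pairs))
  quads <- quadrant_classification(pairs)
  write_stamped(quads, file.path(outdir, "quadrants.tsv"), hash, seed)

  have_expression <- (!is.null(cfg$human_expression) &&
                        !is.null(cfg$mouse_expression) &&
                        !is.null(cfg$homolog_map)) || isTRUE(cfg$synthetic)
  if (have_expression) {
    expr <- stage("expression", {
      if (isTRUE(cfg$synthetic)) {
        sim <- simulate_expression_pair(
          expression_pair_spec(seed = seed + 2L))
        list(human = sim$human, mouse = sim$mouse, map = sim$map)
      } else {
        list(human = read_expression_matrix(cfg$human_expression, "human"),
             mouse = read_expression_matrix(cfg$mouse_expression, "mouse"),
             map = utils::read.delim(cfg$homolog_map,
                                     stringsAsFactors = FALSE))
      }
    })
    scored <- stage("transcriptional_similarity", {
      paired <- intersect_homologous_genes(expr$human, expr$mouse, expr$map)
      h <- reflect_hemisphere(paired$human, map)
      m <- paired$mouse
      # keep genes non-constant in both species so the pair stays aligned
      keep <- apply(unclass(h), 2, stats::sd) > 0 &
        apply(unclass(m), 2, stats::sd) > 0
      hz <- zscore_genes_across_regions(
        new_region_gene_matrix(unclass(h)[, keep, drop = FALSE], "human"))
      mz <- zscore_genes_across_regions(
        new_region_gene_matrix(unclass(m)[, keep, drop = FALSE], "mouse"))
      scores <- add_transcriptional_similarity(scores, hz, mz)
      for (cp in cfg$compartments) {
        cr <- similarity_vs_expression_correlation(scores, cp,
                                                   cfg$bend_constant)
        summary[[paste0("similarity_r_", cp)]] <- cr$r
        summary[[paste0("similarity_p_", cp)]] <- cr$p
      }
      if (!is.null(cfg$gene_subsets)) {
        for (nm in names(cfg$gene_subsets)) {
          genes <- intersect(read_gene_subset(cfg$gene_subsets[[nm]]),
                             colnames(hz))
          nd <- gene_subset_null(hz, mz, scores, genes,
                                 n_resamples = cfg$n_resamples,
                                 seed = seed, bend_constant =
                                   cfg$bend_constant)
          summary[[paste0("null_p_", nm)]] <- nd$p
          summary[[paste0("null_observed_", nm)]] <- nd$observed
          write_stamped(data.frame(value = nd$values),
                        file.path(outdir, sprintf("null_%s.tsv", nm)),
                        hash, seed)
        }
      }
      scores
    })
    scores <- scored
  } else {
    logf("expression inputs absent: expression stages skipped")
  }
  write_stamped(scores, file.path(outdir, "similarity_scores.tsv"),
                hash, seed)

  yaml::write_yaml(lapply(summary, function(v)
    if (is.numeric(v)) round(v, 10) else v),
    file.path(outdir, "summary.yaml"))
  logf("pipeline complete: %s", outdir)
  invisible(summary)
}
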