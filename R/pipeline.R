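#' Default pipeline configuration
#'
#' All thresholds of the two-level analysis in one place, echoed verbatim
#' into the run's provenance file. Defaults follow the field's standard
#' scheme:
#' top 2000 MAD features, consensus clustering with reps = 1000,
#' pItem = 0.8, pFeature = 1, DMPs at BH p < 0.001 and |delta beta| > 0.2,
#' DEGs at |log2FC| > 1 and BH p < 0.05, anti-correlation screen at
#' rho < -0.6 and BH p < 0.05, 2 Mb structural windows. `max_k` defaults
#' to 8: the consensus CDF is informative well below the conventional
#' maxK = 20 at these cohort sizes, and the choice is configurable.
#'
#' @param ... Named overrides of any default.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    top_n = 2000,
    reps = 1000, p_item = 0.8, p_feature = 1.0, max_k = 8,
    meth_k = 2, expr_k = 4, min_cluster_size = 3,
    dmp_p_adj = 0.001, dmp_delta = 0.2,
    deg_lfc = 1, deg_p_adj = 0.05,
    rho_threshold = -0.6, assoc_p_adj = 0.05,
    tel_window_bp = 2e6, cen_window_bp = 2e6,
    max_fail_fraction = 0.10,
    size_cutoff_cm = 2.5,
    n_perm = 1000, chisq_sims = 2000,
    epsilon = 0.001,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$top_n > 0, cfg$reps > 0, cfg$p_item > 0, cfg$p_item <= 1,
            cfg$max_k >= 2, cfg$rho_threshold < 0, cfg$min_cluster_size >= 2)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Methylation-level analysis: epigenetic subtypes and their differences
#'
#' Stage order: probe filtering (failure mask and autosome restriction
#' when supplied), top-MAD feature selection, consensus clustering,
#' cutting at `meth_k` clusters, marker-driven cluster naming, probe-level
#' differential methylation between the two named subtypes,
#' chromatin-state over-representation of the DMPs, and structural-region
#' median methylation with Welch tests.
#'
#' Cluster naming is marker-driven, not order-driven: with `meth_k = 2`,
#' the cluster with the higher fraction of DAXX/ATRX-lost samples is
#' named `"ADM"` and the other `"alpha_like"`. Without a
#' `daxx_atrx_lost` column the clusters stay numbered, with a warning,
#' and the downstream two-group statistics use the numeric labels.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param manifest Probe manifest.
#' @param genome Genome table for structural regions.
#' @param sheet Sample sheet (needs `sample_id`; uses `daxx_atrx_lost`).
#' @param config A [pipeline_config()].
#' @param fail_mask Optional probe-by-sample failure mask.
#' @return List: `labels` (sample -> subtype), `consensus`
#'   (consensus_result), `model_selection` (CDF/delta-area), `dmp`
#'   (DMP table), `state_ora`, `region_map`, `region_medians`,
#'   `region_tests`.
#' @export
run_methylation_level <- function(beta, manifest, genome, sheet, config = pipeline_config(),
                                  fail_mask = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("methylation stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$seed, 2, tag = "meth")
  beta <- stage("filter_probes", filter_probes(
    beta, fail_mask = fail_mask, max_fail_fraction = config$max_fail_fraction,
    manifest = manifest, autosomes = unique(genome$chrom)))
  top <- stage("select_top_mad", select_top_mad(beta, min(config$top_n, nrow(beta))))
  cons <- stage("consensus_cluster", consensus_cluster(
    beta[top, , drop = FALSE], k_range = 2:config$max_k, reps = config$reps,
    p_item = config$p_item, p_feature = config$p_feature, seed = seeds[1]))
  sel <- stage("cdf_and_delta_area", cdf_and_delta_area(cons))
  cl <- cons$assignments[[paste0("k", config$meth_k)]]

  labels <- paste0("cluster", cl)
  names(labels) <- names(cl)
  if ("daxx_atrx_lost" %in% colnames(sheet) && config$meth_k == 2) {
    lost <- stats::setNames(sheet$daxx_atrx_lost, sheet$sample_id)[names(cl)]
    frac <- tapply(as.logical(lost), cl, mean, na.rm = TRUE)
    adm_cluster <- as.integer(names(which.max(frac)))
    labels <- ifelse(cl == adm_cluster, "ADM", "alpha_like")
    names(labels) <- names(cl)
  } else if (config$meth_k == 2) {
    warning("no daxx_atrx_lost column; clusters left unnamed")
  }

  two_group <- length(unique(labels)) == 2
  dmp <- state_ora <- region_tests <- NULL
  group_factor <- factor(labels, levels = sort(unique(labels)))
  if (all(c("alpha_like", "ADM") %in% labels)) {
    # contrast is ADM minus alpha-like
    group_factor <- factor(labels, levels = c("alpha_like", "ADM"))
  }
  if (two_group) {
    dmp <- stage("dmp_test", dmp_test(
      beta, group_factor, p_adj_threshold = config$dmp_p_adj,
      delta_threshold = config$dmp_delta))
    state_ora <- stage("chromatin_state_ora", chromatin_state_ora(
      dmp$probe_id[dmp$significant], manifest, universe = dmp$probe_id))
  }
  region_map <- stage("define_structural_regions", define_structural_regions(
    genome, manifest, tel_window_bp = config$tel_window_bp,
    cen_window_bp = config$cen_window_bp))
  med <- stage("region_medians", region_medians(beta, region_map))
  if (two_group) {
    # keep the reference level first so mean_diff is ADM minus alpha-like
    region_tests <- stage("region_group_test", region_group_test(
      med, stats::setNames(group_factor, names(labels))))
  }

  list(labels = labels, consensus = cons, model_selection = sel, dmp = dmp,
       state_ora = state_ora, region_map = region_map, region_medians = med,
       region_tests = region_tests)
}

#' Expression-level analysis: transcriptomic ADM subtypes and programs
#'
#' Restricted to the ADM samples (the alpha-like epigenetic subtype is
#' excluded, as in the two-level design): low-count filtering,
#' median-of-ratios normalization, shifted-log transform, top-MAD
#' selection, consensus clustering cut at `expr_k`, exclusion of clusters
#' below `min_cluster_size` from one-vs-rest testing, per-subtype NB
#' differential expression, optional preranked GSEA (ranking by the Wald
#' statistic) and rank-sum signature scores, and the
#' promoter-methylation anti-correlation screen per subtype.
#'
#' @param counts Gene-by-sample count matrix (full cohort; subsetting to
#'   `adm_samples` happens here).
#' @param adm_samples Character vector of ADM sample ids.
#' @param manifest Probe manifest (for promoter pairs).
#' @param beta Beta matrix for the same cohort (for the screen).
#' @param config A [pipeline_config()].
#' @param gene_sets Optional gene-set collection for GSEA/ORA.
#' @param signature_genes Optional character vector for the signature score.
#' @return List: `labels` (sample -> `ADM<cluster>`), `consensus`,
#'   `model_selection`, `excluded_subtypes`, `de` (named list of DEG
#'   tables), `gsea`, `ora`, `signature_scores`, `associations` (named
#'   list of anti-correlation tables).
#' @export
run_expression_level <- function(counts, adm_samples, manifest, beta,
                                 config = pipeline_config(), gene_sets = NULL,
                                 signature_genes = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("expression stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$seed, 2, tag = "expr")
  adm_samples <- intersect(adm_samples, colnames(counts))
  if (length(adm_samples) < 4) stop("need >= 4 ADM samples with expression data")
  counts <- counts[, adm_samples, drop = FALSE]
  counts <- stage("filter_low_counts", filter_low_counts(counts))
  sf <- stage("size_factors", size_factors(counts))
  expr <- stage("vst_like", vst_like(counts, sf))
  top <- stage("select_top_mad", select_top_mad(expr, min(config$top_n, nrow(expr))))
  max_k <- min(config$max_k, length(adm_samples) - 1)
  cons <- stage("consensus_cluster", consensus_cluster(
    expr[top, , drop = FALSE], k_range = 2:max_k, reps = config$reps,
    p_item = config$p_item, p_feature = config$p_feature, seed = seeds[1]))
  sel <- stage("cdf_and_delta_area", cdf_and_delta_area(cons))
  cl <- cons$assignments[[paste0("k", config$expr_k)]]
  labels <- stats::setNames(paste0("ADM", cl), names(cl))

  sizes <- table(labels)
  usable <- names(sizes)[sizes >= config$min_cluster_size]
  excluded <- setdiff(names(sizes), usable)
  if (length(excluded) > 0) {
    message("subtype(s) below min_cluster_size excluded from testing: ",
            paste(excluded, collapse = ", "))
  }
  if (length(usable) < 2) stop("fewer than 2 usable transcriptomic clusters")

  m_all <- beta_to_m(beta[, intersect(colnames(beta), adm_samples), drop = FALSE],
                     epsilon = config$epsilon)
  de <- list(); gsea <- list(); ora <- list(); assoc <- list()
  for (st in usable) {
    tab <- stage(paste0("nb_test:", st), nb_test_one_vs_rest(
      counts, labels[colnames(counts)], st, sf = sf,
      lfc_threshold = config$deg_lfc, p_adj_threshold = config$deg_p_adj))
    de[[st]] <- tab
    if (!is.null(gene_sets)) {
      ranked <- stats::setNames(tab$wald_statistic, tab$gene_id)
      ranked <- ranked[is.finite(ranked)]
      gsea[[st]] <- stage(paste0("gsea:", st), gsea_preranked(
        ranked, gene_sets, n_perm = config$n_perm, seed = seeds[2]))
      ora[[st]] <- stage(paste0("ora:", st), set_ora(
        tab$gene_id[tab$significant], tab$gene_id, gene_sets))
    }
    pairs <- stage(paste0("promoter_pairs:", st),
                   suppressWarnings(promoter_probe_pairs(manifest, tab)))
    shared <- intersect(colnames(m_all), colnames(expr))
    assoc[[st]] <- stage(paste0("anticorrelation:", st), anticorrelation_screen(
      m_all[, shared, drop = FALSE], expr[, shared, drop = FALSE], pairs,
      rho_threshold = config$rho_threshold, p_adj_threshold = config$assoc_p_adj))
  }

  scores <- NULL
  if (!is.null(signature_genes)) {
    scores <- stage("signature_score",
                    signature_score(expr, signature_genes, name = "MLP1_like"))
    scores$subtype <- labels[scores$sample_id]
  }

  list(labels = labels, consensus = cons, model_selection = sel,
       excluded_subtypes = excluded, de = de, gsea = gsea, ora = ora,
       signature_scores = scores, associations = assoc, size_factors = sf,
       expr = expr)
}

#' Run the full two-level pipeline and write a run directory
#'
#' Orchestrates methylation-level clustering, the ADM expression-level
#' analysis, survival comparisons and the tumor-size association from a
#' single config and seed, writing every figure-equivalent statistic as
#' TSV plus a provenance JSON (package version, seed, thresholds, input
#' hashes). Two runs with the same inputs, config and seed produce
#' byte-identical directories.
#'
#' @param cohort Either a [simulate_cohort()]-style list (`manifest`,
#'   `genome`, `beta`, `counts`, `sheet`) or a directory path written by
#'   [write_cohort()] (the genome then defaults to [toy_genome()]).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param gene_sets,signature_genes Passed to [run_expression_level()].
#' @return Invisibly, the list of stage results.
#' @export
run_pipeline <- function(cohort, out_dir, config = pipeline_config(),
                         gene_sets = NULL, signature_genes = NULL) {
  input_files <- NULL
  if (is.character(cohort)) {
    dir <- cohort
    input_files <- file.path(dir, c("manifest.tsv", "beta.tsv", "counts.tsv",
                                    "samples.tsv"))
    cohort <- list(
      genome = toy_genome(),
      manifest = read_manifest(file.path(dir, "manifest.tsv")),
      beta = read_matrix(file.path(dir, "beta.tsv"), "beta"),
      counts = read_matrix(file.path(dir, "counts.tsv"), "counts"),
      sheet = read_sample_sheet(file.path(dir, "samples.tsv"))
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  meth <- run_methylation_level(cohort$beta, cohort$manifest, cohort$genome,
                                cohort$sheet, config)
  adm <- names(meth$labels)[meth$labels == "ADM"]
  if (length(adm) == 0) adm <- names(meth$labels) # unnamed clusters: keep all
  expr <- run_expression_level(cohort$counts, adm, cohort$manifest, cohort$beta,
                               config, gene_sets = gene_sets,
                               signature_genes = signature_genes)

  sheet <- cohort$sheet
  surv <- km <- lr <- size_assoc <- NULL
  if (all(c("dfs_time", "dfs_event") %in% colnames(sheet))) {
    lab <- expr$labels[sheet$sample_id]
    ok <- !is.na(lab) & !is.na(sheet$dfs_time)
    if (sum(ok) > 3 && length(unique(lab[ok])) >= 2 && sum(sheet$dfs_event[ok]) >= 1) {
      km <- km_estimate(sheet$dfs_time[ok], sheet$dfs_event[ok], lab[ok])
      lr <- logrank_test(sheet$dfs_time[ok], sheet$dfs_event[ok], lab[ok])
    }
  }
  if ("tumor_size_cm" %in% colnames(sheet)) {
    lab <- expr$labels[sheet$sample_id]
    size <- dichotomize_size(sheet$tumor_size_cm, config$size_cutoff_cm)
    ok <- !is.na(lab) & !is.na(size)
    tab <- table(lab[ok], size[ok])
    if (nrow(tab) >= 2 && ncol(tab) >= 2) {
      size_assoc <- chisq_simulated(unclass(tab), n_sim = config$chisq_sims,
                                    seed = derive_seeds(config$seed, 1, "chisq"))
    }
  }

  res <- list(methylation = meth, expression = expr, km = km, logrank = lr,
              size_association = size_assoc, config = config)
  write_pipeline_outputs(res, out_dir, input_files)
  invisible(res)
}

# Write every tabular result plus provenance JSON into the run directory.
write_pipeline_outputs <- function(res, out_dir, input_files = NULL) {
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  meth <- res$methylation; expr <- res$expression
  w(data.frame(sample_id = names(meth$labels), epigenetic_subtype = meth$labels,
               stringsAsFactors = FALSE), "epigenetic_subtypes.tsv")
  k_meth <- paste0("k", res$config$meth_k)
  cm <- meth$consensus$consensus[[k_meth]]
  w(data.frame(sample_id = rownames(cm), round(cm, 6), check.names = FALSE),
    "consensus_matrix_methylation.tsv")
  w(data.frame(k = names(meth$model_selection$area),
               area = meth$model_selection$area,
               delta_area = meth$model_selection$delta_area),
    "model_selection_methylation.tsv")
  if (!is.null(meth$dmp)) w(meth$dmp, "dmp.tsv")
  if (!is.null(meth$state_ora)) w(meth$state_ora, "chromatin_state_ora.tsv")
  w(meth$region_medians, "region_medians.tsv")
  if (!is.null(meth$region_tests)) w(meth$region_tests, "region_tests.tsv")

  w(data.frame(sample_id = names(expr$labels), transcriptomic_subtype = expr$labels,
               stringsAsFactors = FALSE), "transcriptomic_subtypes.tsv")
  w(data.frame(k = names(expr$model_selection$area),
               area = expr$model_selection$area,
               delta_area = expr$model_selection$delta_area),
    "model_selection_expression.tsv")
  for (st in names(expr$de)) w(expr$de[[st]], paste0("deg_", st, ".tsv"))
  for (st in names(expr$gsea)) w(expr$gsea[[st]], paste0("gsea_", st, ".tsv"))
  for (st in names(expr$associations)) {
    w(expr$associations[[st]], paste0("associations_", st, ".tsv"))
  }
  if (!is.null(expr$signature_scores)) w(expr$signature_scores, "signature_scores.tsv")
  if (!is.null(res$km)) w(res$km, "km_curves.tsv")
  if (!is.null(res$logrank)) {
    w(data.frame(chi_square = res$logrank$chi_square, df = res$logrank$df,
                 p_value = res$logrank$p_value), "logrank.tsv")
  }
  if (!is.null(res$size_association)) {
    w(data.frame(statistic = res$size_association$statistic,
                 p_simulated = res$size_association$p_simulated,
                 n_sim = res$size_association$n_sim), "size_association.tsv")
  }

  prov <- list(
    package = "pannetomics",
    version = as.character(utils::packageVersion("pannetomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(res$config),
    input_md5 = if (!is.null(input_files)) {
      as.list(tools::md5sum(input_files[file.exists(input_files)]))
    } else NULL,
    excluded_subtypes = expr$excluded_subtypes
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Consolidated report of a completed run directory
#'
#' Reads the tabular outputs of [run_pipeline()] back into one list and
#' summarizes headline numbers (subtype sizes, DMP/DEG counts, passing
#' association counts). Stages whose output file is absent (a partial
#' run) are reported as missing rather than failing.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @return List of data.frames plus a `summary` data.frame.
#' @export
report <- function(run_dir) {
  files <- list.files(run_dir, pattern = "\\.tsv$")
  if (length(files) == 0) stop("no pipeline outputs in ", run_dir)
  out <- lapply(files, function(f) {
    utils::read.delim(file.path(run_dir, f), sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
  })
  names(out) <- sub("\\.tsv$", "", files)
  summ <- list()
  if (!is.null(out$epigenetic_subtypes)) {
    summ$epigenetic_sizes <- table(out$epigenetic_subtypes$epigenetic_subtype)
  }
  if (!is.null(out$transcriptomic_subtypes)) {
    summ$transcriptomic_sizes <- table(out$transcriptomic_subtypes$transcriptomic_subtype)
  }
  if (!is.null(out$dmp)) summ$n_dmp <- sum(out$dmp$significant == "TRUE" | out$dmp$significant == TRUE)
  deg_files <- grep("^deg_", names(out), value = TRUE)
  if (length(deg_files) > 0) {
    summ$n_deg <- vapply(out[deg_files], function(t) sum(t$significant == TRUE), integer(1))
  }
  assoc_files <- grep("^associations_", names(out), value = TRUE)
  if (length(assoc_files) > 0) {
    summ$n_passing_pairs <- vapply(out[assoc_files], function(t) sum(t$passes == TRUE), integer(1))
  }
  out$summary <- summ
  if (file.exists(file.path(run_dir, "provenance.json"))) {
    out$provenance <- jsonlite::read_json(file.path(run_dir, "provenance.json"))
  }
  out
}
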