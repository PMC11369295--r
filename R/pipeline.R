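#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the defaults the
#' pipeline is built around: screen FWER 0.05 (Bonferroni over genes
#' attempted), MR causal call at 0.05, replication at nominal 0.05,
#' instrument filters at 0.001, Spearman pruning at 0.9, low-expression
#' filter at 25%.
#'
#' @param sim a [sim_config()] for the synthetic discovery cohort.
#' @param n_replication replication cohort size.
#' @param avail_prob SNV availability probability in the replication
#'   cohort.
#' @param alpha_screen,alpha_mr,alpha_replication significance levels.
#' @param p_thresh_filters instrument-filter threshold.
#' @param rho_max pruning threshold.
#' @param min_expr_fraction low-expression filter fraction.
#' @param seed master seed for the run.
#' @param out output directory (`NULL` for none).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), n_replication = 4904,
                            avail_prob = 0.5, alpha_screen = 0.05,
                            alpha_mr = 0.05, alpha_replication = 0.05,
                            p_thresh_filters = 0.001, rho_max = 0.9,
                            min_expr_fraction = 0.25, seed = 1, out = NULL) {
  for (a in c(alpha_screen, alpha_mr, alpha_replication, p_thresh_filters))
    if (a <= 0 || a >= 1) stop("thresholds must lie in (0, 1)")
  structure(list(sim = sim, n_replication = n_replication,
                 avail_prob = avail_prob, alpha_screen = alpha_screen,
                 alpha_mr = alpha_mr, alpha_replication = alpha_replication,
                 p_thresh_filters = p_thresh_filters, rho_max = rho_max,
                 min_expr_fraction = min_expr_fraction,
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim` block
#' holds [sim_config()] fields. Missing keys take the defaults.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$maf_range)) sim_args$maf_range <- unlist(sim_args$maf_range)
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

#' Flag study genes against known-gene lists
#'
#' Case-insensitive symbol matching per list and pooled over all lists
#' ("known" = member of any list, "novel" = member of none).
#'
#' @param symbols character vector of study gene symbols.
#' @param known_lists named list of character vectors of symbols.
#' @return data.frame with `symbol`, one logical column per list, and
#'   `known`; attribute `counts` with per-list and pooled totals.
#' @export
annotate_known <- function(symbols, known_lists) {
  if (length(known_lists) == 0 || all(lengths(known_lists) == 0))
    warning("empty known-gene lists: all study genes flagged novel")
  out <- data.frame(symbol = symbols)
  low <- tolower(symbols)
  for (nm in names(known_lists))
    out[[nm]] <- low %in% tolower(known_lists[[nm]])
  flag_cols <- setdiff(names(out), "symbol")
  out$known <- if (length(flag_cols))
    Reduce(`|`, out[flag_cols]) else rep(FALSE, nrow(out))
  counts <- c(vapply(flag_cols, function(cn) sum(out[[cn]]), 0L),
              known = sum(out$known), novel = sum(!out$known))
  attr(out, "counts") <- counts
  out
}

stage_log <- function(log_lines, stage, t0, detail) {
  line <- sprintf("[%s] %-12s %6.1fs  %s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(proc.time()[3] - t0), detail)
  message(line)
  c(log_lines, line)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> preprocess -> joint copula screen (+ linear sensitivity
#' screen) -> GO enrichment -> MR -> replication -> known-gene overlap.
#' Writes per-stage TSVs, a JSON manifest (seed, thresholds, stage
#' counts) and a plain-text summary when `config$out` is set.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every stage's result and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[3]
  logl <- character()
  cfg <- config$sim
  cfg$seed <- as.integer(config$seed)

  cohort <- simulate_cohort(cfg)
  ann <- simulate_annotations(cohort$gene_meta$gene_id, seed = config$seed + 7L)
  known <- list(
    database_a = sample(cohort$gene_meta$symbol,
                        max(1, round(0.1 * nrow(cohort$gene_meta)))),
    database_b = sample(cohort$gene_meta$symbol,
                        max(1, round(0.05 * nrow(cohort$gene_meta)))))
  cohort_b <- simulate_replication_cohort(cohort, config$n_replication,
                                          config$avail_prob,
                                          seed = config$seed + 1000L)
  logl <- stage_log(logl, "simulate", t0,
                    sprintf("%d + %d samples, %d genes, %d SNVs",
                            cfg$n_samples, config$n_replication,
                            nrow(cohort$expression), nrow(cohort$genotypes)))

  pre <- preprocess_cohort(cohort, lengths = cohort$gene_meta$length,
                           min_fraction = config$min_expr_fraction)
  logl <- stage_log(logl, "preprocess", t0,
                    sprintf("%d/%d genes kept", length(pre$kept_genes),
                            nrow(cohort$expression)))

  screen <- transcriptome_screen(pre, alpha = config$alpha_screen)
  linear <- linear_screen(pre, alpha = config$alpha_screen)
  cnt <- attr(screen, "counts")
  logl <- stage_log(logl, "screen", t0,
                    sprintf("copula: %d SAT / %d ratio / %d both; linear total %d",
                            cnt["sat_only"], cnt["ratio_only"], cnt["both"],
                            attr(linear, "counts")["total"]))

  annset <- annotation_set(ann$gene2term, ann$ancestors, ann$term_names)
  study_sat <- screen$gene[screen$significant_sat]
  study_ratio <- screen$gene[screen$significant_ratio]
  background <- screen$gene
  enr <- list()
  for (oc in c("sat", "ratio")) {
    study <- if (oc == "sat") study_sat else study_ratio
    if (length(study) == 0) {
      enr[[oc]] <- NULL
      next
    }
    rows <- fisher_enrichment(study, background, annset)
    rows <- correct_terms(rows, alpha = 0.05)
    enr[[oc]] <- list(rows = rows,
                      parents = summarize_parents(
                        rows$term_id[rows$significant], annset))
  }
  logl <- stage_log(logl, "enrich", t0,
                    sprintf("%d terms analyzed; %d/%d significant (SAT/ratio)",
                            if (length(enr)) attr(enr[[1]]$rows, "n_analyzed_terms") else 0L,
                            if (!is.null(enr$sat)) sum(enr$sat$rows$significant) else 0L,
                            if (!is.null(enr$ratio)) sum(enr$ratio$rows$significant) else 0L))

  mr <- mr_screen(screen, cohort$eqtl, pre, alpha = config$alpha_mr,
                  p_thresh = config$p_thresh_filters,
                  rho_max = config$rho_max)
  mc <- attr(mr, "counts")
  logl <- stage_log(logl, "mr", t0,
                    sprintf("analyzable %d/%d, causal %d",
                            sum(mc$analyzable), sum(mc$tested),
                            sum(mc$causal)))

  rep_res <- replication_pipeline(mr, pre, cohort_b,
                                  alpha = config$alpha_replication)
  rc <- attr(rep_res, "counts")
  logl <- stage_log(logl, "replicate", t0,
                    sprintf("investigated %d, confirmed %d",
                            rc["investigated"], rc["confirmed"]))

  assoc_symbols <- cohort$gene_meta$symbol[
    match(unique(c(study_sat, study_ratio)), cohort$gene_meta$gene_id)]
  known_flags <- annotate_known(assoc_symbols, known)
  manifest <- list(
    package_version = as.character(utils::packageVersion("adipocop")),
    seed = config$seed,
    thresholds = config[c("alpha_screen", "alpha_mr", "alpha_replication",
                          "p_thresh_filters", "rho_max",
                          "min_expr_fraction")],
    n_discovery = cfg$n_samples,
    n_replication = config$n_replication,
    genes_simulated = nrow(cohort$expression),
    genes_analyzed = attr(screen, "n_genes"),
    bonferroni_cutoff = attr(screen, "cutoff"),
    screen_counts = as.list(attr(screen, "counts")),
    linear_counts = as.list(attr(linear, "counts")),
    mr_counts = mc,
    replication_counts = as.list(rc),
    known_counts = as.list(attr(known_flags, "counts")))

  res <- list(cohort = cohort, cohort_b = cohort_b, preprocessed = pre,
              screen = screen, linear = linear, enrichment = enr, mr = mr,
              replication = rep_res, known = known_flags,
              manifest = manifest, log = logl)
  if (!is.null(config$out)) write_pipeline_outputs(res, config$out)
  invisible(res)
}

write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$screen, "screen_copula.tsv")
  wt(res$linear, "screen_linear.tsv")
  if (!is.null(res$enrichment$sat)) {
    wt(res$enrichment$sat$rows, "enrichment_sat.tsv")
    wt(res$enrichment$sat$parents, "enrichment_sat_parents.tsv")
  }
  if (!is.null(res$enrichment$ratio)) {
    wt(res$enrichment$ratio$rows, "enrichment_ratio.tsv")
    wt(res$enrichment$ratio$parents, "enrichment_ratio_parents.tsv")
  }
  wt(res$mr, "mr_results.tsv")
  wt(res$replication, "replication_results.tsv")
  wt(res$known, "known_overlap.tsv")
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(res$log, "", pipeline_summary_text(res)),
             file.path(dir, "summary.txt"))
  invisible(dir)
}

pipeline_summary_text <- function(res) {
  m <- res$manifest
  c(sprintf("Joint copula screen of %d genes (cutoff %.3g):",
            m$genes_analyzed, m$bonferroni_cutoff),
    sprintf("  SAT only %d, SAT/TAT only %d, both %d, total %d",
            m$screen_counts$sat_only, m$screen_counts$ratio_only,
            m$screen_counts$both, m$screen_counts$total),
    sprintf("MR: %d analyzable, %d causal",
            sum(m$mr_counts$analyzable), sum(m$mr_counts$causal)),
    sprintf("Replication: %d investigated, %d confirmed",
            m$replication_counts$investigated,
            m$replication_counts$confirmed),
    sprintf("Known-gene overlap: %d known, %d novel",
            m$known_counts$known, m$known_counts$novel))
}
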