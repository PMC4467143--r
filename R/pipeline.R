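# End-to-end orchestration: screen scoring -> seed analysis -> expression
# integration -> progression dynamics, with an integration summary mirroring
# the study's miRNA accounting, and machine-readable reports.

#' Pipeline configuration
#'
#' Central place for the thresholds used across stages: the interaction-score
#' hit cutoff (-1.94), the BH significance level (0.05), the GSEA activity
#' thresholds (|NES| > 2 at FDR < 0.25), the correlation method, and the
#' seeds driving every random step.
#'
#' @param cutoff Interaction-score hit cutoff (default -1.94).
#' @param correlation_method `"spearman"` (default) or `"pearson"`.
#' @param gsea_permutations Permutations per gene set (default 1000).
#' @param q_threshold BH significance level (default 0.05).
#' @param nes_threshold NES magnitude threshold (default 2).
#' @param fdr_threshold GSEA FDR threshold (default 0.25).
#' @param seed Integer seed for all random stages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cutoff = -1.94,
                            correlation_method = c("spearman", "pearson"),
                            gsea_permutations = 1000,
                            q_threshold = 0.05, nes_threshold = 2,
                            fdr_threshold = 0.25, seed = 1) {
  correlation_method <- match.arg(correlation_method)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold must be in (0, 1]")
  if (fdr_threshold <= 0 || fdr_threshold > 1) stop("fdr_threshold must be in (0, 1]")
  if (nes_threshold <= 0) stop("nes_threshold must be positive")
  structure(
    list(cutoff = cutoff, correlation_method = correlation_method,
         gsea_permutations = gsea_permutations, q_threshold = q_threshold,
         nes_threshold = nes_threshold, fdr_threshold = fdr_threshold,
         seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.
#'
#' @param path YAML file with `key: value` entries.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

resolve_input <- function(x, loader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(loader(x))
  if (is.character(x) && length(x) == 1L) stop("input file not found: ", x)
  x
}

#' Run the integrative pipeline
#'
#' Executes every stage for which inputs are supplied. The screen stage is
#' mandatory; the others are optional and simply marked "not run" in the
#' report when their inputs are absent. Each input may be given in-memory
#' (data frame / matrix / list) or as a file path in the formats of the
#' `read_*` helpers.
#'
#' @param inputs A list with elements:
#'   * `screen_plates` — `ScreenPlateTable` data frame or CSV path (required);
#'   * `utr`, `mirna_seqs` — 3'UTR sequence / FASTA path and named mature
#'     miRNA sequences / FASTA path (seed stage);
#'   * `mirna_expr`, `mrna_expr` — miRNA and mRNA (with a MYCN row)
#'     feature x sample matrices or TSV paths (expression stage);
#'   * `gene_sets` — named list or GMT path of MYC(N)-up gene sets;
#'   * `cq`, `annotations` — Cq matrix / TSV and sample-annotation sidecar
#'     (progression stage);
#'   * `signature` — optional data frame `mirna_id`, `direction`;
#'   * `induction_expr`, `induction_groups` — optional matrix plus a list
#'     `list(treated = , control = )` of column ids (induction stage).
#' @param config A [pipeline_config()].
#' @return A list of class `"mirmycn_pipeline"` with the per-stage outputs
#'   (`scores`, `seed_enrichment`, `correlations`, `activity`, `relevance`,
#'   `progression`, `signature_scores`, `induction`, `dynamics_ks`) and
#'   `summary`, the stage-count accounting (see [integration_summary()]).
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs$screen_plates)) stop("inputs$screen_plates is required")

  plates <- resolve_input(inputs$screen_plates, read_screen_plates)
  scores <- score_screen(plates)
  scores <- call_hits(scores, config$cutoff)
  hits <- scores$mirna_id[scores$hit]

  out <- list(config = config, scores = scores, hits = hits)

  utr <- resolve_input(inputs$utr, function(p) read_fasta_sequences(p)[[1L]])
  mirna_seqs <- resolve_input(inputs$mirna_seqs, read_fasta_sequences)
  if (!is.null(utr) && !is.null(mirna_seqs)) {
    classes <- classify_seed_sites(utr, mirna_seqs)
    out$seed_classes <- classes
    out$seed_enrichment <- seed_class_enrichment(scores, classes)
  }

  mirna_expr <- resolve_input(inputs$mirna_expr, read_expression_matrix)
  mrna_expr <- resolve_input(inputs$mrna_expr, read_expression_matrix)
  gene_sets <- resolve_input(inputs$gene_sets, read_gmt)
  if (!is.null(mirna_expr) && !is.null(mrna_expr)) {
    if (!"MYCN" %in% rownames(mrna_expr)) {
      stop("expression stage: mRNA matrix needs a 'MYCN' row")
    }
    out$correlations <- correlate_to_mycn(
      mirna_expr, mrna_expr["MYCN", ],
      method = config$correlation_method, q_threshold = config$q_threshold
    )
    act <- NULL
    if (!is.null(gene_sets)) {
      hit_rows <- intersect(hits, rownames(mirna_expr))
      if (length(hit_rows) > 0L) {
        act <- activity_calls(
          mirna_expr[hit_rows, , drop = FALSE], mrna_expr, gene_sets,
          n_permutations = config$gsea_permutations, seed = config$seed,
          method = config$correlation_method
        )
        out$activity <- act
      }
    }
    expr_calls <- out$correlations[out$correlations$mirna_id %in% rownames(mirna_expr), ]
    act_calls <- if (is.null(act)) {
      data.frame(mirna_id = character(), activity_call = character(),
                 stringsAsFactors = FALSE)
    } else {
      act$calls
    }
    out$relevance <- classify_relevance(hits, expr_calls, act_calls)
  }

  cq <- resolve_input(inputs$cq, read_expression_matrix)
  annotations <- resolve_input(inputs$annotations, read_sample_annotations)
  if (!is.null(cq) && !is.null(annotations)) {
    expr <- preprocess_cq(cq)
    out$progression <- fit_genotype_time_regression(
      expr, annotations, q_threshold = config$q_threshold
    )
    relevant <- if (!is.null(out$relevance)) {
      out$relevance$mirna_id[out$relevance$final == "NB-relevant MYCN-targeting"]
    } else {
      hits
    }
    both <- intersect(relevant, out$progression$mirna_id)
    if (length(both) >= 2L &&
        sum(!out$progression$mirna_id %in% both) >= 2L) {
      out$dynamics_ks <- compare_target_vs_nontarget_dynamics(
        out$progression, both
      )
    }
    if (!is.null(inputs$signature)) {
      out$signature_scores <- signature_score(expr, inputs$signature)
    }
  }

  if (!is.null(inputs$induction_expr) && !is.null(inputs$induction_groups)) {
    g <- inputs$induction_groups
    out$induction <- differential_expression(
      resolve_input(inputs$induction_expr, read_expression_matrix),
      g$treated, g$control, q_threshold = config$q_threshold
    )
  }

  out$summary <- integration_summary(out)
  class(out) <- "mirmycn_pipeline"
  out
}

#' Stage-count accounting of a pipeline run
#'
#' Counts miRNAs at each stage of the cascade: screened, hits, hits with
#' expression data, inversely / positively correlated (final relevance
#' classes), downregulated / upregulated in the murine progression model
#' among the relevant set, and repressed / induced in the induction model.
#' The relevance classes partition the hits.
#'
#' @param results Pipeline results list (see [run_pipeline()]).
#' @return A named list of counts (`NA` for stages that were not run).
#' @export
integration_summary <- function(results) {
  hits <- results$hits
  rel <- results$relevance
  counts <- list(
    screened = nrow(results$scores),
    hits = length(hits),
    with_expression_data = NA_integer_,
    inverse_correlated = NA_integer_,
    positive_correlated = NA_integer_,
    conflicting_excluded = NA_integer_,
    not_supported = NA_integer_,
    no_data = NA_integer_,
    mouse_down = NA_integer_,
    mouse_up = NA_integer_,
    induction_repressed = NA_integer_,
    induction_induced = NA_integer_
  )
  if (!is.null(rel)) {
    counts$with_expression_data <- sum(rel$final != "no-data")
    counts$inverse_correlated <- sum(rel$final == "NB-relevant MYCN-targeting")
    counts$positive_correlated <- sum(rel$final == "MYCN-induced")
    counts$conflicting_excluded <- sum(rel$final == "conflicting-excluded")
    counts$not_supported <- sum(rel$final == "not-supported")
    counts$no_data <- sum(rel$final == "no-data")
  }
  if (!is.null(results$progression)) {
    relevant <- if (!is.null(rel)) {
      rel$mirna_id[rel$final == "NB-relevant MYCN-targeting"]
    } else {
      hits
    }
    prog <- results$progression
    prog_rel <- prog[prog$mirna_id %in% relevant, ]
    counts$mouse_down <- sum(prog_rel$call == "down")
    positive <- if (!is.null(rel)) rel$mirna_id[rel$final == "MYCN-induced"] else character()
    counts$mouse_up <- sum(prog$call[prog$mirna_id %in% positive] == "up")
  }
  if (!is.null(results$induction)) {
    counts$induction_repressed <- sum(results$induction$call == "down")
    counts$induction_induced <- sum(results$induction$call == "up")
  }
  counts
}

#' @export
print.mirmycn_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Integrative miRNA-MYCN pipeline\n")
  cat(sprintf("  screened miRNAs:      %d\n", s$screened))
  cat(sprintf("  screen hits (< %.3g): %d\n", x$config$cutoff, s$hits))
  if (!is.na(s$with_expression_data)) {
    cat(sprintf("  with expression data: %d\n", s$with_expression_data))
    cat(sprintf("  inverse to MYCN:      %d\n", s$inverse_correlated))
    cat(sprintf("  positive to MYCN:     %d\n", s$positive_correlated))
  }
  if (!is.na(s$mouse_down)) {
    cat(sprintf("  down in progression:  %d\n", s$mouse_down))
  }
  invisible(x)
}

# Small stable hash (polynomial rolling hash over the deparsed object) used
# to stamp reports.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write pipeline reports
#'
#' Writes every available stage output as TSV plus the integration summary as
#' JSON. Each TSV starts with comment lines carrying the package version, the
#' configuration hash and the seed, so reports are self-describing; re-running
#' on the same results produces byte-identical files.
#'
#' @param results A `mirmycn_pipeline` object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  stamp <- c(
    sprintf("# mirmycn %s", as.character(utils::packageVersion("mirmycn"))),
    sprintf("# config_hash: %s", config_hash(results$config)),
    sprintf("# seed: %s", results$config$seed)
  )
  write_stage <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(stamp, con)
    suppressWarnings( # the column header intentionally follows the stamp
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    )
    path
  }
  files <- character()
  tables <- list(
    interaction_scores = results$scores,
    seed_classes = results$seed_classes,
    correlations = results$correlations,
    relevance = results$relevance,
    progression = results$progression,
    signature_scores = results$signature_scores,
    induction = results$induction
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) files <- c(files, write_stage(tables[[nm]], nm))
  }
  summary_path <- file.path(dir, "integration_summary.json")
  payload <- list(
    package_version = as.character(utils::packageVersion("mirmycn")),
    config_hash = config_hash(results$config),
    seed = results$config$seed,
    stages_run = names(tables)[!vapply(tables, is.null, logical(1))],
    stages_not_run = names(tables)[vapply(tables, is.null, logical(1))],
    counts = results$summary
  )
  jsonlite::write_json(payload, summary_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(c(files, summary_path))
}
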