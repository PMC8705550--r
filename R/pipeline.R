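#' Default pipeline configuration
#'
#' Every constant of the procedure lives here with its standard value: the
#' GWAS intake gate (p < 1e-5), the proxy LD threshold (r2 > 0.7) and
#' window (1 Mb), the consequence CADD-Phred cutoff (> 15), the MHC
#' interval (chr6:27-33 Mb, GRCh37), the five-criterion scoring constants
#' (genome-wide significance 5e-8, OR > 1.2, the LD bins, top fraction
#' 0.25, reference threshold 20), the drug-selection rules (statuses,
#' interaction score > 0.50) and the ADME thresholds.
#'
#' @param gwas,qtl,panel,pathways paths to the four required inputs.
#' @param consequences,drugs,adme optional input paths (`NULL` to skip the
#'   corresponding evidence or stage).
#' @param out_dir directory for stage outputs and the JSON run report.
#' @param ... overrides for any default parameter listed above.
#' @return a nested list of class `"oxiscore_config"`.
#' @export
pipeline_config <- function(gwas, qtl, panel, pathways,
                            consequences = NULL, drugs = NULL, adme = NULL,
                            out_dir = tempfile("oxiscore_run_"), ...) {
  cfg <- list(
    inputs = list(gwas = gwas, qtl = qtl, panel = panel,
                  pathways = pathways, consequences = consequences,
                  drugs = drugs, adme = adme),
    out_dir = out_dir,
    p_max = 1e-5,
    r2_min = 0.7,
    window_bp = 1e6,
    cadd_min = 15,
    mhc_interval = c(27e6, 33e6),
    mhc_genes = character(0),
    exclude_all_mhc_evidence = TRUE,
    gw_sig_p = 5e-8,
    or_threshold = 1.2,
    top_fraction = 0.25,
    score_threshold = 20,
    tissue = "brain",
    drug_statuses = c("approved", "phase1", "phase2", "phase3"),
    experimental_statuses = "experimental",
    interaction_score_min = 0.50,
    adme = unclass(adme_thresholds()))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "oxiscore_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors [pipeline_config()]: an `inputs` object with the file
#' paths plus any parameter overrides at the top level. Relative input
#' paths are resolved against the JSON file's directory.
#'
#' @param path JSON file.
#' @return an `"oxiscore_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$inputs)) stop("config lacks an 'inputs' object",
                                call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p) || p == "") return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  ins <- lapply(raw$inputs, resolve)
  args <- c(list(gwas = ins$gwas, qtl = ins$qtl, panel = ins$panel,
                 pathways = ins$pathways,
                 consequences = ins$consequences, drugs = ins$drugs,
                 adme = ins$adme),
            raw[setdiff(names(raw), c("inputs"))])
  if (!is.null(args$out_dir)) args$out_dir <- resolve(args$out_dir)
  do.call(pipeline_config, args)
}

# all declared builds must agree; NULL/NA builds are tolerated
check_builds <- function(...) {
  builds <- unlist(lapply(list(...), get_build))
  builds <- builds[!is.na(builds)]
  if (length(unique(builds)) > 1L) {
    stop("genome build mismatch across inputs: ",
         paste(unique(builds), collapse = " vs "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full repositioning pipeline
#'
#' Executes the stages in order: read and gate the GWAS hits, expand LD
#' proxies against the panel, map gene targets from QTL and filtered
#' consequence evidence (excluding MHC genes), intersect with the pathway
#' universe, score and select the top quantile, call directions of effect
#' in the configured tissue, then (when drug inputs are given) filter the
#' drug table on the prioritized genes and gate survivors by ADME rules,
#' separately for the repurposable (approved / clinical-trial) and
#' experimental tracks. All intermediate tables and a JSON report land in
#' `config$out_dir`. The run is deterministic given the inputs.
#'
#' @param config an `"oxiscore_config"` from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a JSON configuration.
#' @return an `"oxiscore_report"`: list with `counts` (the funnel),
#'   `threshold` (realized selection threshold), `config`, `paths`,
#'   `results` (the in-memory stage outputs) and `audit_ok` (row-count
#'   reconciliation of every written table).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "oxiscore_config"))
  ins <- config$inputs
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  hits <- stage("read_gwas", read_gwas_hits(ins$gwas, p_max = config$p_max))
  counts$hits <- nrow(hits)
  counts$hits_dropped_by_p <- attr(hits, "n_dropped")

  panel <- stage("read_panel", read_panel(ins$panel))
  qtls <- stage("read_qtl", read_qtl_table(ins$qtl))
  cons <- NULL
  counts$consequences_kept <- 0L
  if (!is.null(ins$consequences)) {
    cons_all <- stage("read_consequences", read_consequences(
      ins$consequences))
    cons <- stage("consequence_filter",
                  consequence_filter(cons_all, cadd_min = config$cadd_min))
    counts$consequences_kept <- nrow(cons)
    counts$consequences_dropped <- attr(cons, "n_dropped")
    check_builds(hits, panel, qtls, cons_all)
  } else {
    check_builds(hits, panel, qtls)
  }

  proxies <- stage("expand_proxies",
                   expand_proxies(panel, hits, r2_min = config$r2_min,
                                  window_bp = config$window_bp))
  counts$proxy_pairs <- nrow(proxies)

  targets <- stage("map_targets", map_targets(
    hits, proxies, qtls, cons,
    mhc_genes = config$mhc_genes,
    mhc_interval = config$mhc_interval,
    exclude_all_mhc_evidence = config$exclude_all_mhc_evidence))
  counts$gene_targets <- nrow(targets$summary)
  counts$mhc_excluded <- nrow(targets$excluded)

  pathways <- stage("read_pathways", read_pathways_gmt(ins$pathways))
  shared <- stage("overlap", overlap_targets(targets, pathways))
  counts$shared_targets <- nrow(shared$summary)

  scfg <- score_config(gw_sig_p = config$gw_sig_p,
                       or_threshold = config$or_threshold,
                       top_fraction = config$top_fraction,
                       score_threshold = config$score_threshold,
                       brain_tissue = config$tissue,
                       mhc_interval = config$mhc_interval)
  scores <- stage("score", score_targets(shared, scfg))
  scores <- stage("select", select_top(scores, scfg))
  prioritized <- scores$gene[scores$selected]
  counts$prioritized <- length(prioritized)
  threshold <- attr(scores, "threshold")

  directions <- stage("directions", call_directions(shared,
                                                    tissue = config$tissue))
  counts$direction_calls <- nrow(directions)
  counts$direction_conflicts <- sum(directions$conflict)

  results <- list(hits = hits, proxies = proxies, targets = targets,
                  shared = shared, scores = scores,
                  directions = directions)

  if (!is.null(ins$drugs)) {
    drugs <- stage("read_drugs", read_drug_table(ins$drugs))
    counts$drug_records <- nrow(drugs)
    th <- do.call(adme_thresholds, as.list(config$adme))
    profiles <- if (!is.null(ins$adme)) {
      stage("read_adme", read_adme_table(ins$adme))
    } else NULL
    gate <- function(selected) {
      if (is.null(profiles)) return(selected)
      prof <- stage("adme", adme_pass(profiles, th))
      m <- match(selected$drug, prof$compound)
      ok <- !is.na(m) & prof$adme_pass[m]
      out <- selected[ok, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    rep_sel <- stage("filter_drugs", filter_drugs(
      drugs, prioritized, directions, statuses = config$drug_statuses,
      score_min = config$interaction_score_min))
    rep_surv <- gate(rep_sel)
    exp_sel <- stage("filter_drugs_experimental", filter_drugs(
      drugs, prioritized, directions,
      statuses = config$experimental_statuses,
      score_min = config$interaction_score_min))
    exp_surv <- gate(exp_sel)
    counts$repurposable_selected <- nrow(rep_sel)
    counts$repurposable_survivors <- nrow(rep_surv)
    counts$repurposable_targets <- length(unique(rep_surv$target_gene))
    counts$experimental_selected <- nrow(exp_sel)
    counts$experimental_survivors <- nrow(exp_surv)
    results$repurposable <- rep_surv
    results$experimental <- exp_surv
    results$drug_verdicts <- attr(rep_sel, "verdicts")
    if (!is.null(profiles)) results$adme <- adme_pass(profiles, th)
  }

  # -- write stage outputs and the report -------------------------------------
  paths <- list()
  emit <- function(name, df) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    oxi_write_tsv(df, p)
    paths[[name]] <<- p
    p
  }
  emit("proxies", proxies)
  emit("targets", targets$summary)
  emit("shared_targets", shared$summary)
  emit("scores", scores)
  emit("directions", directions)
  if (!is.null(ins$drugs)) {
    emit("repurposable_survivors", results$repurposable)
    emit("experimental_survivors", results$experimental)
    emit("drug_verdicts", results$drug_verdicts)
  }

  # self-audit: every stage count must equal the written table's row count
  audit <- c(
    proxy_pairs = nrow(oxi_read_tsv(paths$proxies)$df) ==
      counts$proxy_pairs,
    shared_targets = nrow(oxi_read_tsv(paths$shared_targets)$df) ==
      counts$shared_targets,
    direction_calls = nrow(oxi_read_tsv(paths$directions)$df) ==
      counts$direction_calls)
  if (!is.null(ins$drugs)) {
    audit <- c(audit, repurposable = nrow(oxi_read_tsv(
      paths$repurposable_survivors)$df) == counts$repurposable_survivors)
  }

  report <- structure(list(counts = counts, threshold = threshold,
                           config = config, paths = paths,
                           results = results, audit_ok = all(audit)),
                      class = "oxiscore_report")
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(counts = counts, threshold = threshold, audit_ok = all(audit),
         thresholds = config[setdiff(names(config),
                                     c("inputs", "out_dir"))],
         outputs = paths),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$paths$report <- json_path
  report
}

#' @export
print.oxiscore_report <- function(x, ...) {
  c0 <- x$counts
  cat("oxiscore run report\n")
  cat(sprintf("  GWAS hits retained:      %d (dropped %d at p >= gate)\n",
              c0$hits, c0$hits_dropped_by_p))
  cat(sprintf("  hit-proxy pairs:         %d\n", c0$proxy_pairs))
  cat(sprintf("  gene targets:            %d (%d MHC-excluded)\n",
              c0$gene_targets, c0$mhc_excluded))
  cat(sprintf("  pathway-shared targets:  %d\n", c0$shared_targets))
  cat(sprintf("  prioritized (top %d%%):   %d at threshold >= %s\n",
              round(100 * x$config$top_fraction), c0$prioritized,
              format(x$threshold)))
  cat(sprintf("  direction calls:         %d (%d conflict)\n",
              c0$direction_calls, c0$direction_conflicts))
  if (!is.null(c0$drug_records)) {
    cat(sprintf("  repurposable survivors:  %d over %d target(s)\n",
                c0$repurposable_survivors, c0$repurposable_targets))
    cat(sprintf("  experimental survivors:  %d\n",
                c0$experimental_survivors))
  }
  if (!x$audit_ok) cat("  WARNING: report/file row-count audit failed\n")
  invisible(x)
}
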