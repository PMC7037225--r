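# End-to-end driver: DEGs -> promoter scanning -> enrichment -> composite
# module -> master regulators, run independently for the up- and
# down-regulated gene sets, with deterministic seeding and file-only
# stage boundaries.

#' Build and validate a pipeline configuration
#'
#' Defaults equal the published analysis parameters wherever one is
#' printed: DEG cut-offs `logFC > 0.7` / `< -0.7` at `p < 0.05`,
#' enrichment cutoff adjusted `p < 0.01`, search radius 12, 1000
#' permutations, FDR 0.05.
#'
#' @param counts,design,promoters,pwms,network Input file paths (counts
#'   TSV + design TSV, promoter FASTA, TRANSFAC matrix file, edge-list
#'   TSV).
#' @param out_dir Output run directory (created if needed).
#' @param degs Optional path to a pre-computed DEG TSV (columns
#'   `gene_id`, `logFC`, `p_value`), bypassing the internal test.
#' @param condition_a,condition_b Condition labels compared by the DE
#'   stage.
#' @param theta_up,theta_down,alpha DEG cut-offs.
#' @param mss_cutoff,css_cutoff Scan cutoffs.
#' @param adj_cut Enrichment selection cutoff.
#' @param no_max_ratio Optional cap of the No set at `no_max_ratio` times
#'   the Yes set (seeded downsampling; `NULL` = keep all).
#' @param tf_source Which motif set feeds the master-regulator stage:
#'   the enriched PWMs, the composite-module members, or their union
#'   (default).
#' @param ga_params Composite-module GA hyperparameter overrides.
#' @param radius,n_permutations,fdr_cut Master-regulator search
#'   parameters.
#' @param seed Global integer seed; all stage seeds derive from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts, design, promoters, pwms, network,
                            out_dir, degs = NULL,
                            condition_a = "control",
                            condition_b = "treatment",
                            theta_up = 0.7, theta_down = -0.7,
                            alpha = 0.05, mss_cutoff = 0.85,
                            css_cutoff = 0.90, adj_cut = 0.01,
                            no_max_ratio = NULL,
                            tf_source = c("union", "enriched", "module"),
                            ga_params = list(), radius = 12L,
                            n_permutations = 1000L, fdr_cut = 0.05,
                            seed = 1L) {
  tf_source <- match.arg(tf_source)
  paths <- c(counts = counts, design = design, promoters = promoters,
             pwms = pwms, network = network)
  if (!is.null(degs)) paths <- c(paths, degs = degs)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing input file: ", missing[[1L]], call. = FALSE)
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 degs = degs, condition_a = condition_a,
                 condition_b = condition_b, theta_up = theta_up,
                 theta_down = theta_down, alpha = alpha,
                 mss_cutoff = mss_cutoff, css_cutoff = css_cutoff,
                 adj_cut = adj_cut, no_max_ratio = no_max_ratio,
                 tf_source = tf_source, ga_params = ga_params,
                 radius = as.integer(radius),
                 n_permutations = as.integer(n_permutations),
                 fdr_cut = fdr_cut, seed = as.integer(seed)),
            class = "pipeline_config")
}

# internal: run one stage with an informative error prefix
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full upstream-analysis pipeline
#'
#' Executes differential expression, promoter scanning, enrichment,
#' composite-module search and the master-regulator search, separately
#' for the up- and down-regulated gene sets, writing all stage outputs
#' and a `manifest.json` into the run directory. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`degs`, `deg_sets`, `hits`, and per-direction `enrichment`,
#'   `module`, `master_regulators`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)

  degs <- run_stage("diffexpr", {
    if (!is.null(config$degs)) {
      d <- read.delim(config$degs, comment.char = "#")
      stopifnot(all(c("gene_id", "logFC", "p_value") %in% colnames(d)))
      d
    } else {
      cm <- read_counts(config$paths$counts, config$paths$design)
      test_de(cm, config$condition_a, config$condition_b)
    }
  })
  sets <- filter_degs(degs, config$theta_up, config$theta_down,
                      config$alpha)
  call_of <- ifelse(degs$gene_id %in% sets$up_set, "up",
                    ifelse(degs$gene_id %in% sets$down_set, "down",
                           "none"))
  write_output_tsv(data.frame(gene_id = degs$gene_id, logFC = degs$logFC,
                              p_value = degs$p_value, call = call_of),
                   outp("degs.tsv"),
                   list(stage = "diffexpr", seed = config$seed,
                        theta_up = config$theta_up,
                        theta_down = config$theta_down,
                        alpha = config$alpha))

  promoters <- run_stage("io", read_fasta(config$paths$promoters))
  pwms <- run_stage("io", read_transfac_matrices(config$paths$pwms))
  network <- run_stage("io", read_network(config$paths$network))

  hits <- run_stage("site_scan",
                    scan_promoters(promoters, pwms, config$mss_cutoff,
                                   config$css_cutoff))
  write_output_tsv(as.data.frame(hits), outp("hits.tsv"),
                   list(stage = "site_scan",
                        mss_cutoff = config$mss_cutoff,
                        css_cutoff = config$css_cutoff))

  prom_len <- max(nchar(promoters$sequence))
  results <- list(degs = degs, deg_sets = sets, hits = hits)
  for (dirn in c("up", "down")) {
    yes <- intersect(sets[[paste0(dirn, "_set")]], promoters$gene_id)
    no <- intersect(sets$no_set, promoters$gene_id)
    if (!is.null(config$no_max_ratio) &&
        length(no) > config$no_max_ratio * length(yes)) {
      set.seed(config$seed + 1L)
      no <- sort(sample(no, config$no_max_ratio * length(yes)))
    }
    if (length(yes) < 2L) {
      warning("direction '", dirn, "': fewer than 2 Yes promoters; ",
              "skipped", call. = FALSE)
      next
    }
    enr <- run_stage(paste0("enrichment_", dirn), {
      tab <- site_frequency_table(hits, yes, no, names(pwms))
      tfbs_enrichment(tab, config$adj_cut)
    })
    write_output_tsv(as.data.frame(enr),
                     outp(paste0("enrichment_", dirn, ".tsv")),
                     list(stage = "enrichment", direction = dirn,
                          adj_cut = config$adj_cut))
    enriched <- select_enriched(enr, config$adj_cut)
    module <- NULL
    if (length(enriched) >= 1L) {
      module <- run_stage(paste0("cma_", dirn),
        optimize_module(enriched, hits, yes, no,
                        ga_params = config$ga_params,
                        seed = config$seed +
                          if (dirn == "up") 2L else 3L,
                        promoter_length = prom_len))
      jsonlite::write_json(
        list(members = module$members, window = module$window,
             p_value = module$p_value, fitness = module$fitness),
        outp(paste0("module_", dirn, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    tf_names <- switch(config$tf_source,
                       enriched = enriched,
                       module = if (is.null(module)) character()
                                else module$members$pwm,
                       union = union(enriched,
                                     if (is.null(module)) character()
                                     else module$members$pwm))
    tf_set <- intersect(tf_names, network$tf_nodes)
    mr <- NULL
    if (length(tf_set) >= 1L) {
      mr <- run_stage(paste0("masterreg_", dirn),
        find_master_regulators(
          network, tf_set,
          mr_params(radius = config$radius,
                    n_permutations = config$n_permutations,
                    fdr_cut = config$fdr_cut,
                    seed = config$seed +
                      if (dirn == "up") 4L else 5L),
          direction = dirn))
      write_output_tsv(as.data.frame(mr),
                       outp(paste0("master_regulators_", dirn, ".tsv")),
                       list(stage = "master_regulators",
                            direction = dirn, radius = config$radius,
                            n_permutations = config$n_permutations,
                            fdr_cut = config$fdr_cut,
                            seed = config$seed))
    }
    results[[dirn]] <- list(yes = yes, no = no, enrichment = enr,
                            module = module, master_regulators = mr)
  }

  manifest <- list(
    tool = "upstreamx",
    version = as.character(utils::packageVersion("upstreamx")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("paths", "out_dir"))],
    inputs = config$paths)
  manifest$parameter_hash <- local({
    tmp <- tempfile()
    on.exit(unlink(tmp))
    jsonlite::write_json(manifest$parameters, tmp, auto_unbox = TRUE,
                         digits = NA, null = "null")
    unname(tools::md5sum(tmp))
  })
  jsonlite::write_json(manifest, outp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
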