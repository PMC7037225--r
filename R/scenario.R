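# Fully planted end-to-end study generator: counts with planted DEGs,
# promoters of up-/down-regulated genes carrying motifs of dedicated TF
# sets, and a signaling network with a planted regulator wired upstream
# of the up-TFs. Written as pipeline input files so the whole analysis
# can be exercised, and recovery judged, without any external data.

# internal: sharp consensus PWM from a DNA string
consensus_matrix <- function(name, s, pseudocount = 0.01) {
  b <- strsplit(toupper(s), "")[[1L]]
  m <- matrix(0, length(b), 4L)
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- 20
  pwm(name, m, pseudocount = pseudocount)
}

# internal: rename nodes of a signaling network under a named map
rename_nodes <- function(net, map) {
  ren <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
  signaling_network(data.frame(source = ren(net$edges$source),
                               target = ren(net$edges$target),
                               stringsAsFactors = FALSE),
                    tf_nodes = ren(net$tf_nodes),
                    nodes = ren(net$nodes))
}

#' Simulate a complete planted upstream-analysis study
#'
#' Generates every input the pipeline needs, with a known ground truth
#' chained through all three stages: genes with planted log fold
#' changes; promoters of up- (down-) regulated genes enriched for the
#' binding motifs of a dedicated up-TF (down-TF) set; and a signaling
#' network in which one planted regulator sits within a few steps
#' upstream of the up-TF set. Motif names double as network TF node ids,
#' which is how the promoter stage hands its TF set to the network
#' stage.
#'
#' @param out_dir Directory the input files are written to.
#' @param seed Integer seed controlling every stage.
#' @param n_genes,n_reps_per_group,frac_de,planted_lfc,dispersion Count
#'   simulator settings (see [simulate_counts()]).
#' @param n_up_tfs,n_down_tfs,n_bg_pwms Sizes of the motif library
#'   parts: up-planted TFs, down-planted TFs, unplanted background
#'   motifs.
#' @param site_rate,bg_site_rate Expected planted sites per promoter in
#'   the targeted and untargeted promoter sets.
#' @param n_nodes,n_tfs,edge_density,max_planted_radius Network
#'   simulator settings (see [simulate_network()]); the planted radius
#'   defaults to 1 here (direct regulator-to-TF edges), the strongest
#'   planting, so end-to-end recovery is judged against an unambiguous
#'   truth even when the promoter stage recovers only part of the TF
#'   set.
#' @return List with the written file `paths`, the `truth` (DE genes,
#'   planted sites, planted regulator and its distances), and the
#'   `tf_names` of the up/down motif sets.
#' @export
simulate_study <- function(out_dir, seed = 13L, n_genes = 400L,
                           n_reps_per_group = 3L, frac_de = 0.2,
                           planted_lfc = 2, dispersion = 0.1,
                           n_up_tfs = 12L, n_down_tfs = 4L,
                           n_bg_pwms = 2L, site_rate = 4,
                           bg_site_rate = 0.1, n_nodes = 300L,
                           n_tfs = 30L, edge_density = 0.005,
                           max_planted_radius = 1L) {
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  up_tfs <- sprintf("TF%02d", seq_len(n_up_tfs))
  down_tfs <- sprintf("DTF%02d", seq_len(n_down_tfs))
  bg_pwms <- sprintf("BG%02d", seq_len(n_bg_pwms))

  # distinct sharp 10-bp motifs
  set.seed(seed)
  all_names <- c(up_tfs, down_tfs, bg_pwms)
  cons <- replicate(length(all_names),
                    paste(sample(c("A", "C", "G", "T"), 10L, TRUE),
                          collapse = ""))
  while (anyDuplicated(cons))
    cons[duplicated(cons)] <- replicate(sum(duplicated(cons)),
                                        paste(sample(c("A", "C", "G",
                                                       "T"), 10L, TRUE),
                                              collapse = ""))
  lib <- setNames(lapply(seq_along(all_names), function(i)
    consensus_matrix(all_names[[i]], cons[[i]])), all_names)

  # stage 1 truth: counts with planted directions
  cs <- simulate_counts(n_genes = n_genes,
                        n_reps_per_group = n_reps_per_group,
                        frac_de = frac_de, planted_lfc = planted_lfc,
                        dispersion = dispersion, seed = seed + 1L)
  de <- cs$truth$de_genes
  up_genes <- de$gene_id[de$direction == "up"]
  down_genes <- de$gene_id[de$direction == "down"]
  other <- setdiff(rownames(cs$counts$counts),
                   c(up_genes, down_genes))

  # stage 2 truth: motif planting by direction
  p_up <- simulate_promoters(up_genes, pwm_library = lib,
                             yes_genes = up_genes,
                             site_rate_yes = site_rate,
                             site_rate_no = 0, plant_pwms = up_tfs,
                             seed = seed + 2L)
  p_down <- simulate_promoters(down_genes, pwm_library = lib,
                               yes_genes = down_genes,
                               site_rate_yes = site_rate,
                               site_rate_no = 0, plant_pwms = down_tfs,
                               seed = seed + 3L)
  p_bg <- simulate_promoters(other, pwm_library = lib,
                             yes_genes = character(),
                             site_rate_yes = bg_site_rate,
                             site_rate_no = bg_site_rate,
                             seed = seed + 4L)
  promoters <- promoter_set(
    c(p_up$promoters$gene_id, p_down$promoters$gene_id,
      p_bg$promoters$gene_id),
    c(p_up$promoters$sequence, p_down$promoters$sequence,
      p_bg$promoters$sequence))
  planted_sites <- rbind(p_up$truth$planted_sites,
                         p_down$truth$planted_sites,
                         p_bg$truth$planted_sites)

  # stage 3 truth: network with the planted regulator upstream of the
  # up-TF set; active TF nodes take the up-TF motif names, a further
  # n_down_tfs TF nodes take the down-TF names
  ns <- simulate_network(n_nodes = n_nodes, n_tfs = n_tfs,
                         edge_density = edge_density,
                         planted_mr_count = 1L,
                         max_planted_radius = max_planted_radius,
                         n_active_tfs = n_up_tfs,
                         seed = seed + 5L)
  active <- ns$truth$active_tfs
  spare <- setdiff(ns$network$tf_nodes, active)[seq_len(n_down_tfs)]
  map <- setNames(c(up_tfs, down_tfs), c(active, spare))
  net <- rename_nodes(ns$network, map)
  regs <- ns$truth$planted_regulators
  regs$tf <- unname(map[regs$tf])
  planted_node <- unique(regs$node)

  paths <- list(counts = file.path(out_dir, "counts.tsv"),
                design = file.path(out_dir, "design.tsv"),
                promoters = file.path(out_dir, "promoters.fa"),
                pwms = file.path(out_dir, "pwms.transfac"),
                network = file.path(out_dir, "network.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_counts(cs$counts, paths$counts, paths$design)
  write_fasta(promoters, paths$promoters)
  write_transfac_matrices(lib, paths$pwms)
  write_network(net, paths$network)
  truth <- list(seed = seed, up_genes = up_genes,
                down_genes = down_genes,
                planted_sites = planted_sites,
                planted_regulator = planted_node,
                regulator_distances = regs,
                up_tfs = up_tfs, down_tfs = down_tfs)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  list(paths = paths, truth = truth,
       tf_names = list(up = up_tfs, down = down_tfs))
}
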