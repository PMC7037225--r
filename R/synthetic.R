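# Simulators with planted ground truth. Each generator is a pure function
# of its parameters and seed, and returns (object, sim_truth).

new_sim_truth <- function(de_genes = NULL, planted_sites = NULL,
                          planted_regulators = NULL, active_tfs = NULL) {
  structure(list(de_genes = de_genes, planted_sites = planted_sites,
                 planted_regulators = planted_regulators,
                 active_tfs = active_tfs),
            class = "sim_truth")
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Counts are drawn as `NB(mu, 1/dispersion)` with
#' `mu_gs = lib_size_s * q_g * 2^(+-lfc)` for planted DE genes in the
#' treatment group (sign drawn per gene) and `mu_gs = lib_size_s * q_g`
#' otherwise; `dispersion = 0` gives Poisson counts. Gene abundances
#' `q_g` are log-normal, normalized to sum to one.
#'
#' @param n_genes Number of genes (default 2000; a scaled-down working
#'   size, see the vignette).
#' @param n_reps_per_group Replicates per condition (default 3, the
#'   donor-replicate design the pipeline assumes).
#' @param frac_de Fraction of genes with a planted fold change.
#' @param planted_lfc Absolute planted log2 fold change (>= 0).
#' @param dispersion Common NB dispersion (>= 0).
#' @param lib_size_range Range library sizes are drawn uniformly from.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return `list(counts = count_matrix, truth = sim_truth)`.
#' @export
simulate_counts <- function(n_genes = 2000L, n_reps_per_group = 3L,
                            frac_de = 0.1, planted_lfc = 1,
                            dispersion = 0.1,
                            lib_size_range = c(2e5, 4e5), seed = 1L) {
  stopifnot(n_reps_per_group >= 2L, dispersion >= 0, planted_lfc >= 0)
  if (frac_de < 0 || frac_de > 1) stop("frac_de outside [0,1]", call. = FALSE)
  rng <- local_rng(seed)
  q <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  q <- q / sum(q)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_de <- round(frac_de * n_genes)
  de_idx <- if (n_de > 0L) sort(sample.int(n_genes, n_de)) else integer(0)
  dir <- if (n_de > 0L) sample(c(1, -1), n_de, replace = TRUE) else numeric(0)
  samples <- c(paste0("ctrl_", seq_len(n_reps_per_group)),
               paste0("trt_", seq_len(n_reps_per_group)))
  cond <- setNames(rep(c("control", "treatment"), each = n_reps_per_group),
                   samples)
  lib <- runif(length(samples), lib_size_range[[1L]], lib_size_range[[2L]])
  fc <- rep(1, n_genes)
  fc[de_idx] <- 2^(dir * planted_lfc)
  m <- matrix(0L, n_genes, length(samples),
              dimnames = list(genes, samples))
  for (s in seq_along(samples)) {
    mu <- lib[[s]] * q * (if (cond[[s]] == "treatment") fc else 1)
    m[, s] <- if (dispersion == 0) rpois(n_genes, mu)
              else rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  truth_de <- data.frame(
    gene_id = genes[de_idx],
    direction = if (n_de > 0L) ifelse(dir > 0, "up", "down") else character(0),
    lfc = dir * planted_lfc, stringsAsFactors = FALSE)
  list(counts = count_matrix(m, cond),
       truth = new_sim_truth(de_genes = truth_de))
}

#' Simulate promoter sequences with planted binding sites
#'
#' Background is an i.i.d. base model at the given GC content. The number
#' of planted sites per promoter is Poisson with rate `site_rate_yes` for
#' genes in `yes_genes` and `site_rate_no` otherwise; each planted site is
#' sampled base-by-base from the column distributions of a PWM drawn from
#' `plant_pwms`, at a uniform position on a uniform strand.
#'
#' @param gene_ids Promoter identifiers.
#' @param length Promoter length in bp (default 1100: -1000..+100).
#' @param gc Background GC content (default 0.5, a promoter-like value).
#' @param pwm_library Named list of `pwm` objects.
#' @param yes_genes Genes receiving the elevated planting rate.
#' @param site_rate_yes,site_rate_no Expected planted sites per promoter
#'   (`site_rate_yes >= site_rate_no >= 0`).
#' @param plant_pwms Names of the PWMs sites are planted from
#'   (default: all of `pwm_library`).
#' @param seed Integer seed.
#' @return `list(promoters = promoter_set, truth = sim_truth)`.
#' @export
simulate_promoters <- function(gene_ids, length = 1100L, gc = 0.5,
                               pwm_library, yes_genes = character(),
                               site_rate_yes = 2, site_rate_no = 0.2,
                               plant_pwms = names(pwm_library), seed = 1L) {
  stopifnot(site_rate_yes >= site_rate_no, site_rate_no >= 0,
            gc >= 0, gc <= 1, length >= 1L)
  if (is.null(names(pwm_library)))
    names(pwm_library) <- vapply(pwm_library, `[[`, character(1), "name")
  maxL <- max(vapply(pwm_library[plant_pwms], function(p) nrow(p$counts),
                     integer(1)))
  if (maxL > length) stop("planted site longer than promoter", call. = FALSE)
  rng <- local_rng(seed)
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- c("A", "C", "G", "T")
  seqs <- character(base::length(gene_ids))
  sites <- list()
  for (g in seq_along(gene_ids)) {
    chars <- sample(bases, length, replace = TRUE, prob = base_prob)
    rate <- if (gene_ids[[g]] %in% yes_genes) site_rate_yes else site_rate_no
    n_sites <- rpois(1L, rate)
    for (k in seq_len(n_sites)) {
      pname <- if (base::length(plant_pwms) == 1L) plant_pwms else
        sample(plant_pwms, 1L)
      f <- pwm_freq(pwm_library[[pname]])
      L <- nrow(f)
      site <- vapply(seq_len(L),
                     function(i) sample(bases, 1L, prob = f[i, ]),
                     character(1))
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-")
        site <- rev(c(A = "T", C = "G", G = "C", T = "A")[site])
      pos <- sample.int(length - L + 1L, 1L) - 1L   # 0-based
      chars[(pos + 1L):(pos + L)] <- site
      sites[[base::length(sites) + 1L]] <-
        data.frame(gene_id = gene_ids[[g]], pwm_name = pname,
                   position = pos, strand = strand,
                   stringsAsFactors = FALSE)
    }
    seqs[[g]] <- paste(chars, collapse = "")
  }
  planted <- if (base::length(sites) == 0L)
    data.frame(gene_id = character(), pwm_name = character(),
               position = integer(), strand = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, sites)
  list(promoters = promoter_set(gene_ids, seqs),
       truth = new_sim_truth(planted_sites = planted))
}

#' Simulate a directed signaling network with planted master regulators
#'
#' The background is an Erdos-Renyi directed acyclic graph on a fixed
#' topological order, with TF nodes placed at the downstream end. Each
#' planted regulator receives directed paths of length at most
#' `max_planted_radius` to at least 80% (by default 90%) of a designated
#' active-TF set; planted paths may create cycles. The truth records the
#' realized shortest directed distances from each planted regulator to
#' each active TF.
#'
#' @param n_nodes,n_tfs Number of nodes and TF nodes.
#' @param edge_density Probability of each admissible (order-respecting)
#'   background edge; must be in `[0,1]`.
#' @param planted_mr_count Number of planted regulators (>= 1).
#' @param max_planted_radius Maximum planted path length (<= 12).
#' @param n_active_tfs Size of the designated active-TF set.
#' @param covered_frac Fraction of active TFs each planted regulator is
#'   wired to (>= 0.8).
#' @param seed Integer seed.
#' @return `list(network = signaling_network, truth = sim_truth)`.
#' @export
simulate_network <- function(n_nodes = 300L, n_tfs = 30L,
                             edge_density = 0.005, planted_mr_count = 1L,
                             max_planted_radius = 3L, n_active_tfs = 12L,
                             covered_frac = 0.9, seed = 1L) {
  stopifnot(max_planted_radius <= 12L, max_planted_radius >= 1L,
            planted_mr_count >= 1L, n_tfs < n_nodes,
            n_active_tfs <= n_tfs, covered_frac >= 0.8, covered_frac <= 1)
  if (edge_density < 0 || edge_density > 1)
    stop("requested density incompatible with acyclicity constraint",
         call. = FALSE)
  rng <- local_rng(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  # TFs are the last n_tfs nodes in topological order
  tfs <- nodes[(n_nodes - n_tfs + 1L):n_nodes]
  # background DAG: edge i -> j allowed iff i < j in the order
  src <- integer(0); tgt <- integer(0)
  for (i in seq_len(n_nodes - 1L)) {
    js <- which(rbinom(n_nodes - i, 1L, edge_density) == 1L) + i
    src <- c(src, rep(i, length(js))); tgt <- c(tgt, js)
  }
  active <- sort(sample(tfs, n_active_tfs))
  non_tf <- setdiff(nodes, tfs)
  planted <- sample(non_tf[seq_len(min(length(non_tf), 50L))],
                    planted_mr_count)
  n_cover <- ceiling(covered_frac * n_active_tfs)
  # planted wiring mimics a genuine master regulator: short paths to many
  # active TFs, partly direct and partly through shared relay nodes, so
  # its decayed reach is large without an excessive out-degree
  for (pr in planted) {
    targets <- sample(active, n_cover)
    if (max_planted_radius == 1L) {
      n_direct <- n_cover
    } else {
      n_direct <- ceiling(n_cover / 2)
    }
    for (tf in targets[seq_len(n_direct)]) {
      src <- c(src, match(pr, nodes)); tgt <- c(tgt, match(tf, nodes))
    }
    rest <- targets[-seq_len(n_direct)]
    if (length(rest) > 0L) {
      relays <- sample(setdiff(non_tf, planted),
                       ceiling(length(rest) / 4))
      for (j in seq_along(rest)) {
        rl <- relays[[((j - 1L) %% length(relays)) + 1L]]
        src <- c(src, match(pr, nodes), match(rl, nodes))
        tgt <- c(tgt, match(rl, nodes), match(rest[[j]], nodes))
      }
    }
  }
  edges <- unique(data.frame(source = nodes[src], target = nodes[tgt],
                             stringsAsFactors = FALSE))
  net <- signaling_network(edges, tf_nodes = tfs, nodes = nodes)
  # realized shortest distances planted -> active TFs (forward BFS)
  adj <- split(edges$target, edges$source)
  reg_rows <- list()
  for (pr in planted) {
    d <- bfs_levels(adj, pr, nodes)
    for (tf in active)
      if (is.finite(d[[tf]]))
        reg_rows[[length(reg_rows) + 1L]] <-
          data.frame(node = pr, tf = tf, distance = d[[tf]],
                     stringsAsFactors = FALSE)
  }
  list(network = net,
       truth = new_sim_truth(
         planted_regulators = do.call(rbind, reg_rows),
         active_tfs = active))
}

# internal: BFS levels over an adjacency list (named list of character
# vectors); returns named numeric distances with Inf for unreached
bfs_levels <- function(adj, start, nodes) {
  d <- setNames(rep(Inf, length(nodes)), nodes)
  d[[start]] <- 0
  frontier <- start
  depth <- 0
  while (length(frontier) > 0L) {
    depth <- depth + 1
    nxt <- unique(unlist(adj[intersect(frontier, names(adj))],
                         use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    if (length(nxt) == 0L) break
    d[nxt] <- depth
    frontier <- nxt
  }
  d
}

# internal: deterministic RNG initialization for the generators
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
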