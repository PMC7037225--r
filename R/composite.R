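# Composite-module analysis: windowed co-occurrence scoring of motif
# combinations (max 10 members, 200-300 bp window) optimized by a seeded
# genetic algorithm against the Wilcoxon separation of Yes vs No
# promoter scores.

#' One-sided Wilcoxon rank-sum separation of Yes over No scores
#'
#' Tests the alternative that Yes scores are stochastically larger. For
#' groups both smaller than 8 the p-value is computed by exact
#' enumeration of rank assignments (valid under ties); otherwise a normal
#' approximation with tie and continuity correction is used. If all
#' pooled scores are identical the p-value is 1.
#'
#' @param yes_scores,no_scores Non-empty numeric score vectors.
#' @return `list(p_value =, fitness =)` with `fitness = -log10(p)`.
#' @export
wilcoxon_fitness <- function(yes_scores, no_scores) {
  stopifnot(length(yes_scores) > 0L, length(no_scores) > 0L)
  n1 <- length(yes_scores); n2 <- length(no_scores); n <- n1 + n2
  pooled <- c(yes_scores, no_scores)
  if (length(unique(pooled)) == 1L)
    return(list(p_value = 1, fitness = 0))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  if (n1 < 8L && n2 < 8L) {
    sets <- combn(n, n1)
    w_all <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(w_all >= w_obs - 1e-9)
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(pooled)
    s2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (s2 <= 0) return(list(p_value = 1, fitness = 0))
    p <- pnorm((w_obs - mu - 0.5) / sqrt(s2), lower.tail = FALSE)
    p <- min(1, max(p, .Machine$double.xmin))
  }
  list(p_value = p, fitness = -log10(p))
}

# internal: CSR hit index over a fixed promoter list and PWM universe.
# Returns list(off, start, member) with `member` the 1-based PWM index.
build_hit_index <- function(hits, gene_ids, pwm_names) {
  keep <- hits$gene_id %in% gene_ids & hits$pwm %in% pwm_names
  h <- hits[keep, , drop = FALSE]
  gi <- match(h$gene_id, gene_ids)
  o <- order(gi, h$start)
  h <- h[o, , drop = FALSE]; gi <- gi[o]
  counts <- tabulate(gi, nbins = length(gene_ids))
  list(off = c(0L, cumsum(counts)),
       start = as.integer(h$start),
       member = match(h$pwm, pwm_names))
}

#' Windowed co-occurrence score of a composite module per promoter
#'
#' The score of a promoter is the maximum over window start positions of
#' the weighted sum over module members of `min(hits in window,
#' max_count)`; promoters with no member hits score 0.
#'
#' @param promoter_hits A `tfbs_hits` data.frame.
#' @param module A `composite_module` (or list with `members` data.frame
#'   columns `pwm`, `weight`, `max_count`, and `window`).
#' @param gene_ids Promoters to score (zero-hit promoters included).
#' @param promoter_length Promoter length in bp (default 1100).
#' @return Named numeric vector of scores, one per `gene_ids`.
#' @export
module_score <- function(promoter_hits, module, gene_ids,
                         promoter_length = 1100L) {
  members <- module$members
  stopifnot(nrow(members) >= 1L)
  idx <- build_hit_index(promoter_hits, gene_ids, members$pwm)
  sc <- cpp_module_scores(idx$off, idx$start, ifelse(is.na(idx$member),
                                                     0L, idx$member),
                          as.numeric(members$weight),
                          as.integer(members$max_count),
                          as.integer(module$window),
                          as.integer(promoter_length))
  setNames(sc, gene_ids)
}

#' @export
print.composite_module <- function(x, ...) {
  cat(sprintf(
    "composite_module: %d member(s), window %d bp, p = %.3g (fitness %.2f)\n",
    nrow(x$members), x$window, x$p_value, x$fitness))
  print(x$members, row.names = FALSE)
  invisible(x)
}

# default GA hyperparameters
default_ga_params <- function() {
  list(pop_size = 50L, generations = 100L, tournament_k = 3L,
       crossover_p = 0.5, mutation_p = 0.1, max_members = 10L,
       window_range = c(200L, 300L), max_count_range = 1:3,
       complexity_penalty = 0.05)
}

#' Genetic-algorithm search for the best composite module
#'
#' The genome is (member subset of at most `max_members` PWMs, per-member
#' weight in `[0,1]` and saturation count, window width in
#' `window_range`). Fitness is the Wilcoxon separation of Yes over No
#' promoter scores minus a small complexity penalty per member;
#' tournament selection, uniform crossover, per-field mutation, elitism
#' of one. Fully deterministic given `seed`.
#'
#' @param enriched_pwms Character vector of candidate PWM names.
#' @param hits A `tfbs_hits` data.frame covering both promoter sets.
#' @param yes_genes,no_genes Promoter id sets being separated.
#' @param ga_params Hyperparameter list, see `default_ga_params` values
#'   in the description; partial lists are merged over the defaults.
#' @param seed Integer seed.
#' @param promoter_length Promoter length in bp.
#' @return A `composite_module` with members, window, `p_value`,
#'   `fitness` (`-log10 p`, unpenalized) and the per-generation best
#'   penalized fitness in attribute `history`.
#' @export
optimize_module <- function(enriched_pwms, hits, yes_genes, no_genes,
                            ga_params = list(), seed = 1L,
                            promoter_length = 1100L) {
  stopifnot(length(enriched_pwms) >= 1L)
  gp <- utils::modifyList(default_ga_params(), ga_params)
  if (gp$max_members < 1L || gp$max_members > 10L)
    stop("max_members must be in 1..10", call. = FALSE)
  if (gp$window_range[[1L]] < 200L || gp$window_range[[2L]] > 300L ||
      gp$window_range[[1L]] > gp$window_range[[2L]])
    stop("window_range must lie within [200, 300]", call. = FALSE)
  set.seed(as.integer(seed))
  K <- length(enriched_pwms)
  cap <- min(gp$max_members, K)
  yes_idx <- build_hit_index(hits, yes_genes, enriched_pwms)
  no_idx <- build_hit_index(hits, no_genes, enriched_pwms)
  windows <- gp$window_range[[1L]]:gp$window_range[[2L]]
  mcr <- gp$max_count_range

  evaluate <- function(ind) {
    w <- ifelse(ind$incl, ind$w, 0)
    ys <- cpp_module_scores(yes_idx$off, yes_idx$start, yes_idx$member,
                            w, ind$mc, ind$W, promoter_length)
    ns <- cpp_module_scores(no_idx$off, no_idx$start, no_idx$member,
                            w, ind$mc, ind$W, promoter_length)
    wf <- wilcoxon_fitness(ys, ns)
    list(p = wf$p_value, raw = wf$fitness,
         fit = wf$fitness - gp$complexity_penalty * sum(ind$incl))
  }
  repair <- function(ind) {
    k <- sum(ind$incl)
    if (k == 0L) ind$incl[[sample.int(K, 1L)]] <- TRUE
    if (k > cap) {
      on <- which(ind$incl)
      ind$incl[sample(on, k - cap)] <- FALSE
    }
    ind
  }
  random_ind <- function() {
    incl <- rep(FALSE, K)
    incl[sample.int(K, sample.int(min(3L, cap), 1L))] <- TRUE
    list(incl = incl, w = runif(K), mc = sample(mcr, K, replace = TRUE),
         W = sample(windows, 1L))
  }
  mutate <- function(ind) {
    flip <- runif(K) < gp$mutation_p
    ind$incl[flip] <- !ind$incl[flip]
    rw <- runif(K) < gp$mutation_p
    ind$w[rw] <- runif(sum(rw))
    rm_ <- runif(K) < gp$mutation_p
    ind$mc[rm_] <- sample(mcr, sum(rm_), replace = TRUE)
    if (runif(1L) < gp$mutation_p) ind$W <- sample(windows, 1L)
    repair(ind)
  }
  crossover <- function(a, b) {
    take <- runif(K) < gp$crossover_p
    child <- a
    child$incl[take] <- b$incl[take]
    child$w[take] <- b$w[take]
    child$mc[take] <- b$mc[take]
    if (runif(1L) < gp$crossover_p) child$W <- b$W
    repair(child)
  }

  pop <- replicate(gp$pop_size, random_ind(), simplify = FALSE)
  evals <- lapply(pop, evaluate)
  fits <- vapply(evals, `[[`, numeric(1), "fit")
  history <- numeric(gp$generations)
  for (gen in seq_len(gp$generations)) {
    elite <- which.max(fits)
    newpop <- vector("list", gp$pop_size)
    newpop[[1L]] <- pop[[elite]]
    for (i in 2:gp$pop_size) {
      t1 <- sample.int(gp$pop_size, gp$tournament_k)
      t2 <- sample.int(gp$pop_size, gp$tournament_k)
      a <- pop[[t1[which.max(fits[t1])]]]
      b <- pop[[t2[which.max(fits[t2])]]]
      newpop[[i]] <- mutate(crossover(a, b))
    }
    pop <- newpop
    evals <- lapply(pop, evaluate)
    fits <- vapply(evals, `[[`, numeric(1), "fit")
    history[[gen]] <- max(fits)
  }
  best <- which.max(fits)
  ind <- pop[[best]]
  members <- data.frame(pwm = enriched_pwms[ind$incl],
                        weight = ind$w[ind$incl],
                        max_count = ind$mc[ind$incl],
                        stringsAsFactors = FALSE)
  structure(list(members = members, window = ind$W,
                 p_value = evals[[best]]$p,
                 fitness = evals[[best]]$raw),
            class = "composite_module",
            history = history, seed = seed)
}
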