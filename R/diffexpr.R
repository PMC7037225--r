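# Differential expression: median-of-ratios size factors, a conditional
# negative-binomial exact test with a common method-of-moments dispersion,
# and the logFC / p-value cut-off filter that defines the Yes/No sets.

#' Median-of-ratios size factors
#'
#' The reference is the per-gene geometric mean over genes with all
#' positive counts; each sample's factor is the median count/reference
#' ratio, rescaled so the factors have geometric mean one. If no gene has
#' all-positive counts the total-count factors are used instead, with a
#' warning.
#'
#' @param counts A `count_matrix` or plain counts matrix.
#' @return Named numeric vector of size factors, one per sample.
#' @export
normalize_size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(all(colSums(m) > 0))
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warning("no gene with all-positive counts; using total-count factors",
            call. = FALSE)
    sf <- colSums(m)
  } else {
    ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
    sf <- apply(m[pos, , drop = FALSE], 2L, function(k) median(k / ref))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

# internal: common dispersion by method of moments on normalized counts.
# Per gene, alpha_g = (v - mbar) / mbar^2 with v the pooled within-group
# variance of normalized counts; the common value is the median of the
# finite per-gene estimates floored at zero.
estimate_common_dispersion <- function(norm, group) {
  groups <- unique(group)
  mbar <- rowMeans(norm)
  v <- rowMeans(sapply(groups, function(g)
    apply(norm[, group == g, drop = FALSE], 1L, var)))
  alpha <- (v - mbar) / mbar^2
  alpha <- alpha[is.finite(alpha) & mbar > 0]
  if (length(alpha) == 0L) return(0)
  max(0, median(alpha))
}

#' Negative-binomial exact test for two conditions
#'
#' For each gene the two group sums are modeled as negative binomial with
#' a common method-of-moments dispersion and means proportional to the
#' summed size factors; the two-sided p-value is the conditional
#' probability, given the total, of outcomes at most as likely as the one
#' observed. `logFC` is `log2` of the ratio of mean normalized counts
#' with a pseudo-count of 0.5 in both numerator and denominator. Genes
#' with zero counts everywhere are retained with `logFC = 0`, `p = 1`.
#'
#' @param counts A `count_matrix`.
#' @param condition_a,condition_b Condition labels; `logFC > 0` means
#'   higher expression in `condition_b`.
#' @return A `deg_table` data.frame with columns `gene_id`, `logFC`,
#'   `p_value`, `mean_expr`; the estimated dispersion and size factors
#'   are attached as attributes.
#' @export
test_de <- function(counts, condition_a = "control",
                    condition_b = "treatment") {
  stopifnot(inherits(counts, "count_matrix"))
  cond <- counts$condition_of
  sel_a <- names(cond)[cond == condition_a]
  sel_b <- names(cond)[cond == condition_b]
  if (length(sel_a) < 2L || length(sel_b) < 2L)
    stop("need >= 2 replicates per condition", call. = FALSE)
  m <- counts$counts[, c(sel_a, sel_b), drop = FALSE]
  sf <- normalize_size_factors(count_matrix(m, cond[c(sel_a, sel_b)]))
  norm <- sweep(m, 2L, sf, `/`)
  group <- cond[colnames(m)]
  alpha <- estimate_common_dispersion(norm, group)
  mean_a <- rowMeans(norm[, sel_a, drop = FALSE])
  mean_b <- rowMeans(norm[, sel_b, drop = FALSE])
  logfc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  ka <- rowSums(m[, sel_a, drop = FALSE])
  kb <- rowSums(m[, sel_b, drop = FALSE])
  sfa <- sf[sel_a]; sfb <- sf[sel_b]
  p <- vapply(seq_len(nrow(m)), function(g)
    nb_exact_p(ka[[g]], kb[[g]], sfa, sfb, alpha), numeric(1))
  zero <- ka + kb == 0
  logfc[zero] <- 0
  p[zero] <- 1
  res <- data.frame(gene_id = rownames(m), logFC = unname(logfc),
                    p_value = unname(p),
                    mean_expr = unname((mean_a + mean_b) / 2),
                    stringsAsFactors = FALSE)
  structure(res, class = c("deg_table", "data.frame"),
            dispersion = alpha, size_factors = sf,
            conditions = c(condition_a, condition_b))
}

# internal: conditional NB exact test on group sums.
# Under the null the common concentration q is estimated from the total;
# each group sum is NB with mean q * sum(sf) and a size parameter matched
# to the variance of a sum of per-sample NB counts. The two-sided p-value
# sums the conditional probabilities of all splits of the total that are
# no more likely than the observed one.
nb_exact_p <- function(ka, kb, sfa, sfb, alpha) {
  ks <- ka + kb
  if (ks == 0) return(1)
  q <- ks / (sum(sfa) + sum(sfb))
  mua <- q * sum(sfa); mub <- q * sum(sfb)
  dens <- function(x, mu, mu2sum) {
    if (alpha == 0) return(dpois(x, mu))
    size <- mu^2 / (alpha * mu2sum)
    dnbinom(x, mu = mu, size = size)
  }
  mu2a <- sum((q * sfa)^2); mu2b <- sum((q * sfb)^2)
  k <- 0:ks
  pk <- dens(k, mua, mu2a) * dens(ks - k, mub, mu2b)
  tot <- sum(pk)
  if (tot <= 0) return(1)
  pobs <- pk[[ka + 1L]]
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]) / tot)
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("deg_table: %d genes (%s vs %s), common dispersion %.4g\n",
              nrow(x), attr(x, "conditions")[[1L]],
              attr(x, "conditions")[[2L]], attr(x, "dispersion")))
  NextMethod()
}

#' Partition genes into up / down / background sets by cut-offs
#'
#' Inequalities are strict, matching the printed thresholds: up-regulated
#' means `logFC > theta_up` and `p < alpha`; down-regulated means
#' `logFC < theta_down` and `p < alpha`. Everything else forms the
#' "No" background set used by the enrichment stage.
#'
#' @param table A `deg_table` (or data.frame with `gene_id`, `logFC`,
#'   `p_value`).
#' @param theta_up,theta_down logFC thresholds (defaults 0.7 / -0.7).
#' @param alpha p-value threshold (default 0.05).
#' @return `list(up_set =, down_set =, no_set =)` of gene-id character
#'   vectors partitioning the gene universe.
#' @export
filter_degs <- function(table, theta_up = 0.7, theta_down = -0.7,
                        alpha = 0.05) {
  stopifnot(theta_down < 0, theta_up > 0)
  up <- table$logFC > theta_up & table$p_value < alpha
  down <- table$logFC < theta_down & table$p_value < alpha
  list(up_set = table$gene_id[up],
       down_set = table$gene_id[down],
       no_set = table$gene_id[!up & !down])
}
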