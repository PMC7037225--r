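# Yes/No site-frequency comparison per PWM: Fisher exact enrichment with
# Benjamini-Hochberg control.

#' Tabulate per-PWM site frequencies in Yes and No promoter sets
#'
#' By default "frequency" is promoter presence/absence: a promoter counts
#' as hit for a PWM if it carries at least one site for it, which makes
#' the downstream Fisher test exactly valid. A per-bp site-density
#' variant (`stat = "density"`) counts sites against total scanned bp
#' instead.
#'
#' @param hits A `tfbs_hits` data.frame.
#' @param yes_genes,no_genes Disjoint gene-id sets.
#' @param pwm_names PWMs to tabulate (default: all seen in `hits`).
#' @param stat `"presence"` (default) or `"density"`.
#' @param promoter_length Promoter length in bp, used by the density
#'   variant only.
#' @return An `enrichment_table` data.frame (p-values unfilled).
#' @export
site_frequency_table <- function(hits, yes_genes, no_genes,
                                 pwm_names = NULL, stat = c("presence",
                                                            "density"),
                                 promoter_length = 1100L) {
  stat <- match.arg(stat)
  stopifnot(length(intersect(yes_genes, no_genes)) == 0L)
  if (is.null(pwm_names)) pwm_names <- sort(unique(hits$pwm))
  known <- hits$gene_id %in% c(yes_genes, no_genes)
  hits <- hits[known, , drop = FALSE]
  rows <- lapply(pwm_names, function(pn) {
    h <- hits[hits$pwm == pn, , drop = FALSE]
    if (stat == "presence") {
      yh <- length(intersect(unique(h$gene_id), yes_genes))
      nh <- length(intersect(unique(h$gene_id), no_genes))
      yt <- length(yes_genes); nt <- length(no_genes)
    } else {
      yh <- sum(h$gene_id %in% yes_genes)
      nh <- sum(h$gene_id %in% no_genes)
      yt <- length(yes_genes) * promoter_length
      nt <- length(no_genes) * promoter_length
    }
    data.frame(pwm_name = pn, yes_hit = yh, yes_total = yt,
               no_hit = nh, no_total = nt, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(pwm_name = character(), yes_hit = integer(),
                      yes_total = integer(), no_hit = integer(),
                      no_total = integer(), stringsAsFactors = FALSE)
  yes_rate <- tab$yes_hit / tab$yes_total
  no_rate <- tab$no_hit / tab$no_total
  tab$fold <- ifelse(no_rate == 0, ifelse(yes_rate == 0, NA_real_, Inf),
                     yes_rate / no_rate)
  structure(tab, class = c("enrichment_table", "data.frame"),
            stat = stat)
}

#' One-sided Fisher exact test for enrichment in the Yes set
#'
#' Tests the 2x2 table `[yes_hit, yes_miss; no_hit, no_miss]` against the
#' alternative of a higher hit rate in the Yes set.
#'
#' @param yes_hit,yes_total,no_hit,no_total Table margins.
#' @return One-sided p-value.
#' @export
enrich_test <- function(yes_hit, yes_total, no_hit, no_total) {
  stopifnot(yes_total > 0, no_total > 0,
            yes_hit <= yes_total, no_hit <= no_total)
  m <- matrix(c(yes_hit, yes_total - yes_hit,
                no_hit, no_total - no_hit), 2L, byrow = TRUE)
  fisher.test(m, alternative = "greater")$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_i = min_{j >= rank(i)} m * p_(j) / j`, capped at one, returned in
#' the input order.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  p.adjust(p, method = "BH")
}

#' Run the enrichment test over a site-frequency table
#'
#' @param tab An `enrichment_table` from [site_frequency_table()].
#' @param adj_cut Adjusted-p selection cutoff (default 0.01, strict `<`).
#' @return The table with `p_value`, `adj_p` and logical `selected`
#'   columns filled in.
#' @export
tfbs_enrichment <- function(tab, adj_cut = 0.01) {
  if (nrow(tab) == 0L) {
    tab$p_value <- numeric(0); tab$adj_p <- numeric(0)
    tab$selected <- logical(0)
    return(tab)
  }
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i)
    enrich_test(tab$yes_hit[[i]], tab$yes_total[[i]],
                tab$no_hit[[i]], tab$no_total[[i]]), numeric(1))
  tab$adj_p <- bh_adjust(tab$p_value)
  tab$selected <- tab$adj_p < adj_cut
  attr(tab, "adj_cut") <- adj_cut
  tab
}

#' Names of enriched PWMs
#'
#' @param tab An `enrichment_table` with `adj_p` filled in.
#' @param adj_cut Strict adjusted-p cutoff (default 0.01).
#' @return Character vector of PWM names, sorted by `adj_p` then name.
#' @export
select_enriched <- function(tab, adj_cut = 0.01) {
  sel <- tab[tab$adj_p < adj_cut, , drop = FALSE]
  sel <- sel[order(sel$adj_p, sel$pwm_name), , drop = FALSE]
  sel$pwm_name
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table (%s): %d PWMs", attr(x, "stat"), nrow(x)))
  if (!is.null(x$selected)) cat(sprintf(", %d selected", sum(x$selected)))
  cat("\n")
  NextMethod()
}
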