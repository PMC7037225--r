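# Shared fixture builders: everything is generated in code at test time.

# a sharp PWM whose consensus is `s` (count 20 for the consensus base)
consensus_pwm <- function(name, s, pseudocount = 0.01) {
  b <- strsplit(toupper(s), "")[[1]]
  m <- matrix(0, length(b), 4)
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- 20
  pwm(name, m, pseudocount = pseudocount)
}

# a random PWM of length L (positive Dirichlet-ish counts)
random_pwm <- function(name, L, seed) {
  set.seed(seed)
  pwm(name, matrix(rgamma(L * 4, shape = 0.5) + 0.05, L, 4))
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# independent naive scanner: scores every window of every promoter on
# both strands with match_score (the single-window entry point), keeping
# windows that pass both cutoffs
naive_scan <- function(promoters, pwms, mss_cutoff = 0.85,
                       css_cutoff = 0.90) {
  rows <- list()
  for (pn in names(pwms)) {
    L <- nrow(pwms[[pn]]$counts)
    for (g in seq_len(nrow(promoters))) {
      s <- promoters$sequence[[g]]
      if (nchar(s) < L) next
      for (st in 0:(nchar(s) - L)) {
        win <- substr(s, st + 1, st + L)
        for (strand in c("+", "-")) {
          w <- if (strand == "+") win else revcomp_chr(win)
          sc <- suppressWarnings(match_score(pwms[[pn]], w))
          if (!anyNA(sc) && sc[["mss"]] >= mss_cutoff &&
              sc[["css"]] >= css_cutoff)
            rows[[length(rows) + 1]] <- data.frame(
              gene_id = promoters$gene_id[[g]], pwm = pn, start = st,
              strand = strand, mss = sc[["mss"]], css = sc[["css"]],
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), pwm = character(),
                      start = integer(), strand = character(),
                      mss = numeric(), css = numeric())
  out[order(out$gene_id, out$pwm, out$start, out$strand), , drop = FALSE]
}

# brute-force module score over every window start (independent of the
# compiled path)
brute_module_score <- function(hits, module, gene_ids, prom_len = 1100) {
  W <- module$window
  vapply(gene_ids, function(g) {
    h <- hits[hits$gene_id == g & hits$pwm %in% module$members$pwm, ,
              drop = FALSE]
    if (nrow(h) == 0) return(0)
    best <- 0
    for (s in 0:max(0, prom_len - W)) {
      sc <- 0
      for (m in seq_len(nrow(module$members))) {
        cnt <- sum(h$pwm == module$members$pwm[[m]] &
                     h$start >= s & h$start < s + W)
        sc <- sc + module$members$weight[[m]] *
          min(cnt, module$members$max_count[[m]])
      }
      best <- max(best, sc)
    }
    best
  }, numeric(1))
}

# brute-force BH step-up: adj_(i) = min_{j >= i} m p_(j) / j in sorted
# order, mapped back to input order
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- rev(cummin(rev(m * sorted / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force median-of-ratios size factors
brute_size_factors <- function(m) {
  pos <- apply(m, 1, function(r) all(r > 0))
  ref <- apply(m[pos, , drop = FALSE], 1, function(r)
    exp(mean(log(r))))
  sf <- vapply(seq_len(ncol(m)), function(j)
    median(m[pos, j] / ref), numeric(1))
  sf / exp(mean(log(sf)))
}

# exact one-sided hypergeometric tail for a 2x2 enrichment table
hyper_tail_p <- function(yh, yt, nh, nt) {
  hits <- yh + nh
  sum(vapply(yh:min(yt, hits), function(k)
    choose(yt, k) * choose(nt, hits - k), numeric(1))) /
    choose(yt + nt, hits)
}
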