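test_that("match_score maximizer, minimizer, N handling, brute force", {
  p <- consensus_pwm("M", "ACGTAC", pseudocount = 0.01)
  expect_equal(unname(match_score(p, "ACGTAC")["mss"]), 1)
  # per-position minimizer of a consensus matrix is any non-consensus
  # base (all non-consensus share the pseudocount frequency)
  expect_equal(unname(match_score(p, "CAACCA")["mss"]), 0)
  expect_true(anyNA(match_score(p, "ACGTAN")))

  # random 8-bp PWM vs direct evaluation of the formula
  rp <- random_pwm("R", 8, seed = 3)
  set.seed(3)
  win <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
  f <- pwm_freq(rp)
  info <- rowSums(f * log(4 * f))
  idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
  raw <- sum(info * f[cbind(1:8, idx)])
  mn <- sum(info * apply(f, 1, min)); mx <- sum(info * apply(f, 1, max))
  expect_equal(unname(match_score(rp, win)["mss"]), (raw - mn) / (mx - mn),
               tolerance = 1e-12)
  # css: best 5-wide info block
  blocks <- vapply(1:4, function(s) sum(info[s:(s + 4)]), numeric(1))
  cs <- which.max(blocks); core <- cs:(cs + 4)
  rawc <- sum(info[core] * f[cbind(core, idx[core])])
  mnc <- sum((info * apply(f, 1, min))[core])
  mxc <- sum((info * apply(f, 1, max))[core])
  expect_equal(unname(match_score(rp, win)["css"]),
               (rawc - mnc) / (mxc - mnc), tolerance = 1e-12)
})

test_that("a planted consensus flanked by minimizers yields one + hit", {
  p <- consensus_pwm("M", "ACGTACGGTA")
  # flank with the complement-free minimizer pattern: for a consensus
  # matrix every non-consensus base minimizes, so use a homopolymer that
  # is neither the consensus nor its reverse complement at any offset
  flank <- strrep("A", 30)
  seqs <- paste0(flank, "ACGTACGGTA", flank)
  ps <- promoter_set("g1", seqs)
  hits <- scan_promoters(ps, list(M = p), mss_cutoff = 0.99,
                         css_cutoff = 0.99)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 30L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$end, 40L)
})

test_that("scanner equals the naive reference on synthetic promoters", {
  pwms <- list(A = consensus_pwm("A", "ACGTACGGTA"),
               B = random_pwm("B", 7, seed = 5),
               C = random_pwm("C", 11, seed = 6))
  sp <- simulate_promoters(sprintf("g%02d", 1:12), length = 120,
                           pwm_library = pwms,
                           yes_genes = sprintf("g%02d", 1:6),
                           site_rate_yes = 2, site_rate_no = 0.5,
                           plant_pwms = c("A", "B"), seed = 8)
  # cutoffs chosen off the k/L score lattice of consensus matrices so
  # the two code paths cannot disagree on floating-point boundary ties
  got <- scan_promoters(sp$promoters, pwms, mss_cutoff = 0.77,
                        css_cutoff = 0.83)
  ref <- naive_scan(sp$promoters, pwms, mss_cutoff = 0.77,
                    css_cutoff = 0.83)
  expect_equal(nrow(got), nrow(ref))
  expect_equal(got$gene_id, ref$gene_id)
  expect_equal(got$start, ref$start)
  expect_equal(got$strand, ref$strand)
  expect_equal(got$mss, ref$mss, tolerance = 1e-9)
  expect_equal(got$css, ref$css, tolerance = 1e-9)
})

test_that("reverse-complementing promoters swaps strands, reflects starts", {
  pwms <- list(B = random_pwm("B", 7, seed = 5))
  sp <- simulate_promoters(sprintf("g%02d", 1:8), length = 150,
                           pwm_library = pwms,
                           yes_genes = sprintf("g%02d", 1:8),
                           site_rate_yes = 2, seed = 9)
  fwd <- scan_promoters(sp$promoters, pwms, mss_cutoff = 0.8,
                        css_cutoff = 0.8)
  rc <- promoter_set(sp$promoters$gene_id,
                     vapply(sp$promoters$sequence, revcomp_chr,
                            character(1)))
  rev <- scan_promoters(rc, pwms, mss_cutoff = 0.8, css_cutoff = 0.8)
  L <- 7
  key <- function(h, len) paste(h$gene_id, h$pwm,
                                ifelse(h$strand == "+", "-", "+"),
                                len - L - h$start, round(h$mss, 9))
  expect_setequal(key(fwd, 150), paste(rev$gene_id, rev$pwm, rev$strand,
                                       rev$start, round(rev$mss, 9)))
})

test_that("mss is scale invariant and cutoffs act monotonically", {
  rp <- random_pwm("R", 9, seed = 12)
  rp10 <- pwm("R10", rp$counts * 10, pseudocount = rp$pseudocount)
  sp <- simulate_promoters("g1", length = 200,
                           pwm_library = list(R = rp), yes_genes = "g1",
                           site_rate_yes = 2, seed = 13)
  h1 <- scan_promoters(sp$promoters, list(R = rp), 0.7, 0.7)
  h2 <- scan_promoters(sp$promoters, list(R = rp10), 0.7, 0.7)
  expect_equal(h1$mss, h2$mss, tolerance = 1e-12)
  expect_equal(h1$start, h2$start)

  strict <- scan_promoters(sp$promoters, list(R = rp), 0.9, 0.9)
  loose <- scan_promoters(sp$promoters, list(R = rp), 0.7, 0.7)
  expect_true(all(paste(strict$start, strict$strand) %in%
                    paste(loose$start, loose$strand)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("a PWM longer than the promoter warns and yields no hits", {
  p <- random_pwm("L", 30, seed = 2)
  ps <- promoter_set("g1", "ACGTACGTAC")
  expect_warning(h <- scan_promoters(ps, list(L = p)), "longer than")
  expect_equal(nrow(h), 0L)
})
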