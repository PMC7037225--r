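test_that("count simulator honours frac_de, determinism and the null", {
  sim <- simulate_counts(n_genes = 100, n_reps_per_group = 3,
                         frac_de = 0, seed = 1)
  expect_equal(nrow(sim$truth$de_genes), 0L)

  expect_error(simulate_counts(frac_de = 1.2), "frac_de")

  a <- simulate_counts(n_genes = 50, seed = 9)
  b <- simulate_counts(n_genes = 50, seed = 9)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$de_genes, b$truth$de_genes)

  # dispersion 0, no planted fold change: per-gene mean/lib-size ratios
  # agree across groups within Poisson error at n_reps = 50
  sim0 <- simulate_counts(n_genes = 200, n_reps_per_group = 50,
                          frac_de = 0, planted_lfc = 0, dispersion = 0,
                          seed = 4)
  m <- sim0$counts$counts
  grp <- sim0$counts$condition_of
  lib <- colSums(m)
  rate_a <- rowMeans(sweep(m[, grp == "control"], 2,
                           lib[grp == "control"], `/`))
  rate_b <- rowMeans(sweep(m[, grp == "treatment"], 2,
                           lib[grp == "treatment"], `/`))
  # relative error shrinks as 1/sqrt(expected count over 50 reps)
  expect_lt(median(abs(rate_b - rate_a) / (rate_a + rate_b)), 0.05)
})

test_that("promoter simulator plants recoverable sites deterministically", {
  p1 <- consensus_pwm("M1", "ACGTACGGTA")
  none <- simulate_promoters(c("g1", "g2"), pwm_library = list(M1 = p1),
                             yes_genes = "g1", site_rate_yes = 0,
                             site_rate_no = 0, seed = 2)
  expect_equal(nrow(none$truth$planted_sites), 0L)

  a <- simulate_promoters(sprintf("g%02d", 1:10),
                          pwm_library = list(M1 = p1),
                          yes_genes = sprintf("g%02d", 1:5), seed = 3)
  b <- simulate_promoters(sprintf("g%02d", 1:10),
                          pwm_library = list(M1 = p1),
                          yes_genes = sprintf("g%02d", 1:5), seed = 3)
  expect_identical(a$promoters$sequence, b$promoters$sequence)
  expect_identical(a$truth$planted_sites, b$truth$planted_sites)

  expect_error(
    simulate_promoters("g1", length = 5, pwm_library = list(M1 = p1)),
    "longer than promoter")

  # generated promoters satisfy the type invariants
  expect_true(all(nchar(a$promoters$sequence) == 1100L))
  expect_true(all(grepl("^[ACGTN]+$", a$promoters$sequence)))
  expect_true(all(a$truth$planted_sites$position >= 0))
  expect_true(all(a$truth$planted_sites$position + nrow(p1$counts) <= 1100))
})

test_that("scanner recovers planted sharp sites at high rate", {
  p1 <- consensus_pwm("M1", "ACGTACGGTA")
  sp <- simulate_promoters(sprintf("g%03d", 1:200),
                           pwm_library = list(M1 = p1),
                           yes_genes = sprintf("g%03d", 1:200),
                           site_rate_yes = 3, site_rate_no = 0, seed = 1)
  # the recovery claim pins the matrix-score cutoff only; planted sites
  # are column-distribution draws, so a non-consensus base can land in
  # the 5-bp core and fail a strict core cutoff without ever dropping
  # the matrix score below 0.85
  hits <- scan_promoters(sp$promoters, list(M1 = p1), mss_cutoff = 0.85,
                         css_cutoff = 0)
  planted <- sp$truth$planted_sites
  found <- mapply(function(g, pos, strand)
    any(hits$gene_id == g & hits$start == pos & hits$strand == strand),
    planted$gene_id, planted$position, planted$strand)
  expect_gte(mean(found), 0.9)
})

test_that("network simulator wiring matches its recorded truth", {
  # radius 1: planted node has direct edges to >= 80% of active TFs
  sim1 <- simulate_network(planted_mr_count = 1, max_planted_radius = 1,
                           seed = 5)
  pl <- unique(sim1$truth$planted_regulators$node)
  direct <- sim1$network$edges$target[sim1$network$edges$source == pl]
  expect_gte(length(intersect(direct, sim1$truth$active_tfs)),
             ceiling(0.8 * length(sim1$truth$active_tfs)))
  expect_true(all(sim1$truth$planted_regulators$distance == 1))

  # BFS distances from planted node to active TFs equal the recorded
  # truth (independent igraph oracle)
  skip_if_not_installed("igraph")
  sim <- simulate_network(seed = 6)
  g <- igraph::graph_from_data_frame(sim$network$edges, directed = TRUE,
                                     vertices = sim$network$nodes)
  pl <- unique(sim$truth$planted_regulators$node)
  d <- igraph::distances(g, v = pl, to = sim$truth$active_tfs,
                         mode = "out")
  tr <- sim$truth$planted_regulators
  expect_equal(unname(d[1, tr$tf]), tr$distance)
  expect_true(all(tr$distance <= 3))

  # determinism and acyclicity guard
  e1 <- simulate_network(seed = 11)$network$edges
  e2 <- simulate_network(seed = 11)$network$edges
  expect_identical(e1, e2)
  expect_error(simulate_network(edge_density = 1.5), "acyclicity")
})
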