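test_that("module scores: singles, window exclusion, brute force", {
  mod1 <- list(members = data.frame(pwm = "A", weight = 1,
                                    max_count = 1), window = 250L)
  hits <- data.frame(gene_id = "g1", pwm = "A", start = 500L)
  expect_equal(unname(module_score(hits, mod1, "g1")), 1)
  expect_equal(unname(module_score(hits, mod1, c("g1", "g2"))[2]), 0)

  # two members 400 bp apart cannot share a 250 bp window
  mod2 <- list(members = data.frame(pwm = c("A", "B"), weight = c(1, 1),
                                    max_count = c(1, 1)), window = 250L)
  hits2 <- data.frame(gene_id = "g1", pwm = c("A", "B"),
                      start = c(100L, 500L))
  expect_equal(unname(module_score(hits2, mod2, "g1")), 1)
  # brought within the window they do sum
  hits3 <- data.frame(gene_id = "g1", pwm = c("A", "B"),
                      start = c(100L, 300L))
  expect_equal(unname(module_score(hits3, mod2, "g1")), 2)

  # brute-force equality over every window start on synthetic promoters
  set.seed(23)
  genes <- sprintf("g%02d", 1:30)
  hits4 <- data.frame(
    gene_id = sample(genes, 150, TRUE),
    pwm = sample(c("A", "B", "C"), 150, TRUE),
    start = sample(0:1090, 150, TRUE))
  mod3 <- list(members = data.frame(pwm = c("A", "B", "C"),
                                    weight = c(0.9, 0.4, 0.7),
                                    max_count = c(2, 1, 3)),
               window = 220L)
  expect_equal(unname(module_score(hits4, mod3, genes)),
               unname(brute_module_score(hits4, mod3, genes)),
               tolerance = 1e-12)
})

test_that("Wilcoxon separation: exact enumeration and approximation", {
  ex <- wilcoxon_fitness(c(3, 4, 5), c(0, 1, 2))
  expect_equal(ex$p_value, 1 / 20)
  expect_equal(ex$fitness, -log10(1 / 20))

  same <- wilcoxon_fitness(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.5)

  expect_equal(wilcoxon_fitness(c(1, 1), c(1, 1))$p_value, 1)

  # normal approximation within 10% relative error of the exact p on
  # null draws at 10+10 (mid-range p, where the approximation is used)
  set.seed(33)
  sets <- combn(20, 10)
  for (i in 1:10) {
    y <- runif(10); n <- runif(10)
    approx <- wilcoxon_fitness(y, n)$p_value
    # exact enumeration over C(20,10) rank assignments
    r <- rank(c(y, n))
    w_all <- colSums(matrix(r[sets], nrow = 10))
    exact <- mean(w_all >= sum(r[1:10]) - 1e-9)
    expect_lt(abs(approx - exact) / exact, 0.10)
  }
})

test_that("GA finds the singleton optimum with a one-PWM library", {
  p <- consensus_pwm("M1", "ACGTACGGTA")
  yes <- sprintf("y%02d", 1:30); no <- sprintf("n%02d", 1:60)
  sp <- simulate_promoters(c(yes, no), pwm_library = list(M1 = p),
                           yes_genes = yes, site_rate_yes = 2,
                           site_rate_no = 0.1, seed = 3)
  hits <- scan_promoters(sp$promoters, list(M1 = p))
  mod <- optimize_module("M1", hits, yes, no, seed = 1,
                         ga_params = list(generations = 20L))
  expect_equal(mod$members$pwm, "M1")
  expect_gt(mod$fitness, 2)
})

test_that("GA fitness beats every singleton and is monotone in time", {
  pwms <- list(A = consensus_pwm("A", "ACGTACGGTA"),
               B = consensus_pwm("B", "GGATCCGTAT"),
               C = random_pwm("C", 10, seed = 7),
               D = random_pwm("D", 10, seed = 8))
  yes <- sprintf("y%02d", 1:40); no <- sprintf("n%02d", 1:80)
  sp <- simulate_promoters(c(yes, no), pwm_library = pwms,
                           yes_genes = yes, site_rate_yes = 2,
                           site_rate_no = 0.2, plant_pwms = c("A", "B"),
                           seed = 4)
  hits <- scan_promoters(sp$promoters, pwms)
  mod <- optimize_module(names(pwms), hits, yes, no, seed = 2,
                         ga_params = list(generations = 40L))
  # exhaustive singleton sweep at the returned window width
  single_fit <- vapply(names(pwms), function(pn) {
    m <- list(members = data.frame(pwm = pn, weight = 1, max_count = 1),
              window = mod$window)
    wilcoxon_fitness(module_score(hits, m, yes),
                     module_score(hits, m, no))$fitness
  }, numeric(1))
  expect_gte(mod$fitness, max(single_fit) - 1e-9)

  hist <- attr(mod, "history")
  expect_true(all(diff(hist) >= -1e-12))

  # member cap and window range are honoured
  expect_lte(nrow(mod$members), 10L)
  expect_gte(mod$window, 200L)
  expect_lte(mod$window, 300L)

  # determinism
  mod2 <- optimize_module(names(pwms), hits, yes, no, seed = 2,
                          ga_params = list(generations = 40L))
  expect_identical(mod$members, mod2$members)
  expect_identical(mod$fitness, mod2$fitness)
})

test_that("GA parameter validation rejects out-of-range settings", {
  hits <- data.frame(gene_id = "g1", pwm = "A", start = 1L)
  expect_error(optimize_module("A", hits, "g1", "g2",
                               ga_params = list(max_members = 11L)),
               "max_members")
  expect_error(optimize_module("A", hits, "g1", "g2",
                               ga_params = list(window_range = c(100L,
                                                                 300L))),
               "window_range")
})
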