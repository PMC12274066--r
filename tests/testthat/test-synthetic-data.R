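test_that("pure-birth tree simulator meets its contract", {
  tr <- simulate_tree(2, 1, seed = 4)
  expect_equal(length(tr$tip.label), 2)
  d <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(d, c(1, 1))

  expect_identical(write_newick(simulate_tree(12, 1, seed = 9)),
                   write_newick(simulate_tree(12, 1, seed = 9)))

  tr100 <- simulate_tree(100, 1, seed = 2)
  expect_equal(nrow(tr100$edge), 2 * 100 - 2)
  expect_true(ape::is.binary(tr100))
  expect_equal(mean(ape::node.depth.edgelength(tr100)[1:100]), 1)
})

test_that("Brownian simulator matches closed-form moments", {
  tr <- read_newick("(A:1,B:1);")
  # degenerate diffusion: all tips at the root state
  z <- simulate_brownian_traits(tr, matrix(0), mu = 3, seed = 1)
  expect_equal(z$trait1, c(3, 3))

  # Var(x_A - x_B) = 2R on a unit cherry
  R <- 1.7
  diffs <- vapply(1:4000, function(i) {
    s <- simulate_brownian_traits(tr, matrix(R), 0, seed = i)
    s$trait1[1] - s$trait1[2]
  }, numeric(1))
  expect_equal(stats::var(diffs), 2 * R, tolerance = 0.1)

  # independent traits stay uncorrelated on average
  tr2 <- simulate_tree(12, 1, seed = 7)
  cors <- vapply(1:300, function(i) {
    s <- simulate_brownian_traits(tr2, diag(c(1, 1)), c(0, 0), seed = 1000 + i)
    stats::cor(s$trait1, s$trait2)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 * stats::sd(cors) / sqrt(length(cors)) + 0.02)

  expect_error(simulate_brownian_traits(tr, matrix(c(1, 2, 2, 1), 2),
                                        c(0, 0)), "positive semidefinite")
})

test_that("Brownian tip covariance matches C x R on a 3-tip tree", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  R <- 0.8
  tips <- vapply(1:6000, function(i) {
    unlist(simulate_brownian_traits(tr, matrix(R), 0, seed = i)$trait1)
  }, numeric(3))
  S <- stats::cov(t(tips))
  C <- phylo_covariance(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(S), unname(C * R), tolerance = 0.12)
})

test_that("codon alignment simulator honors branch lengths and omega", {
  phi <- balanced_phi()
  m <- codon_model(2, 0.5, phi)
  tr <- read_newick("(A:0,B:0);")
  aln <- simulate_codon_alignment(tr, m, 50, seed = 3)
  expect_identical(aln$sequences[["A"]], aln$sequences[["B"]])

  # omega = 0 forbids amino-acid changes entirely
  tr2 <- read_newick("(A:2,B:2);")
  m0 <- codon_model(2, 0, phi)
  aln0 <- simulate_codon_alignment(tr2, m0, 200, seed = 5)
  gc <- Biostrings::GENETIC_CODE
  aaA <- gc[substring(aln0$sequences[["A"]], seq(1, 598, 3), seq(3, 600, 3))]
  aaB <- gc[substring(aln0$sequences[["B"]], seq(1, 598, 3), seq(3, 600, 3))]
  expect_identical(unname(aaA), unname(aaB))

  expect_identical(simulate_codon_alignment(tr2, m, 30, seed = 8)$sequences,
                   simulate_codon_alignment(tr2, m, 30, seed = 8)$sequences)
})

test_that("codon simulator stays at stationarity on a long branch", {
  phi <- random_phi()
  m <- codon_model(2, 0.3, phi)
  tr <- read_newick("(A:5,B:5);")
  aln <- simulate_codon_alignment(tr, m, 4000, seed = 12)
  sense <- sense_codons()
  obs <- table(factor(substring(aln$sequences[["A"]],
                                seq(1, 3 * 4000 - 2, 3),
                                seq(3, 3 * 4000, 3)), levels = sense))
  freq <- as.numeric(obs) / 4000
  expect_lt(max(abs(freq - m$pi)), 0.02)
})

test_that("TE genome simulator produces consistent truths and annotations", {
  tp <- te_params(n_families = 3, family_ages = c(0, 0.1, 0.5),
                  copies_per_family = 20, copy_length = 400,
                  coverage = 0.5, read_length = 100)
  sim <- simulate_te_genome(tp, genome_size = 1e5, seed = 2)
  expect_equal(sim$true_te_bp, 3 * 20 * 400)
  # age-0 family: divergence exactly 0, all its copies recent
  f0 <- sim$copies[sim$copies$family == 1, ]
  expect_true(all(f0$divergence == 0))
  expect_gte(sim$true_recent_te_bp, sum(f0$length))
  v <- validate_te_annotations(sim$annotations)
  expect_true(all(sim$annotations$annotated_bp %in% c(0, 100)))

  empty <- simulate_te_genome(te_params(n_families = 0), 1e5, seed = 1)
  expect_equal(nrow(empty$annotations), 0)
  expect_equal(empty$true_te_bp, 0)
})

test_that("C-value record generator encodes size-dependent underestimation", {
  sizes <- 10^seq(7, 9, length.out = 40)
  rec0 <- simulate_cvalue_records(sizes, noise_sd = 0, under_coef = 0,
                                  seed = 1)
  expect_equal(rec0$assembly_size, rec0$cvalue * 0.978e9)

  rec <- simulate_cvalue_records(sizes, noise_sd = 0, under_coef = 0.1,
                                 seed = 1)
  ratio <- rec$assembly_size / (rec$cvalue * 0.978e9)
  # ratio falls with genome size
  expect_true(all(diff(ratio) <= 1e-12))
  expect_identical(simulate_cvalue_records(sizes, seed = 3),
                   simulate_cvalue_records(sizes, seed = 3))
})

test_that("scenario bundle is internally consistent and plants the MHH link", {
  sc <- simulation_scenario(n_species = 12, n_genes = 2, n_codons = 60,
                            te = te_params(coverage = 0.25,
                                           copies_per_family = 5),
                            seed = 11)
  b <- generate_scenario(sc)
  expect_setequal(b$traits$species, b$tree$tip.label)
  expect_setequal(names(b$te), b$traits$species)
  expect_setequal(b$cvalue_records$species, b$traits$species)
  for (a in b$alignments) {
    expect_setequal(names(a$sequences), b$traits$species)
  }

  # MHH-true world: omega and TE fraction rise together (negative log_ne
  # link on both channels); check on a large trait-only draw
  sc_true <- simulation_scenario(n_species = 150, seed = 21)
  bt <- generate_scenario(sc_true, simulate_alignments = FALSE,
                          simulate_te_reads = FALSE)
  expect_gt(stats::cor(bt$traits$true_omega, bt$traits$log_te_frac,
                       method = "spearman"), 0)

  # MHH-false world: constant omega everywhere
  sc_false <- simulation_scenario(n_species = 20, omega_link = NULL,
                                  omega = 0.25, seed = 5)
  bf <- generate_scenario(sc_false, simulate_alignments = FALSE,
                          simulate_te_reads = FALSE)
  expect_true(all(bf$traits$true_omega == 0.25))
})
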