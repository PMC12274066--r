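test_that("insertion-heavy sequences are dropped at the strict 10% rule", {
  # 5 species, 40 columns; focal 'x' holds residues in columns where the
  # other four are gapped
  base <- strrep("ATG", 20)   # 60 columns
  gapify <- function(s, cols) {
    v <- strsplit(s, "")[[1]]; v[cols] <- "-"; paste(v, collapse = "")
  }
  n_ins <- function(frac) round(60 * frac)
  mk <- function(frac) {
    ins_cols <- seq_len(n_ins(frac))
    seqs <- c(x = base,
              a = gapify(base, ins_cols), b = gapify(base, ins_cols),
              c = gapify(base, ins_cols), d = gapify(base, ins_cols))
    codon_alignment(seqs, gene = "g")
  }
  flt15 <- filter_insertion_heavy(mk(0.15))
  expect_false("x" %in% names(flt15$sequences))
  flt10 <- filter_insertion_heavy(mk(0.10))
  expect_true("x" %in% names(flt10$sequences))   # exactly 10% retained

  clean <- codon_alignment(c(a = base, b = base, c = base))
  expect_identical(filter_insertion_heavy(clean), clean)
})

test_that("short-branch gene filter keeps the boundary", {
  l <- c(g1 = 0.0005, g2 = 0.001, g3 = 0.02)
  keep <- filter_short_branch_genes(l)
  expect_identical(unname(keep), c(FALSE, TRUE, TRUE))
})

test_that("gene blacklist removes listed genes and warns on unknowns", {
  genes <- c("g1", "g2", "g3", "g4")
  expect_identical(apply_gene_blacklist(genes, NULL), genes)
  bl <- data.frame(clade = c("X", "X", NA), gene = c("g2", "g4", "g1"))
  expect_identical(apply_gene_blacklist(genes, bl, clade = "X"), "g3")
  expect_identical(apply_gene_blacklist(genes, bl, clade = "Y"), c("g2", "g3", "g4"))
  bl2 <- data.frame(clade = NA, gene = "nope")
  expect_warning(out <- apply_gene_blacklist(genes, bl2), "nope")
  expect_identical(out, genes)
})

test_that("species aggregation implements the printed formula verbatim", {
  one <- data.frame(species = "s", K_N = 2, K_S = 2, O_N = 4, O_S = 4,
                    l = 0.5)
  agg <- aggregate_species_dnds(one)
  expect_equal(agg$dN, 0.25)   # 2 / (4 / 0.5)
  expect_equal(agg$dS, 0.25)

  two <- data.frame(species = "s", K_N = c(1, 2), K_S = c(4, 2),
                    O_N = c(2, 3), O_S = c(5, 1), l = c(0.1, 0.4))
  agg2 <- aggregate_species_dnds(two)
  oracle <- brute_aggregate(two$K_N, two$K_S, two$O_N, two$O_S, two$l)
  expect_identical(agg2$dN, oracle$dN)
  expect_identical(agg2$dS, oracle$dS)
  expect_identical(agg2$dnds, oracle$dnds)

  # duplicating all records leaves rates unchanged
  dup <- rbind(two, two)
  aggd <- aggregate_species_dnds(dup)
  expect_equal(aggd$dN, agg2$dN)
  expect_equal(aggd$dS, agg2$dS)

  # random record lists: exact match against the brute-force evaluation
  set.seed(12)
  for (r in 1:20) {
    n <- sample(1:8, 1)
    rec <- data.frame(species = "s",
                      K_N = stats::runif(n, 0, 20),
                      K_S = stats::runif(n, 0, 20),
                      O_N = stats::runif(n, 1, 30),
                      O_S = stats::runif(n, 1, 30),
                      l = stats::runif(n, 0.01, 1))
    agg <- aggregate_species_dnds(rec)
    oracle <- brute_aggregate(rec$K_N, rec$K_S, rec$O_N, rec$O_S, rec$l)
    expect_identical(agg$dnds, oracle$dnds)
  }

  expect_error(aggregate_species_dnds(
    data.frame(species = c("s", "t"), K_N = 1, K_S = 1, O_N = 1, O_S = 1,
               l = 1)), "more than one species")
})

test_that("the counts-only denominator variant differs as documented", {
  rec <- data.frame(species = "s", K_N = c(1, 2), K_S = c(4, 2),
                    O_N = c(2, 3), O_S = c(5, 1), l = c(0.1, 0.4))
  alt <- aggregate_species_dnds(rec, denominator = "counts_only")
  expect_equal(alt$dN, sum(rec$K_N) / sum(rec$O_N))
  expect_equal(alt$dS, sum(rec$K_S) / sum(rec$O_S))
})

test_that("terminal-branch trimming removes saturated and tiny branches", {
  tr <- read_newick("((a:0.2,b:0.3):0.1,(c:0.2,d:0.1):0.3);")
  tab <- data.frame(species = c("a", "b", "c", "d"), dnds = c(0.1, 0.2, 0.3, 0.4))
  aa <- c(a = 1.5, b = 0.5, c = 0.01, d = 0.005)
  out <- trim_terminal_branches(tr, tab, aa)
  expect_setequal(out$table$species, c("b", "c"))   # 0.01 boundary kept
  expect_setequal(out$removed, c("a", "d"))
  # pruning preserves the remaining pairwise path length
  full_d <- ape::cophenetic.phylo(tr)["b", "c"]
  expect_equal(ape::cophenetic.phylo(out$tree)["b", "c"], full_d)
})

test_that("GC3 computation handles pure and mixed compositions", {
  expect_equal(compute_gc3(codon_alignment(c(a = "ATGATC", b = "AAGGGC"))), 1)
  expect_equal(compute_gc3(codon_alignment(c(a = "ATAATT", b = "AAAGGT"))), 0)
  expect_equal(compute_gc3(codon_alignment(c(a = "ATGATT"))), 0.5)
  # gaps at third positions are ignored
  expect_equal(compute_gc3(codon_alignment(c(a = "AT-ATC"))), 1)
})

test_that("GC3 gene-set selection is deterministic and coverage-filtered", {
  set.seed(5)
  gc3 <- stats::setNames(stats::runif(120), sprintf("g%03d", 1:120))
  cov <- stats::setNames(rep(1, 120), names(gc3))
  cov[c("g001", "g002")] <- 0.94   # below the 95% coverage rule
  cfg <- pipeline_config()
  sets <- select_gc3_genesets(gc3, cov, cfg)
  expect_length(sets$poor, 50)
  expect_length(sets$rich, 50)
  expect_length(intersect(sets$poor, sets$rich), 0)
  expect_false(any(c("g001", "g002") %in% c(sets$poor, sets$rich)))
  # permuting the input leaves the sets unchanged
  perm <- sample(120)
  sets2 <- select_gc3_genesets(gc3[perm], cov[perm], cfg)
  expect_identical(sets, sets2)
  # ties broken lexicographically
  gc3_tie <- stats::setNames(rep(c(0.1, 0.9), each = 60), names(gc3))
  sets3 <- suppressWarnings(select_gc3_genesets(gc3_tie, cov, cfg))
  expect_identical(sets3$poor, sort(sets3$poor))
})

test_that("record filters commute", {
  set.seed(8)
  rec <- data.frame(species = rep(c("a", "b"), each = 6),
                    gene = rep(sprintf("g%d", 1:6), 2),
                    K_N = stats::runif(12), K_S = stats::runif(12),
                    O_N = stats::runif(12, 1, 2), O_S = stats::runif(12, 1, 2),
                    l = stats::runif(12, 0.0001, 0.1))
  cfg <- pipeline_config()
  bl <- data.frame(clade = NA, gene = c("g2", "g5"))
  f_branch <- function(r) r[r$l >= cfg$gene_branch_min, , drop = FALSE]
  f_bl <- function(r) r[r$gene %in% apply_gene_blacklist(unique(r$gene), bl), ,
                        drop = FALSE]
  a <- f_bl(f_branch(rec)); b <- f_branch(f_bl(rec))
  expect_identical(a[order(a$species, a$gene), ], b[order(b$species, b$gene), ])
})
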