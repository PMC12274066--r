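#' Simulate a pure-birth time tree
#'
#' Yule tree with the requested number of tips, rescaled so the mean
#' root-to-tip path length equals 1 (the tree is ultrametric in time, so
#' every tip sits at depth 1). A stand-in fixture for an empirical
#' phylogeny; any newick tree can replace it in the pipeline.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate per unit time.
#' @param seed Integer seed.
#' @return A rooted binary `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1) {
  if (n_species < 2) stop("need at least 2 species")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- mean(ape::node.depth.edgelength(tree)[seq_len(n_species)])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate multivariate Brownian traits on a tree
#'
#' Trait increments along each branch are independent multivariate normals
#' with covariance `branch length x R`; tip values are returned, node
#' values optionally.
#'
#' @param tree Rooted `phylo`.
#' @param R p x p symmetric positive-semidefinite per-unit-length trait
#'   covariance (a scalar is taken as 1 x 1).
#' @param mu Root state (length p).
#' @param trait_names Column names (default `trait1..p`).
#' @param seed Integer seed.
#' @param return_nodes Also return internal-node values (attribute
#'   `node_values`).
#' @return Data.frame with `species` plus one column per trait; rownames
#'   are species ids.
#' @export
simulate_brownian_traits <- function(tree, R, mu, trait_names = NULL,
                                     seed = 1, return_nodes = FALSE) {
  validate_phylogeny(tree)
  R <- as.matrix(R)
  p <- nrow(R)
  if (!isSymmetric(unname(R), tol = 1e-10)) stop("R must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("R must be positive semidefinite")
  if (length(mu) != p) stop("mu must have length ", p)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(p))
  set.seed(seed)
  # principal square root handles semidefinite R (chol would fail)
  es <- eigen(R, symmetric = TRUE)
  Rhalf <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  vals <- matrix(NA_real_, n_node, p)
  root <- n_tip + 1L
  vals[root, ] <- mu
  pre <- ape::reorder.phylo(tree, "postorder")
  edges <- pre$edge[rev(seq_len(nrow(pre$edge))), , drop = FALSE]
  elens <- pre$edge.length[rev(seq_len(nrow(pre$edge)))]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    z <- stats::rnorm(p)
    vals[ch, ] <- vals[par, ] + sqrt(elens[k]) * as.numeric(Rhalf %*% z)
  }
  tips <- vals[seq_len(n_tip), , drop = FALSE]
  out <- data.frame(species = tree$tip.label, tips)
  names(out)[-1] <- trait_names
  rownames(out) <- tree$tip.label
  if (return_nodes) {
    colnames(vals) <- trait_names
    attr(out, "node_values") <- vals
  }
  out
}

# Per-edge codon models for branch-specific omega, cached by omega value.
.edge_models <- function(base_model, omegas) {
  uo <- unique(omegas)
  cache <- lapply(uo, function(o) {
    if (o == base_model$omega) base_model else
      codon_model(base_model$kappa, o, base_model$phi)
  })
  cache[match(omegas, uo)]
}

#' Simulate a gap-free codon alignment under YN98(F3X4)
#'
#' Root codons are drawn from the stationary distribution; each branch
#' evolves every site by the YN98 transition kernel, with an optionally
#' branch-specific omega.
#'
#' @param tree Rooted `phylo` (branch lengths in substitutions per codon
#'   site).
#' @param model A `codon_model` providing kappa and F3X4 frequencies (and
#'   omega when `branch_omegas` is `NULL`).
#' @param n_codons Alignment length in codons.
#' @param branch_omegas `NULL` (use `model$omega`), a scalar, or a numeric
#'   vector along `tree$edge` rows.
#' @param seed Integer seed.
#' @param gene Gene id for the returned alignment.
#' @param edge_models Optional precomputed per-edge `codon_model` list
#'   (internal; avoids rebuilding spectral factors across many genes).
#' @return A `codon_alignment` over the tree tips.
#' @export
simulate_codon_alignment <- function(tree, model, n_codons,
                                     branch_omegas = NULL, seed = 1,
                                     gene = "gene", edge_models = NULL) {
  validate_phylogeny(tree)
  set.seed(seed)
  n_edge <- nrow(tree$edge)
  omegas <- if (is.null(branch_omegas)) rep(model$omega, n_edge)
    else if (length(branch_omegas) == 1) rep(branch_omegas, n_edge)
    else branch_omegas
  if (length(omegas) != n_edge) stop("branch_omegas must match tree$edge rows")
  if (any(omegas < 0)) stop("branch omegas must be >= 0")
  models <- if (is.null(edge_models)) .edge_models(model, omegas)
    else edge_models
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_codons)
  root <- n_tip + 1L
  nstate <- length(model$pi)
  states[root, ] <- sample.int(nstate, n_codons, replace = TRUE,
                               prob = model$pi)
  post <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(post$edge)))
  edge_match <- match(paste(post$edge[, 1], post$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in ord) {
    par <- post$edge[k, 1]; ch <- post$edge[k, 2]
    P <- transition_probabilities(models[[edge_match[k]]],
                                  post$edge.length[k])
    parent_states <- states[par, ]
    child_states <- integer(n_codons)
    for (s in unique(parent_states)) {
      idx <- which(parent_states == s)
      child_states[idx] <- sample.int(nstate, length(idx), replace = TRUE,
                                      prob = P[s, ])
    }
    states[ch, ] <- child_states
  }
  sense <- .codon_tables$sense
  seqs <- vapply(seq_len(n_tip), function(i) {
    paste(sense[states[i, ]], collapse = "")
  }, character(1))
  names(seqs) <- tree$tip.label
  codon_alignment(seqs, gene = gene)
}

#' Default TE generator parameters
#'
#' @param n_families Number of TE families.
#' @param family_ages Ages (expected divergence time units); default
#'   exponential spread from very recent to old.
#' @param copies_per_family Copy count per family.
#' @param copy_length Copy length (bp).
#' @param coverage Fraction of the genome sampled as reads (low-coverage
#'   read sampling; 0.25 by default).
#' @param read_length Read length (bp).
#' @return List of class `te_params`.
#' @export
te_params <- function(n_families = 10, family_ages = NULL,
                      copies_per_family = 50, copy_length = 500,
                      coverage = 0.25, read_length = 150) {
  if (is.null(family_ages)) {
    family_ages <- seq(0.005, 0.35, length.out = n_families)
  }
  if (length(family_ages) != n_families) stop("one age per family")
  if (any(family_ages < 0)) stop("family ages must be >= 0")
  if (any(copy_length <= 0)) stop("copy lengths must be > 0")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  copies_per_family <- rep_len(copies_per_family, n_families)
  structure(list(n_families = n_families, family_ages = family_ages,
                 copies_per_family = copies_per_family,
                 copy_length = copy_length, coverage = coverage,
                 read_length = read_length),
            class = "te_params")
}

#' Simulate a repeat landscape and its low-coverage read annotations
#'
#' TE copies diverge from their family consensus with expected divergence
#' `min(1 - exp(-age), 0.4)` (a Jukes-Cantor-style saturating map); the
#' realized per-copy divergence is binomial around that expectation. Reads
#' are sampled uniformly from TE and non-TE space at the configured
#' coverage; a read falling in a TE copy inherits the copy's class and
#' divergence in full (`annotated_bp = read_bp`), others are unannotated.
#'
#' @param params A [te_params()].
#' @param genome_size Genome size in bp (must exceed the summed TE bp).
#' @param seed Integer seed.
#' @param recent_divergence_max Threshold defining the true recent TE bp.
#' @return List: `annotations` (TE read-annotation data.frame),
#'   `true_te_bp`, `true_recent_te_bp`, `copies` (per-copy table).
#' @export
simulate_te_genome <- function(params, genome_size, seed = 1,
                               recent_divergence_max = 0.05) {
  stopifnot(inherits(params, "te_params"))
  set.seed(seed)
  nf <- params$n_families
  if (nf == 0 || sum(params$copies_per_family) == 0) {
    ann <- data.frame(read_id = character(0), annotated_bp = numeric(0),
                      repeat_class = character(0), divergence = numeric(0),
                      read_bp = numeric(0))
    return(list(annotations = ann, true_te_bp = 0, true_recent_te_bp = 0,
                copies = NULL))
  }
  classes <- rep_len(setdiff(.te_classes, "none"), nf)
  copies <- do.call(rbind, lapply(seq_len(nf), function(f) {
    ncp <- params$copies_per_family[f]
    if (ncp == 0) return(NULL)
    exp_div <- min(1 - exp(-params$family_ages[f]), 0.4)
    div <- stats::rbinom(ncp, params$copy_length, exp_div) / params$copy_length
    data.frame(family = f, class = classes[f], length = params$copy_length,
               divergence = div)
  }))
  true_te_bp <- sum(copies$length)
  if (true_te_bp >= genome_size) {
    stop("summed TE bp (", true_te_bp, ") exceeds genome size")
  }
  true_recent <- sum(copies$length[copies$divergence < recent_divergence_max])
  n_reads <- max(1L, round(params$coverage * genome_size / params$read_length))
  in_te <- stats::runif(n_reads) < true_te_bp / genome_size
  copy_idx <- rep(NA_integer_, n_reads)
  if (any(in_te)) {
    copy_idx[in_te] <- sample.int(nrow(copies), sum(in_te), replace = TRUE,
                                  prob = copies$length)
  }
  ann <- data.frame(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    annotated_bp = ifelse(in_te, params$read_length, 0),
    repeat_class = ifelse(in_te, copies$class[copy_idx], "none"),
    divergence = ifelse(in_te, copies$divergence[copy_idx], NA_real_),
    read_bp = params$read_length)
  list(annotations = ann, true_te_bp = true_te_bp,
       true_recent_te_bp = true_recent, copies = copies)
}

#' Simulate heteroscedastic C-value and assembly-size records
#'
#' C-values carry multiplicative lognormal measurement noise; assembly
#' sizes underestimate the true size by a fraction that grows with genome
#' size, reproducing the size-dependent gap between assemblies and
#' cytometric measurements.
#'
#' @param true_sizes True genome sizes in bp.
#' @param noise_sd Standard deviation of the lognormal C-value noise.
#' @param under_coef Underestimation coefficient: the assembly misses a
#'   fraction `min(under_coef * log10(size / size_ref), 0.6)` (floored at
#'   0) of the genome, so the gap widens with genome size.
#' @param seed Integer seed.
#' @param size_ref Genome size at which underestimation starts.
#' @param pg_to_bp Conversion constant.
#' @return Data.frame: `species`, `assembly_size` (bp), `cvalue` (pg),
#'   `method` (cycled FCM/FD/FIA), `date` (cycled years), `true_size`.
#' @export
simulate_cvalue_records <- function(true_sizes, noise_sd = 0.05,
                                    under_coef = 0.05, seed = 1,
                                    size_ref = 1e7, pg_to_bp = 0.978e9) {
  if (any(true_sizes <= 0)) stop("true sizes must be > 0")
  set.seed(seed)
  n <- length(true_sizes)
  cvalue_bp <- true_sizes * exp(stats::rnorm(n, 0, noise_sd))
  under <- pmin(pmax(under_coef * log10(true_sizes / size_ref), 0), 0.6)
  data.frame(
    species = if (is.null(names(true_sizes)))
      sprintf("sp%03d", seq_len(n)) else names(true_sizes),
    assembly_size = true_sizes * (1 - under),
    cvalue = cvalue_bp / pg_to_bp,
    method = rep_len(c("FCM", "FD", "FIA"), n),
    date = rep_len(2000:2020, n),
    true_size = true_sizes)
}

#' Describe a full simulation scenario
#'
#' The scenario fixes the data-generating world for an end-to-end run:
#' a pure-birth tree; three traits diffusing as correlated Brownian
#' motions — a latent log effective population size (`log_ne`), a log TE
#' amount (`log_te_frac`, logit TE fraction of the genome) and log genome
#' size (`log_gs`); codon alignments under YN98 whose per-branch omega is
#' optionally coupled to `log_ne` (an MHH-true world); per-species repeat
#' landscapes consistent with the TE trait; and noisy C-value/assembly
#' records of the genome-size trait.
#'
#' @param n_species Tips of the simulated tree.
#' @param birth_rate Speciation rate.
#' @param trait_covariance 3 x 3 per-unit-length covariance of
#'   `(log_ne, log_te_frac, log_gs)`. The default encodes an MHH-true
#'   world: TE amount and genome size rise as Ne falls.
#' @param root_state Root values of the three traits
#'   (`log_gs` in log bp).
#' @param omega_link `NULL` (constant omega; an MHH-false world for the
#'   dN/dS channel) or `c(a, b)` with per-branch
#'   `omega = exp(a + b * log_ne)` clipped to `[0.01, 2]`; `b < 0` makes
#'   small-Ne lineages evolve at higher omega.
#' @param kappa,omega Codon model parameters (omega used when
#'   `omega_link` is `NULL`).
#' @param phi F3X4 positional frequencies.
#' @param n_genes,n_codons Alignment count and length.
#' @param te Base [te_params()] shared by species (copy numbers are
#'   rescaled per species to match the TE trait).
#' @param cvalue_noise_sd,cvalue_under_coef C-value record noise.
#' @param seed Integer seed.
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(
    n_species = 50, birth_rate = 1,
    trait_covariance = matrix(c(0.5, -0.35, -0.25,
                                -0.35, 0.5, 0.30,
                                -0.25, 0.30, 0.5) * 0.5, 3, 3,
                              dimnames = list(
                                c("log_ne", "log_te_frac", "log_gs"),
                                c("log_ne", "log_te_frac", "log_gs"))),
    root_state = c(log_ne = 0, log_te_frac = -1.5, log_gs = log(2e7)),
    omega_link = c(a = log(0.2), b = -0.5),
    kappa = 2, omega = 0.2,
    phi = matrix(c(0.30, 0.20, 0.30, 0.20,
                   0.25, 0.30, 0.20, 0.25,
                   0.20, 0.30, 0.30, 0.20), 3, 4, byrow = TRUE),
    n_genes = 10, n_codons = 300,
    te = te_params(), cvalue_noise_sd = 0.05, cvalue_under_coef = 0.05,
    seed = 1) {
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 trait_covariance = trait_covariance,
                 root_state = root_state, omega_link = omega_link,
                 kappa = kappa, omega = omega, phi = phi,
                 n_genes = n_genes, n_codons = n_codons, te = te,
                 cvalue_noise_sd = cvalue_noise_sd,
                 cvalue_under_coef = cvalue_under_coef,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Generate every pipeline input from a scenario
#'
#' @param scenario A [simulation_scenario()].
#' @param simulate_alignments Set `FALSE` to skip codon alignments (trait,
#'   TE and C-value channels only; much faster for comparative-stage
#'   studies).
#' @param simulate_te_reads Set `FALSE` to skip the read-level repeat
#'   landscapes; the analytic per-species TE truth (`te_bp_true`) is kept.
#' @return List of class `scenario_bundle`: `tree`, `traits` (per-species
#'   truth: traits, true omega on the terminal branch, genome size, TE bp),
#'   `alignments` (list of `codon_alignment`), `te` (per-species list from
#'   [simulate_te_genome()]), `cvalue_records`, `scenario`.
#' @export
generate_scenario <- function(scenario = simulation_scenario(),
                              simulate_alignments = TRUE,
                              simulate_te_reads = TRUE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  seed <- scenario$seed
  tree <- simulate_tree(scenario$n_species, scenario$birth_rate, seed)
  traits <- simulate_brownian_traits(
    tree, scenario$trait_covariance, scenario$root_state,
    trait_names = colnames(scenario$trait_covariance),
    seed = seed + 1L, return_nodes = TRUE)
  node_vals <- attr(traits, "node_values")
  n_edge <- nrow(tree$edge)
  if (!is.null(scenario$omega_link)) {
    a <- scenario$omega_link[1]; b <- scenario$omega_link[2]
    branch_omegas <- pmin(pmax(
      exp(a + b * node_vals[tree$edge[, 2], "log_ne"]), 0.01), 2)
  } else {
    branch_omegas <- rep(scenario$omega, n_edge)
  }
  n_tip <- length(tree$tip.label)
  term_edge <- match(seq_len(n_tip), tree$edge[, 2])
  traits$true_omega <- branch_omegas[term_edge]
  traits$genome_size_true <- exp(traits$log_gs)
  traits$te_frac_true <- stats::plogis(traits$log_te_frac)
  traits$te_bp_true <- traits$genome_size_true * traits$te_frac_true

  base_model <- codon_model(scenario$kappa, scenario$omega, scenario$phi)
  alignments <- NULL
  if (simulate_alignments && scenario$n_genes > 0) {
    models <- .edge_models(base_model, branch_omegas)
    alignments <- lapply(seq_len(scenario$n_genes), function(g) {
      simulate_codon_alignment(tree, base_model, scenario$n_codons,
                               branch_omegas = branch_omegas,
                               seed = seed + 100L + g,
                               gene = sprintf("gene%03d", g),
                               edge_models = models)
    })
    names(alignments) <- vapply(alignments, `[[`, character(1), "gene")
  }

  te_out <- NULL
  if (simulate_te_reads) {
    te_out <- lapply(seq_len(n_tip), function(i) {
      tp <- scenario$te
      target_bp <- traits$te_bp_true[i]
      tp$copies_per_family <- pmax(
        0L, round(target_bp / tp$copy_length *
                    tp$copies_per_family / sum(tp$copies_per_family)))
      simulate_te_genome(tp, traits$genome_size_true[i],
                         seed = seed + 1000L + i)
    })
    names(te_out) <- tree$tip.label
    # report the realized (post-rounding) repeat truth per species
    traits$te_bp_true <- vapply(te_out, `[[`, numeric(1), "true_te_bp")
    traits$recent_te_bp_true <- vapply(te_out, `[[`, numeric(1),
                                       "true_recent_te_bp")
  }

  cvr <- simulate_cvalue_records(
    stats::setNames(traits$genome_size_true, traits$species),
    noise_sd = scenario$cvalue_noise_sd,
    under_coef = scenario$cvalue_under_coef,
    seed = seed + 2L)

  structure(list(tree = tree, traits = traits, alignments = alignments,
                 te = te_out, cvalue_records = cvr, scenario = scenario),
            class = "scenario_bundle")
}
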