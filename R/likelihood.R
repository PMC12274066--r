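# Codon-state indices per tip (rows) and site (columns); NA = missing.
.tip_indices <- function(aln, tips) {
  cm <- codon_matrix(aln)
  missing_tips <- setdiff(tips, rownames(cm))
  if (length(missing_tips) > 0) {
    stop("tree tip(s) without sequence: ", paste(missing_tips, collapse = ", "))
  }
  idx <- do.call(rbind, lapply(tips, function(sp) codon_indices(cm[sp, ])))
  rownames(idx) <- tips
  idx
}

# Collapse identical site patterns; returns unique index matrix + weights.
.compress_patterns <- function(idx) {
  key <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  list(idx = idx[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]),
       site_of = match(key, key[first]))
}

# Partial-likelihood matrices (61 x npatterns) for each tip row of idx.
.tip_partials_from_idx <- function(idx) {
  n_state <- length(.codon_tables$sense)
  lapply(seq_len(nrow(idx)), function(i) {
    v <- idx[i, ]
    L <- matrix(0, n_state, length(v))
    L[cbind(v[!is.na(v)], which(!is.na(v)))] <- 1
    L[, is.na(v)] <- 1
    L
  })
}

# Postorder pruning with per-node rescaling. Returns per-pattern log-lik.
.prune_loglik <- function(tree, model, tipL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nsites <- ncol(tipL[[1]])
  Ls <- vector("list", n_node)
  Ls[seq_len(n_tip)] <- tipL
  logscale <- numeric(nsites)
  post <- ape::reorder.phylo(tree, "postorder")
  edges <- post$edge
  Pmats <- lapply(post$edge.length, transition_probabilities, model = model)
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    contrib <- Pmats[[k]] %*% Ls[[ch]]
    Ls[[par]] <- if (is.null(Ls[[par]])) contrib else Ls[[par]] * contrib
    mx <- apply(Ls[[par]], 2, max)
    if (any(mx < 1e-150)) {
      mx[mx == 0] <- 1
      Ls[[par]] <- sweep(Ls[[par]], 2, mx, "/")
      logscale <- logscale + log(mx)
    }
  }
  root <- edges[nrow(edges), 1]
  sitelik <- colSums(model$pi * Ls[[root]])
  log(sitelik) + logscale
}

#' Log-likelihood of a codon alignment under YN98(F3X4)
#'
#' Felsenstein pruning over the 61 sense-codon states, with site-pattern
#' compression. Codons containing gaps or ambiguity codes contribute a
#' partial likelihood of 1 (missing data). Branch lengths are expected
#' substitutions per codon site.
#'
#' @param alignment A `codon_alignment` containing every tree tip.
#' @param tree A rooted `phylo`; tips must be a subset of alignment species.
#' @param model A `codon_model`.
#' @return Total log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(alignment, tree, model) {
  validate_phylogeny(tree)
  idx <- .tip_indices(alignment, tree$tip.label)
  cp <- .compress_patterns(idx)
  tipL <- .tip_partials_from_idx(cp$idx)
  sum(.prune_loglik(tree, model, tipL) * cp$weights)
}

#' Maximum-likelihood fit of the YN98(F3X4) model
#'
#' Optimizes `kappa` and `omega` (and, optionally, all branch lengths) by
#' bounded quasi-Newton (`L-BFGS-B`) on log-transformed parameters. The fit
#' proceeds in two stages: `kappa`/`omega` alone from several starting
#' points with branch lengths held at their input values, then a joint
#' refinement including branch lengths from the best stage-one point. F3X4
#' positional frequencies are fixed at their observed counts, as is
#' standard. Bounds: kappa in [0.05, 100], omega in [1e-4, 10], branch
#' lengths in [1e-7, 20].
#'
#' @param alignment A `codon_alignment`.
#' @param tree Rooted `phylo` giving the topology (and starting branch
#'   lengths, in substitutions per codon site).
#' @param optimize_branch_lengths Re-optimize branch lengths under the
#'   codon model (default `TRUE`; per-gene branch lengths are refit so
#'   mapped counts refer to this gene's own divergence).
#' @param starts List of `c(kappa, omega)` stage-one starting points.
#' @return List with `model` (fitted `codon_model`), `tree` (branch lengths
#'   refitted when requested), `loglik`, `convergence` (0 = converged) and
#'   `n_starts_used`.
#' @export
fit_yn98 <- function(alignment, tree, optimize_branch_lengths = TRUE,
                     starts = list(c(2, 0.5), c(1, 1), c(8, 0.1))) {
  validate_phylogeny(tree)
  phi <- positional_frequencies(alignment)
  idx <- .tip_indices(alignment, tree$tip.label)
  cp <- .compress_patterns(idx)
  tipL <- .tip_partials_from_idx(cp$idx)
  w <- cp$weights
  lb_ko <- log(c(0.05, 1e-4)); ub_ko <- log(c(100, 10))
  n_edge <- nrow(tree$edge)
  bl0 <- pmax(tree$edge.length, 1e-6)

  cache <- new.env(parent = emptyenv())
  get_model <- function(kappa, omega) {
    key <- paste(signif(kappa, 14), signif(omega, 14))
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- codon_model(kappa, omega, phi)
    cache[[key]] <- m
    m
  }

  negll_ko <- function(par) {
    m <- get_model(exp(par[1]), exp(par[2]))
    v <- -sum(.prune_loglik(tree, m, tipL) * w)
    if (!is.finite(v)) 1e10 else v
  }
  negll_joint <- function(par) {
    m <- get_model(exp(par[1]), exp(par[2]))
    tr <- tree
    tr$edge.length <- exp(par[-(1:2)])
    v <- -sum(.prune_loglik(tr, m, tipL) * w)
    if (!is.finite(v)) 1e10 else v
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(log(st), negll_ko, method = "L-BFGS-B", lower = lb_ko,
                   upper = ub_ko, control = list(maxit = 200, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("fit_yn98: optimization failed from all starts")

  if (optimize_branch_lengths) {
    p0 <- c(best$par, log(bl0))
    fit <- tryCatch(
      stats::optim(p0, negll_joint, method = "L-BFGS-B",
                   lower = c(lb_ko, rep(log(1e-7), n_edge)),
                   upper = c(ub_ko, rep(log(20), n_edge)),
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value <= best$value + 1e-9) best <- fit
  }
  kappa <- exp(best$par[1]); omega <- exp(best$par[2])
  tr <- tree
  if (optimize_branch_lengths && length(best$par) > 2) {
    tr$edge.length <- exp(best$par[-(1:2)])
  }
  list(model = codon_model(kappa, omega, phi), tree = tr,
       loglik = -best$value, convergence = best$convergence,
       n_starts_used = length(starts))
}
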