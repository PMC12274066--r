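# Label masks over the rate matrix: off-diagonal rates split into
# synonymous and nonsynonymous single-step changes.
.label_mask <- function(label = c("N", "S")) {
  label <- match.arg(label)
  ct <- .codon_tables
  if (label == "N") ct$single & ct$nonsyn else ct$single & !ct$nonsyn
}

# Integral factor J_mn(t) = int_0^t exp(l_m s) exp(l_n (t-s)) ds.
.J_factor <- function(lambda, t) {
  n <- length(lambda)
  dl <- outer(lambda, lambda, "-")
  el <- exp(lambda * t)
  J <- (el %o% rep(1, n) - rep(1, n) %o% el) / dl
  near <- abs(dl) < 1e-9
  Jnear <- t * exp(outer(lambda, lambda, "+") / 2 * t)
  J[near] <- Jnear[near]
  J
}

# E[N_L(t) ; X(t)=j | X(0)=i] matrix: int_0^t exp(Qs) B exp(Q(t-s)) ds
# with B the labeled part of Q, via the cached spectral factors.
.labeled_moment_matrix <- function(model, t, mask) {
  B <- model$Q
  B[!mask] <- 0
  Bt <- model$Uinv %*% B %*% model$U
  M <- model$U %*% (Bt * .J_factor(model$lambda, t)) %*% model$Uinv
  M[M < 0] <- 0
  M
}

# Inside (F), outside (O per edge) partial likelihoods with per-site log
# offsets, plus per-site log-likelihood; postorder edge order throughout.
.map_partials <- function(tree, model, tipL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nsites <- ncol(tipL[[1]])
  post <- ape::reorder.phylo(tree, "postorder")
  edges <- post$edge
  Pmats <- lapply(post$edge.length, transition_probabilities, model = model)
  Fs <- vector("list", n_node); Fs[seq_len(n_tip)] <- tipL
  OffF <- matrix(0, n_node, nsites)
  H <- vector("list", nrow(edges))    # H[[k]] = P_k F_child(k), child offset
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    H[[k]] <- Pmats[[k]] %*% Fs[[ch]]
    Fs[[par]] <- if (is.null(Fs[[par]])) H[[k]] else Fs[[par]] * H[[k]]
    OffF[par, ] <- OffF[par, ] + OffF[ch, ]
    mx <- apply(Fs[[par]], 2, max)
    if (any(mx < 1e-120)) {
      mx[mx == 0] <- 1
      Fs[[par]] <- sweep(Fs[[par]], 2, mx, "/")
      OffF[par, ] <- OffF[par, ] + log(mx)
    }
  }
  root <- edges[nrow(edges), 1]
  sitell <- log(colSums(model$pi * Fs[[root]])) + OffF[root, ]
  # outside pass (preorder = reverse postorder)
  Gs <- vector("list", n_node); OffG <- matrix(0, n_node, nsites)
  Gs[[root]] <- matrix(model$pi, length(model$pi), nsites)
  Oe <- vector("list", nrow(edges)); OffO <- matrix(0, nrow(edges), nsites)
  for (k in rev(seq_len(nrow(edges)))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    sib <- which(edges[, 1] == par & seq_len(nrow(edges)) != k)
    O <- Gs[[par]]
    off <- OffG[par, ]
    for (s in sib) {
      O <- O * H[[s]]
      off <- off + OffF[edges[s, 2], ]
    }
    mx <- apply(O, 2, max)
    if (any(mx < 1e-120)) {
      mx[mx == 0] <- 1
      O <- sweep(O, 2, mx, "/")
      off <- off + log(mx)
    }
    Oe[[k]] <- O; OffO[k, ] <- off
    Gs[[ch]] <- crossprod(Pmats[[k]], O)
    OffG[ch, ] <- off
  }
  list(edges = edges, elens = post$edge.length, Fs = Fs, OffF = OffF,
       Oe = Oe, OffO = OffO, sitell = sitell, post = post)
}

#' Map expected synonymous and nonsynonymous substitution counts
#'
#' For every branch, computes the posterior expected number of synonymous
#' (`K_S`) and nonsynonymous (`K_N`) substitutions conditional on the
#' alignment, summed over sites: the joint posterior over branch endpoint
#' states is combined with the expected number of labeled changes of an
#' endpoint-conditioned Markov path, the latter obtained analytically from
#' the spectral decomposition of the rate matrix.
#'
#' @param model A fitted `codon_model`.
#' @param tree Rooted `phylo` whose branch lengths match the model scaling.
#' @param alignment A `codon_alignment` covering the tips.
#' @return A data.frame with one row per branch: `parent`, `child`,
#'   `branch` (tip label for terminal branches, otherwise `node<N>`),
#'   `length`, `K_N`, `K_S`.
#' @export
map_substitutions <- function(model, tree, alignment) {
  validate_phylogeny(tree)
  idx <- .tip_indices(alignment, tree$tip.label)
  cp <- .compress_patterns(idx)
  tipL <- .tip_partials_from_idx(cp$idx)
  mp <- .map_partials(tree, model, tipL)
  n_tip <- length(tree$tip.label)
  maskN <- .label_mask("N"); maskS <- .label_mask("S")
  out <- data.frame(parent = mp$edges[, 1], child = mp$edges[, 2],
                    branch = ifelse(mp$edges[, 2] <= n_tip,
                                    tree$tip.label[mp$edges[, 2]],
                                    paste0("node", mp$edges[, 2])),
                    length = mp$elens, K_N = NA_real_, K_S = NA_real_)
  for (k in seq_len(nrow(mp$edges))) {
    ch <- mp$edges[k, 2]
    t <- mp$elens[k]
    wsite <- exp(mp$OffO[k, ] + mp$OffF[ch, ] - mp$sitell)
    for (lbl in c("N", "S")) {
      M <- .labeled_moment_matrix(model, t, if (lbl == "N") maskN else maskS)
      numer <- colSums(mp$Oe[[k]] * (M %*% mp$Fs[[ch]]))
      cnt <- sum(numer * wsite * cp$weights)
      if (lbl == "N") out$K_N[k] <- cnt else out$K_S[k] <- cnt
    }
  }
  out
}

#' Expected labeled substitution counts on one branch
#'
#' Convenience wrapper around [map_substitutions()] for a single branch.
#'
#' @param model A fitted `codon_model`.
#' @param tree Rooted `phylo`.
#' @param alignment A `codon_alignment`.
#' @param branch A tip label (terminal branch) or an edge index into
#'   `tree$edge`.
#' @return Named numeric vector `c(K_N = ..., K_S = ...)`.
#' @export
expected_labeled_counts <- function(model, tree, alignment, branch) {
  tab <- map_substitutions(model, tree, alignment)
  row <- if (is.character(branch)) {
    tab[tab$branch == branch, , drop = FALSE]
  } else {
    child <- tree$edge[branch, 2]
    tab[tab$child == child, , drop = FALSE]
  }
  if (nrow(row) != 1L) stop("branch not found: ", branch)
  c(K_N = row$K_N, K_S = row$K_S)
}

#' Expected counts under the matched neutral model
#'
#' The neutral reference sets omega to 1 while keeping kappa and the codon
#' frequencies, rescales to mean rate 1, and takes the unconditional
#' expectation of labeled changes over `l * n_sites` site-substitution
#' opportunities: `O_L = l * n_sites * sum_i pi_i sum_{j in L} Q0_ij`.
#' By construction `O_N + O_S = l * n_sites` exactly.
#'
#' @param model A `codon_model` (its kappa and frequencies are reused).
#' @param branch_length Branch length `l` (substitutions per codon site).
#' @param n_sites Number of codon sites contributing.
#' @return Named numeric vector `c(O_N = ..., O_S = ...)`.
#' @export
neutral_expected_counts <- function(model, branch_length, n_sites) {
  Q0 <- build_yn98_rate_matrix(model$kappa, 1, model$pi)
  fluxN <- sum(model$pi * rowSums(Q0 * .label_mask("N")))
  fluxS <- sum(model$pi * rowSums(Q0 * .label_mask("S")))
  c(O_N = branch_length * n_sites * fluxN,
    O_S = branch_length * n_sites * fluxS)
}

#' Per-gene terminal-branch substitution records
#'
#' Fits the YN98(F3X4) model to one gene (branch lengths re-optimized under
#' the codon model), maps expected synonymous/nonsynonymous counts on every
#' terminal branch, and pairs them with the neutral expectations for the
#' same branch lengths. `n_sites` for the neutral expectation is the number
#' of unambiguous codons the species contributes to the gene.
#'
#' @param alignment A `codon_alignment`.
#' @param tree Rooted `phylo`; tips restricted to alignment species.
#' @param optimize_branch_lengths Passed to [fit_yn98()].
#' @return A data.frame (one row per species): `gene`, `species`, `K_N`,
#'   `K_S`, `O_N`, `O_S`, `l`, `n_sites`, plus fitted `kappa`, `omega`.
#' @export
map_gene_substitutions <- function(alignment, tree,
                                   optimize_branch_lengths = TRUE) {
  keep <- intersect(tree$tip.label, names(alignment$sequences))
  if (length(keep) < 3) stop("fewer than 3 species shared by tree and alignment")
  if (length(keep) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, keep)
  }
  fit <- fit_yn98(alignment, tree,
                  optimize_branch_lengths = optimize_branch_lengths)
  mapped <- map_substitutions(fit$model, fit$tree, alignment)
  term <- mapped[mapped$child <= length(fit$tree$tip.label), , drop = FALSE]
  cm <- codon_matrix(alignment)
  n_sites <- vapply(term$branch, function(sp) {
    sum(!is.na(codon_indices(cm[sp, ])))
  }, numeric(1))
  O <- t(vapply(seq_len(nrow(term)), function(i) {
    neutral_expected_counts(fit$model, term$length[i], n_sites[i])
  }, numeric(2)))
  data.frame(gene = alignment$gene, species = term$branch,
             K_N = term$K_N, K_S = term$K_S,
             O_N = O[, 1], O_S = O[, 2], l = term$length,
             n_sites = n_sites, kappa = fit$model$kappa,
             omega = fit$model$omega, row.names = NULL)
}
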