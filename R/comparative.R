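#' Felsenstein independent contrasts
#'
#' Standard pruning recursion: at each internal node the contrast is the
#' difference of the two daughter values divided by the square root of the
#' summed daughter variances (branch lengths, extended by
#' `v1 * v2 / (v1 + v2)` for estimated ancestral values); ancestral values
#' are branch-length-weighted averages. Polytomies are resolved arbitrarily
#' into zero-length branches first, with a warning. Tips with missing trait
#' values are pruned before the recursion.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param x Named numeric vector of tip trait values (names = tip labels).
#' @return An object of class `contrast_set`: data.frame with `node`,
#'   `contrast`, `variance`, plus attributes `trait` and `n_tips`.
#' @export
compute_contrasts <- function(tree, x) {
  validate_phylogeny(tree)
  x <- x[!is.na(x)]
  keep <- intersect(tree$tip.label, names(x))
  if (length(keep) < 2) stop("need >= 2 tips with trait values")
  if (length(keep) < length(tree$tip.label)) tree <- ape::keep.tip(tree, keep)
  if (!ape::is.binary(tree)) {
    warning("resolving polytomies with zero-length branches")
    tree <- ape::multi2di(tree)
  }
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  edges <- post$edge; elens <- post$edge.length
  n_node <- n_tip + tree$Nnode
  val <- numeric(n_node)
  var_ext <- numeric(n_node)   # branch above node + pruning extension
  val[seq_len(n_tip)] <- x[tree$tip.label]
  blen <- numeric(n_node)
  blen[edges[, 2]] <- elens
  var_ext[seq_len(n_tip)] <- blen[seq_len(n_tip)]
  children <- split(edges[, 2], edges[, 1])
  contrasts <- numeric(0); variances <- numeric(0); nodes <- integer(0)
  # edges into the same parent are consecutive in postorder: process the
  # parent at its last incoming edge, when both daughters are finished
  last_edge <- !duplicated(edges[, 1], fromLast = TRUE)
  for (k in which(last_edge)) {
    par <- edges[k, 1]
    ch <- children[[as.character(par)]]
    v1 <- var_ext[ch[1]]; v2 <- var_ext[ch[2]]
    if (v1 + v2 <= 0) stop("zero total variance at node ", par)
    contrasts <- c(contrasts, (val[ch[1]] - val[ch[2]]) / sqrt(v1 + v2))
    variances <- c(variances, v1 + v2)
    nodes <- c(nodes, par)
    val[par] <- (v2 * val[ch[1]] + v1 * val[ch[2]]) / (v1 + v2)
    var_ext[par] <- blen[par] + v1 * v2 / (v1 + v2)
  }
  out <- data.frame(node = nodes, contrast = contrasts, variance = variances)
  structure(out, trait = attr(x, "trait"), n_tips = n_tip,
            class = c("contrast_set", "data.frame"))
}

#' Through-origin regression of one contrast set on another
#'
#' Contrasts have arbitrary sign, so the regression is forced through the
#' origin: `slope = sum(cx * cy) / sum(cx^2)`, with the two-sided p-value on
#' `n - 1` degrees of freedom and the no-intercept adjusted R-squared.
#'
#' @param cx,cy `contrast_set`s (or plain numeric vectors) on the same
#'   nodes.
#' @return List of class `regression_result`: `slope`, `intercept` (`NA`),
#'   `adj_r_squared`, `p_value`, `n`.
#' @export
pic_regression <- function(cx, cy) {
  x <- if (is.data.frame(cx)) cx$contrast else cx
  y <- if (is.data.frame(cy)) cy$contrast else cy
  if (length(x) != length(y)) stop("contrast sets differ in length")
  n <- length(x)
  if (n < 3) stop("need at least 3 contrasts")
  sxx <- sum(x^2)
  if (sxx == 0) stop("zero variance in predictor contrasts")
  fit <- summary(stats::lm(y ~ x + 0))
  structure(list(slope = unname(fit$coefficients[1, 1]), intercept = NA,
                 adj_r_squared = fit$adj.r.squared,
                 p_value = unname(fit$coefficients[1, 4]), n = n),
            class = "regression_result")
}

#' Ordinary least squares with optional log transforms
#'
#' @param x,y Numeric vectors.
#' @param log_x,log_y Apply natural log before fitting (values must be
#'   positive).
#' @return A `regression_result` (with intercept).
#' @export
ols_regression <- function(x, y, log_x = FALSE, log_y = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (log_x) { if (any(x <= 0)) stop("non-positive x under log"); x <- log(x) }
  if (log_y) { if (any(y <= 0)) stop("non-positive y under log"); y <- log(y) }
  fit <- summary(stats::lm(y ~ x))
  structure(list(slope = unname(fit$coefficients["x", 1]),
                 intercept = unname(fit$coefficients["(Intercept)", 1]),
                 adj_r_squared = fit$adj.r.squared,
                 p_value = unname(fit$coefficients["x", 4]),
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope = %.4g%s, adj-R2 = %.3g, p = %.3g, n = %d\n",
              x$slope,
              if (is.na(x$intercept)) " (through origin)"
              else sprintf(", intercept = %.4g", x$intercept),
              x$adj_r_squared, x$p_value, x$n))
  invisible(x)
}

#' REML fit of multivariate Brownian trait evolution
#'
#' Traits are assumed to diffuse along the tree as a multivariate Brownian
#' motion with per-unit-branch-length covariance `R`. With tip covariance
#' `C` from [phylo_covariance()], the GLS root state is
#' `mu = (1' C^-1 1)^-1 1' C^-1 Y` and the REML covariance estimate is
#' `R = (Y - 1 mu')' C^-1 (Y - 1 mu') / (n - 1)`. This is the simplified,
#' likelihood-based analogue of a Bayesian coevolution model: it estimates
#' the same trait covariance matrix but no ancestral node states.
#'
#' @param tree Rooted `phylo`.
#' @param traits Matrix or data.frame of tip trait values (rows named by
#'   tip label) with `p` columns; complete cases only.
#' @return Object of class `brownian_fit`: `R` (p x p), `mu`, `correlation`,
#'   `n`, `loglik` (restricted log-likelihood).
#' @export
fit_brownian_multivariate <- function(tree, traits) {
  validate_phylogeny(tree)
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) stop("trait rows must be named by tip label")
  ok <- stats::complete.cases(traits)
  traits <- traits[ok, , drop = FALSE]
  keep <- intersect(tree$tip.label, rownames(traits))
  p <- ncol(traits)
  if (length(keep) < p + 1) stop("need at least p + 1 complete tips")
  tree <- ape::keep.tip(tree, keep)
  Y <- traits[tree$tip.label, , drop = FALSE]
  C <- phylo_covariance(tree)
  n <- nrow(Y)
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular tip covariance (duplicate zero-length tips?)"))
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Ci %*% one)
  mu <- as.numeric(t(one) %*% Ci %*% Y) / denom
  Yc <- sweep(Y, 2, mu)
  R <- t(Yc) %*% Ci %*% Yc / (n - 1)
  R <- (R + t(R)) / 2
  corr <- stats::cov2cor(R)
  ldC <- determinant(C, logarithm = TRUE)$modulus
  ll <- -0.5 * ((n - 1) * determinant(R, logarithm = TRUE)$modulus +
                  p * (ldC + log(denom)) + p * (n - 1))
  structure(list(R = R, mu = mu, correlation = corr, n = n,
                 loglik = as.numeric(ll), tree = tree),
            class = "brownian_fit")
}

#' @export
print.brownian_fit <- function(x, ...) {
  cat(sprintf("multivariate Brownian REML fit: %d tips, %d traits\n",
              x$n, ncol(x$R)))
  print(round(x$correlation, 3))
  invisible(x)
}

#' Parametric-bootstrap support for trait-pair correlations
#'
#' For each trait pair, traits are re-simulated under the fitted Brownian
#' model with that pair's covariance forced to zero (the null), refit, and
#' the support is the fraction of null correlations lying below the
#' observed one. Support above 0.9 flags a positive association, below 0.1
#' a negative one, mirroring the reading convention of Bayesian posterior
#' probabilities in coevolution models.
#'
#' @param fit A `brownian_fit`.
#' @param n_reps Bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @return Data.frame: `trait_x`, `trait_y`, `correlation`, `support`,
#'   `flagged`.
#' @export
bootstrap_support <- function(fit, n_reps = 500, seed = 1) {
  stopifnot(inherits(fit, "brownian_fit"))
  if (n_reps < 100) warning("fewer than 100 bootstrap replicates")
  p <- ncol(fit$R)
  tn <- colnames(fit$R)
  if (is.null(tn)) tn <- paste0("trait", seq_len(p))
  pairs <- utils::combn(p, 2)
  out <- vector("list", ncol(pairs))
  set.seed(seed)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    obs <- fit$correlation[i, j]
    if (abs(obs) >= 1 - 1e-12) {
      out[[q]] <- data.frame(trait_x = tn[i], trait_y = tn[j],
                             correlation = obs,
                             support = as.numeric(obs > 0), flagged = TRUE)
      next
    }
    R0 <- fit$R[c(i, j), c(i, j)]
    R0[1, 2] <- R0[2, 1] <- 0
    null_corr <- vapply(seq_len(n_reps), function(r) {
      sim <- simulate_brownian_traits(
        fit$tree, R0, mu = fit$mu[c(i, j)],
        trait_names = c("a", "b"),
        seed = sample.int(.Machine$integer.max, 1))
      f <- fit_brownian_multivariate(
        fit$tree, as.matrix(sim[, c("a", "b")]))
      f$correlation[1, 2]
    }, numeric(1))
    support <- mean(null_corr < obs)
    out[[q]] <- data.frame(trait_x = tn[i], trait_y = tn[j],
                           correlation = obs, support = support,
                           flagged = support > 0.9 | support < 0.1)
  }
  do.call(rbind, out)
}

#' Split a trait table at the BUSCO-duplication threshold
#'
#' Species with `busco_duplicated` strictly above the threshold likely
#' carry whole or partial genome duplications that inflate genome size;
#' comparative analyses are run on both the full and the reduced set.
#'
#' @param table A `species_traits` table with `busco_duplicated`.
#' @param cfg A [pipeline_config()].
#' @return List: `full` (unchanged table), `reduced` (screened table),
#'   `excluded` (species ids).
#' @export
duplication_screen <- function(table, cfg = pipeline_config()) {
  if (!"busco_duplicated" %in% names(table)) {
    stop("busco_duplicated column required")
  }
  high <- !is.na(table$busco_duplicated) &
    table$busco_duplicated > cfg$duplication_max
  list(full = table, reduced = table[!high, , drop = FALSE],
       excluded = table$species[high])
}
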