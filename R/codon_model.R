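# Universal genetic code over the 61 sense codons. State order is fixed
# (alphabetical codons minus stops) and shared by all model code.
.nucs <- c("A", "C", "G", "T")

.codon_tables <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  sense <- codons[gc != "*"]
  aa <- gc[sense]
  pos <- lapply(1:3, function(p) substr(sense, p, p))
  # single-nucleotide neighbour structure of the sense-codon graph
  n <- length(sense)
  diff_pos <- matrix(0L, n, n)
  for (p in 1:3) {
    d <- outer(pos[[p]], pos[[p]], "!=")
    diff_pos <- diff_pos + d
  }
  single <- diff_pos == 1L
  is_transition_pair <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  transition <- matrix(FALSE, n, n)
  for (p in 1:3) {
    d <- outer(pos[[p]], pos[[p]], "!=")
    tr <- outer(pos[[p]], pos[[p]], is_transition_pair)
    transition[single & d] <- tr[single & d]
  }
  nonsyn <- outer(aa, aa, "!=")
  list(sense = sense, aa = aa, pos = pos, single = single,
       transition = transition, nonsyn = nonsyn)
})

#' F3X4 codon frequencies from positional nucleotide frequencies
#'
#' The F3X4 parameterization sets the frequency of a sense codon
#' proportional to the product of its three positional nucleotide
#' frequencies, renormalized after excluding the three stop codons.
#'
#' @param x Either a 3 x 4 matrix of positional nucleotide frequencies
#'   (rows = codon positions, columns = A, C, G, T; each row summing to 1),
#'   or a `codon_alignment` from which positional frequencies are counted
#'   (gaps and ambiguity codes excluded).
#' @return Named numeric vector of length 61 summing to 1.
#' @export
build_f3x4 <- function(x) {
  phi <- if (inherits(x, "codon_alignment")) positional_frequencies(x) else x
  if (!is.matrix(phi) || !all(dim(phi) == c(3, 4))) {
    stop("phi must be a 3 x 4 matrix (positions x A,C,G,T)")
  }
  if (any(phi < 0) || any(abs(rowSums(phi) - 1) > 1e-8)) {
    stop("each row of phi must be a frequency vector summing to 1")
  }
  colnames(phi) <- .nucs
  ct <- .codon_tables
  pi <- phi[1, ct$pos[[1]]] * phi[2, ct$pos[[2]]] * phi[3, ct$pos[[3]]]
  names(pi) <- ct$sense
  s <- sum(pi)
  if (s <= 0) stop("all sense codons have zero frequency under phi")
  pi / s
}

#' Observed positional nucleotide frequencies of an alignment
#'
#' @param aln A `codon_alignment`.
#' @return A 3 x 4 matrix (positions x A,C,G,T), rows summing to 1.
#' @export
positional_frequencies <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  chars <- strsplit(aln$sequences, "")
  phi <- matrix(0, 3, 4, dimnames = list(NULL, .nucs))
  for (s in chars) {
    posidx <- rep_len(1:3, length(s))
    ok <- s %in% .nucs
    tab <- table(factor(posidx[ok], levels = 1:3), factor(s[ok], levels = .nucs))
    phi <- phi + as.matrix(tab)
  }
  if (any(rowSums(phi) == 0)) stop("no unambiguous nucleotides at some codon position")
  sweep(phi, 1, rowSums(phi), "/")
}

#' YN98 rate matrix over the 61 sense codons
#'
#' Off-diagonal rates are nonzero only between codons differing at exactly
#' one position: `Q[i, j] = pi[j] * kappa^[transition] * omega^[nonsynonymous]`.
#' The diagonal makes rows sum to zero and the matrix is rescaled so the
#' stationary mean rate `-sum(pi * diag(Q))` equals 1, i.e. branch lengths
#' are in expected substitutions per codon site.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Stationary codon frequencies (length 61, summing to 1),
#'   e.g. from [build_f3x4()].
#' @return A 61 x 61 rate matrix with codon dimnames.
#' @export
build_yn98_rate_matrix <- function(kappa, omega, pi) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  ct <- .codon_tables
  if (length(pi) != length(ct$sense) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be 61 sense-codon frequencies summing to 1")
  }
  n <- length(pi)
  Q <- matrix(0, n, n, dimnames = list(ct$sense, ct$sense))
  Q[ct$single] <- rep(pi, each = n)[ct$single]
  Q[ct$single & ct$transition] <- Q[ct$single & ct$transition] * kappa
  Q[ct$single & ct$nonsyn] <- Q[ct$single & ct$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate rate matrix (zero mean rate)")
  Q / rate
}

#' Construct a YN98(F3X4) codon model
#'
#' Bundles the model parameters with the derived codon frequencies, scaled
#' rate matrix and its spectral decomposition (used for transition
#' probabilities and substitution mapping). The chain is time-reversible, so
#' the symmetrized matrix `diag(sqrt(pi)) Q diag(1/sqrt(pi))` has a real
#' spectrum; eigenvectors are stored in that basis.
#'
#' @param kappa,omega YN98 parameters.
#' @param phi 3 x 4 positional nucleotide frequency matrix (F3X4).
#' @return An object of class `codon_model` with elements `kappa`, `omega`,
#'   `phi`, `pi`, `Q`, and spectral factors `U`, `Uinv`, `lambda` such that
#'   `Q = U diag(lambda) Uinv`.
#' @export
codon_model <- function(kappa, omega, phi) {
  pi <- build_f3x4(phi)
  if (any(pi < 1e-12)) {
    # zero positional frequencies (possible with observed counts on short
    # alignments) would break the spectral factorization; floor and
    # renormalize at negligible mass
    pi <- pmax(pi, 1e-12)
    pi <- pi / sum(pi)
  }
  Q <- build_yn98_rate_matrix(kappa, omega, pi)
  sp <- .spectral(Q, pi)
  structure(list(kappa = kappa, omega = omega, phi = phi, pi = pi, Q = Q,
                 U = sp$U, Uinv = sp$Uinv, lambda = sp$lambda),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("YN98(F3X4) codon model: kappa = %.4g, omega = %.4g\n",
              x$kappa, x$omega))
  invisible(x)
}

# Spectral decomposition of a reversible rate matrix via symmetrization.
.spectral <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))           # D Q D^-1, symmetric for reversible Q
  S <- (S + t(S)) / 2                # guard tiny asymmetry
  es <- eigen(S, symmetric = TRUE)
  U <- es$vectors / d                # D^-1 V
  Uinv <- t(es$vectors * d)          # V^T D
  list(U = U, Uinv = Uinv, lambda = es$values)
}

#' Transition probability matrix of a codon model
#'
#' `P(t) = exp(Q t)` computed from the cached spectral decomposition.
#'
#' @param model A `codon_model`.
#' @param t Branch length (expected substitutions per codon site, >= 0).
#' @return A 61 x 61 stochastic matrix.
#' @export
transition_probabilities <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  P <- model$U %*% (exp(model$lambda * t) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)

}

# Indices of sense codons for a character vector of codon strings; NA for
# codons containing gaps/ambiguity (treated as missing data) ; error for stops.
codon_indices <- function(codons) {
  idx <- match(codons, .codon_tables$sense)
  unknown <- is.na(idx) & !grepl("[^ACGT]", codons)
  if (any(unknown)) {
    stop("stop codon(s) in alignment: ",
         paste(unique(codons[unknown]), collapse = ", "))
  }
  idx
}
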