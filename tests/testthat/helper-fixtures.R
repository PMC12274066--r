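# Shared fixtures and independent oracles, built in code.

balanced_phi <- function() {
  matrix(c(0.30, 0.20, 0.30, 0.20,
           0.25, 0.30, 0.20, 0.25,
           0.20, 0.30, 0.30, 0.20), 3, 4, byrow = TRUE)
}

random_phi <- function() {
  phi <- matrix(stats::runif(12, 0.5, 1.5), 3, 4)
  phi / rowSums(phi)
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# brute-force log-likelihood for a 3-taxon tree ((A:ta,B:tb):tr,C:tc);
# sums over all 61^2 internal-state assignments per site
brute_loglik_3taxon <- function(model, ta, tb, tr, tc, codA, codB, codC) {
  sense <- sense_codons()
  Pr <- transition_probabilities(model, tr)
  Pa <- transition_probabilities(model, ta)
  Pb <- transition_probabilities(model, tb)
  Pc <- transition_probabilities(model, tc)
  total <- 0
  for (s in seq_along(codA)) {
    ia <- match(codA[s], sense); ib <- match(codB[s], sense)
    ic <- match(codC[s], sense)
    lik <- sum(model$pi * Pc[, ic] * (Pr %*% (Pa[, ia] * Pb[, ib])))
    total <- total + log(lik)
  }
  total
}

# nonsynonymous indicator over sense-codon pairs, from the genetic code
nonsyn_matrix <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  aa <- gc[sense]
  outer(aa, aa, "!=")
}

# direct evaluation of the per-species aggregation as printed:
# rate = sum(K) / sum(O / l)
brute_aggregate <- function(K_N, K_S, O_N, O_S, l) {
  dN <- sum(K_N) / sum(O_N / l)
  dS <- sum(K_S) / sum(O_S / l)
  list(dN = dN, dS = dS, dnds = dN / dS)
}

# forward Gillespie path sampler under a codon rate matrix; returns
# endpoint state and labeled jump counts
sample_codon_path <- function(Q, nonsyn, i, t) {
  rates <- -diag(Q)
  nN <- 0L; nS <- 0L; time <- 0; s <- i
  repeat {
    w <- stats::rexp(1, rates[s])
    if (time + w > t) break
    time <- time + w
    probs <- Q[s, ]; probs[s] <- 0
    ns <- sample.int(length(rates), 1, prob = probs)
    if (nonsyn[s, ns]) nN <- nN + 1L else nS <- nS + 1L
    s <- ns
  }
  c(state = s, nN = nN, nS = nS)
}

small_trait_table <- function() {
  as_species_traits(data.frame(
    species = c("a", "b", "c", "d"),
    assembly_size = c(1e9, 2e9, 5e8, 3e9),
    cvalue = c(1.2, NA, 0.6, NA),
    method = c("FCM", NA, "FD", NA),
    date = c(2010, NA, 2005, NA),
    contig_N50 = c(6e4, 49999, 5e4, 2e5),
    busco_complete = c(95, 80, 70, 69.9),
    busco_duplicated = c(5, 35, 30, 10)))
}
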