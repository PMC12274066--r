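#' Construct a codon alignment
#'
#' A codon alignment is a named character vector of equal-length aligned
#' nucleotide sequences over `{A, C, G, T, -}` (ambiguity codes are accepted
#' and treated as missing data), with total length divisible by 3. Column
#' triplets are in frame: codon k of every species occupies columns
#' `3k-2 .. 3k`.
#'
#' @param sequences Named character vector, one aligned sequence per species.
#' @param gene Gene identifier string.
#' @return An object of class `codon_alignment`: list with `sequences`
#'   (uppercase), `gene`, `n_codons`.
#' @export
codon_alignment <- function(sequences, gene = "gene") {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("all sequences must be named by species")
  }
  if (anyDuplicated(names(sequences))) stop("duplicate species names")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("unequal sequence lengths: ", paste(unique(lens), collapse = ", "))
  }
  if (lens[1] %% 3L != 0L) {
    stop("alignment length ", lens[1], " not divisible by 3 (frame error)")
  }
  structure(
    list(sequences = sequences, gene = gene,
         n_codons = unname(lens[1]) %/% 3L),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment '", x$gene, "': ", length(x$sequences),
      " species x ", x$n_codons, " codons\n", sep = "")
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped) of aligned nucleotide
#'   sequences.
#' @param gene Gene identifier; defaults to the file name without extension.
#' @return A `codon_alignment`.
#' @export
read_codon_fasta <- function(path, gene = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA format error: ", conditionMessage(e))
  )
  if (length(ss) == 0L) stop("FASTA format error: no records in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  codon_alignment(seqs, gene = gene)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  ss <- Biostrings::BStringSet(aln$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Split a codon_alignment into a species x codon matrix of 3-letter strings.
codon_matrix <- function(aln) {
  m <- t(vapply(aln$sequences, function(s) {
    substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
  }, character(aln$n_codons)))
  if (aln$n_codons == 1L) m <- matrix(m, ncol = 1L,
                                      dimnames = list(names(aln$sequences)))
  rownames(m) <- names(aln$sequences)
  m
}
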