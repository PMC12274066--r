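#' Read a rooted phylogeny from a newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree is the
#' coordinate system for all comparative computation in the package, so the
#' reader enforces the invariants every downstream stage assumes: a single
#' root, unique tip labels, and non-negative branch lengths in substitutions
#' per site.
#'
#' @param text A newick string (terminated by `;`). Mutually exclusive with
#'   `file`.
#' @param file Path to a newick file.
#' @return An object of class `phylo` (ape), rooted, with `edge.length` set.
#' @examples
#' tr <- read_newick("(A:1,B:2);")
#' tr$tip.label
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("newick file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("newick parse error: could not parse input")
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny to canonical newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylogeny(tree)
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate the phylogeny invariants used throughout the package
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly, after checks.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

#' Brownian tip covariance implied by a rooted tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`;
#' the diagonal holds root-to-tip depths. This is the covariance of tip
#' values under unit-rate Brownian motion and the weight matrix of the GLS
#' regression that independent contrasts reproduce.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A symmetric `n x n` matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  ape::vcv(tree)
}
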