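#' Read a host phylogeny from Newick or NEXUS
#'
#' Reads a rooted tree and canonicalizes tip labels: surrounding whitespace is
#' trimmed, internal runs of whitespace are replaced by a single underscore,
#' and surrounding quotes are dropped. Matching of species names downstream is
#' case-sensitive after this canonicalization; no fuzzy matching is attempted.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (default, sniff the first non-blank character),
#'   `"newick"` or `"nexus"`.
#' @return An object of class `phylo` with canonical tip labels.
#' @export
read_host_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    head_txt <- paste(readLines(path, n = 5L, warn = FALSE), collapse = " ")
    format <- if (grepl("#NEXUS", head_txt, ignore.case = TRUE)) "nexus" else "newick"
  }
  tree <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (is.null(tree)) stop("could not parse tree file: ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  tree$tip.label <- canonical_species(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels after canonicalization: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (max(tip_depths(tree)) <= 0) stop("tree has zero total height")
  tree
}

canonical_species <- function(x) {
  x <- gsub("^['\"]|['\"]$", "", trimws(x))
  gsub("[[:space:]]+", "_", x)
}

#' Root-to-tip path lengths
#' @param tree A `phylo` object.
#' @return Named numeric vector of tip depths.
#' @keywords internal
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Check that a tree is ultrametric
#'
#' The phylogenetic mixed model requires equal root-to-tip distances for all
#' taxa (a Brownian-motion relatedness matrix with unit diagonal). This check
#' fails when any tip depth deviates from the maximum depth by more than
#' `rel_tolerance` times the tree height.
#'
#' @param tree A `phylo` object.
#' @param rel_tolerance Relative tolerance on tip-depth deviation; default
#'   `1e-6`, loose enough for rounding in time-calibrated consensus trees.
#' @return A list with elements `pass` (logical), `max_deviation` (absolute),
#'   and `height`.
#' @export
validate_ultrametric <- function(tree, rel_tolerance = 1e-6) {
  d <- tip_depths(tree)
  h <- max(d)
  dev <- max(abs(d - h))
  list(pass = dev <= rel_tolerance * h, max_deviation = dev, height = h)
}

#' Phylogenetic relatedness matrix from an ultrametric tree
#'
#' Computes the matrix `A` whose entry (i, j) is the shared root-to-MRCA path
#' length of species i and j divided by the tree height, so the diagonal is
#' exactly 1. Under Brownian-motion trait evolution this is the correlation
#' matrix of species-level effects.
#'
#' @param tree A `phylo` object, ultrametric within `rel_tolerance`.
#' @param rel_tolerance Passed to [validate_ultrametric()].
#' @param force If `TRUE`, a non-ultrametric tree is coerced by extending each
#'   terminal branch so all tips reach the maximum depth (logged via a
#'   warning); otherwise non-ultrametric input is an error.
#' @return Symmetric positive semidefinite matrix with unit diagonal, row and
#'   column names the canonical species order (tree tip order).
#' @export
relatedness_matrix <- function(tree, rel_tolerance = 1e-6, force = FALSE) {
  chk <- validate_ultrametric(tree, rel_tolerance)
  if (!chk$pass) {
    if (!force) {
      stop("tree is not ultrametric (max tip-depth deviation ",
           format(chk$max_deviation), "); use force = TRUE to extend tip branches")
    }
    warning("non-ultrametric tree: extending terminal branches to equal depth")
    d <- tip_depths(tree)
    tips <- match(seq_along(tree$tip.label), tree$edge[, 2L])
    tree$edge.length[tips] <- tree$edge.length[tips] + (max(d) - d)
  }
  V <- ape::vcv(tree)
  A <- V / max(diag(V))
  diag(A) <- 1
  rn <- canonical_species(rownames(A))
  dimnames(A) <- list(rn, rn)
  A
}

#' Align a relatedness matrix with an observation table
#'
#' Restricts and orders `A` to the species present in the observations.
#' Species observed but absent from the tree are an error (silent mismatches
#' would corrupt the model); tree-only species are dropped with a message.
#'
#' @param A Relatedness matrix with species dimnames.
#' @param obs Observation table with a `species` column.
#' @return List with `A` (restricted, rows ordered by first appearance in
#'   `obs`), `obs` (with `species` canonicalized), and `dropped` (tree-only
#'   species removed from `A`).
#' @export
align_species <- function(A, obs) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), "species" %in% names(obs))
  obs$species <- canonical_species(as.character(obs$species))
  sp_obs <- unique(obs$species)
  missing_sp <- setdiff(sp_obs, rownames(A))
  if (length(missing_sp)) {
    stop("species in observations but not in the tree: ",
         paste(missing_sp, collapse = ", "))
  }
  keep <- intersect(sp_obs, rownames(A))
  if (!length(keep)) stop("no species shared between tree and observations")
  dropped <- setdiff(rownames(A), keep)
  if (length(dropped)) {
    message("dropping ", length(dropped), " tree-only species from A")
  }
  list(A = A[keep, keep, drop = FALSE], obs = obs, dropped = dropped)
}

#' Write a relatedness matrix as TSV
#' @param A Relatedness matrix.
#' @param path Output path.
#' @export
write_relatedness_tsv <- function(A, path) {
  df <- data.frame(species = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Cholesky with escalating diagonal jitter (1e-10 up to 1e-6); used wherever a
# correlation/covariance matrix may be numerically semidefinite.
chol_jitter <- function(M, jitter0 = 1e-10, max_jitter = 1e-6) {
  L <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(L)) return(L)
  j <- jitter0
  repeat {
    L <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    if (j >= max_jitter) stop("Cholesky failed even with jitter ", format(j))
    j <- j * 10
  }
}
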