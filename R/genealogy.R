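## Genealogies are ape "phylo" objects with branch lengths in coalescent
## units (2N generations). External branches connect tips to their first
## ancestral node; their lengths tau_i drive the theory of the empirical
## distribution of singletons: p_i = E[tau_i / tau1].

checkGenealogy <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("every tip must be labeled")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  invisible(tree)
}

#' External branch lengths of a genealogy
#'
#' The external branch of tip `i` connects it to its first ancestral node;
#' its length is \eqn{\tau^{(i)}}, and \eqn{\tau_1 = \sum_i \tau^{(i)}} is
#' the total external branch length (`sum()` of the returned vector).
#'
#' @param tree an ape `phylo` with branch lengths and labeled tips.
#' @return named numeric vector of external branch lengths, in tip order.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
#' externalBranchLengths(tr)  # A=1, B=1, C=3; tau1 = 5
#' @export
externalBranchLengths <- function(tree) {
  checkGenealogy(tree)
  n <- length(tree$tip.label)
  ext <- tree$edge[, 2] <= n
  tau <- numeric(n)
  tau[tree$edge[ext, 2]] <- tree$edge.length[ext]
  names(tau) <- tree$tip.label
  tau
}

#' Theoretical distribution of singletons from genealogies
#'
#' For each tree, the probability that a singleton is carried by chromosome
#' `i` equals the ratio of its external branch length to the total external
#' branch length, \eqn{\tau^{(i)}/\tau_1}. Averaging these ratios over a
#' collection of genealogies (e.g. independent loci) yields the theoretical
#' counterpart \eqn{p_i} of the empirical distribution of singletons.
#'
#' @param trees a list of `phylo` objects (or a `multiPhylo`) sharing one
#'   tip label set.
#' @return named numeric vector `p` summing to 1, aligned to the tip labels
#'   of the first tree.
#' @export
theoreticalSingletonDistribution <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("at least one tree is required")
  labs <- sort(trees[[1]]$tip.label)
  ratios <- lapply(trees, function(tr) {
    tau <- externalBranchLengths(tr)
    if (!identical(sort(names(tau)), labs))
      stop("all trees must share the same tip label set")
    tau1 <- sum(tau)
    if (tau1 == 0) return(NULL)
    (tau / tau1)[labs]
  })
  drop <- vapply(ratios, is.null, logical(1))
  if (any(drop))
    warning(sum(drop), " trees with zero total external length excluded")
  ratios <- ratios[!drop]
  if (!length(ratios)) stop("no tree with positive total external length")
  p <- Reduce(`+`, ratios) / length(ratios)
  # report in the tip order of the first tree
  p[trees[[1]]$tip.label]
}

#' Read and write genealogies in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that validate
#' the result as a genealogy (labeled tips, non-negative branch lengths).
#'
#' @param path file path.
#' @return `readGenealogy` returns a `phylo` (or `multiPhylo` when the file
#'   holds several trees); `writeGenealogy` returns `path` invisibly.
#' @export
readGenealogy <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "multiPhylo")) lapply(trees, checkGenealogy)
  else checkGenealogy(trees)
  trees
}

#' @rdname readGenealogy
#' @param tree a `phylo` or list of `phylo`.
#' @export
writeGenealogy <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
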