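# Newick serialization of phylogenies. Trees are `ape::phylo` objects;
# bootstrap supports ride on internal-node labels.

#' Read a Newick tree
#'
#' Internal node labels are interpreted as bipartition supports where numeric.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("Newick file not found: ", path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(paste0("malformed Newick: ",
                                                  conditionMessage(e))))
  if (is.null(tr)) abort(paste0("malformed Newick in ", path))
  tr
}

#' Write a tree to a Newick file
#'
#' Branch lengths keep at least six significant digits; internal node labels
#' (bootstrap supports) are preserved.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) abort("tree must be an ape phylo object")
  ape::write.tree(tree, file = path)
  invisible(path)
}
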