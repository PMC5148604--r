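#' Read and write newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that add the
#' validation the screen relies on: branch lengths must be present and
#' nonnegative, and tip labels must be unique (duplicate tips would make the
#' species-to-row alignment ambiguous).
#'
#' @param text A newick string.
#' @param file Optional path; used instead of `text` when supplied.
#' @return `parse_newick` returns an [ape::phylo] object; `write_newick`
#'   returns a newick string.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) {
    ape::read.tree(file = file)
  } else {
    if (!is.character(text) || length(text) != 1L) {
      stop("`text` must be a single newick string", call. = FALSE)
    }
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("newick parse error: ", conditionMessage(e),
                                      call. = FALSE))
  }
  if (is.null(tree)) stop("newick parse error: malformed tree string", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  tree
}

#' @rdname parse_newick
#' @param tree An [ape::phylo] tree.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  check_phylo(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    invisible(txt)
  } else {
    txt
  }
}

check_phylo <- function(tree, rooted = FALSE) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (rooted && !ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  invisible(tree)
}
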