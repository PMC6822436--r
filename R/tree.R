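#' Read a rooted phylogeny from a Newick file
#'
#' Parses one Newick string with \pkg{ape}. Missing branch lengths default to
#' 1.0 so that trees given as pure topology still yield clade depths; a
#' multifurcating top node is accepted as the root as-is.
#'
#' @param path file containing a single Newick string.
#' @return an [ape::phylo] tree.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparseable Newick in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("unparseable Newick in ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("expected a single tree in ", path, ", found ", length(tr),
           call. = FALSE)
    tr <- tr[[1L]]
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  if (any(tr$edge.length < 0))
    stop("negative branch length(s) in ", path, call. = FALSE)
  tr
}

#' Write a phylogeny to a Newick file
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Postorder edge matrix of a phylo tree (children visited before parents).
postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder")$edge
}

#' Node heights of a rooted tree
#'
#' The height of a node is the maximum path length (sum of branch lengths)
#' from the node down to any of its descendant leaves; leaves have height 0.
#' For ultrametric trees this is the usual depth of each divergence.
#'
#' @param tree an [ape::phylo] tree.
#' @return numeric vector indexed by ape node number
#'   (tips `1..Ntip`, then internal nodes).
#' @export
node_heights <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  h <- numeric(n)
  po <- ape::reorder.phylo(tree, "postorder")
  ed <- po$edge
  len <- po$edge.length
  if (is.null(len)) len <- rep(1, nrow(ed))
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1L]; c <- ed[i, 2L]
    h[p] <- max(h[p], h[c] + len[i])
  }
  h
}

# List of tip-index vectors for every node (tips included), via one postorder
# accumulation. Element k holds the tips of the clade rooted at node k.
clade_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- i
  ed <- postorder_edges(tree)
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1L]; c <- ed[i, 2L]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  out
}

# children[[k]]: the child node numbers of node k.
node_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

#' Reconcile a phylogeny with an abundance table
#'
#' Detection requires the tree's leaves and the table's taxa to be the same
#' set in the same order. With `on_mismatch = "prune_and_drop"` taxa absent
#' from the tree are dropped from the table and leaves absent from the table
#' are pruned from the tree (degree-2 nodes collapsed, branch lengths summed);
#' a summary of dropped identifiers is logged to standard error.
#'
#' @param tree an [ape::phylo] tree.
#' @param table samples x taxa count matrix.
#' @param on_mismatch `"error"` (default) or `"prune_and_drop"`.
#' @return list with elements `tree` and `table`, label sets identical and
#'   the table's columns ordered to match `tree$tip.label`.
#' @export
align_tree_and_table <- function(tree, table,
                                 on_mismatch = c("error", "prune_and_drop")) {
  on_mismatch <- match.arg(on_mismatch)
  table <- abundance_table(table)
  tips <- tree$tip.label
  taxa <- colnames(table)
  common <- intersect(tips, taxa)
  if (length(common) == 0L)
    stop("tree leaves and table taxa share no identifiers", call. = FALSE)
  extra_tree <- setdiff(tips, taxa)
  extra_tab <- setdiff(taxa, tips)
  if (length(extra_tree) || length(extra_tab)) {
    if (on_mismatch == "error") {
      off <- c(extra_tree, extra_tab)
      stop("tree/table identifier mismatch (",
           length(off), " ids), e.g.: ",
           paste(head(sort_ids(off), 10L), collapse = ", "), call. = FALSE)
    }
    if (length(extra_tree)) {
      log_msg("INFO", "pruning ", length(extra_tree),
              " tree leaf(ves) absent from table")
      tree <- ape::keep.tip(tree, common)
    }
    if (length(extra_tab))
      log_msg("INFO", "dropping ", length(extra_tab),
              " table taxon(a) absent from tree")
  }
  table <- table[, tree$tip.label, drop = FALSE]
  list(tree = tree, table = table)
}
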