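#' Normalize species labels
#'
#' Species binomials arrive from trees and trait tables with inconsistent
#' whitespace/underscore conventions. Normalization trims outer whitespace and
#' converts internal runs of whitespace to a single underscore; case is
#' preserved. All matching between trees and tables is exact after this
#' normalization.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_labels(c("Sphenodon punctatus", " Caiman  crocodilus "))
normalize_labels <- function(x) {
  x <- trimws(x)
  gsub("[[:space:]]+", "_", x)
}

#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. Beyond parsing, it
#' enforces the invariants the downstream covariance machinery relies on:
#' unique tip labels (after normalization), finite non-negative branch
#' lengths, and a single root. Missing branch lengths default to 1 with a
#' warning, consistent with the unit-branch convention used for composite
#' trees; `strict = TRUE` rejects them instead.
#'
#' @param text A single Newick statement terminated by ";". Exactly one of
#'   `text`/`file` must be given.
#' @param file Path to a file containing one Newick statement.
#' @param strict If `TRUE`, missing branch lengths are an error rather than
#'   defaulting to 1.
#' @return An object of class `phylo` with normalized, unique tip labels.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
read_newick <- function(text = NULL, file = NULL, strict = FALSE) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file, call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text) || !grepl(";\\s*$", text)) {
    stop("Newick parse error: statement must end with ';'", call. = FALSE)
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf(
      "Newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
      n_open, n_close
    ), call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unparseable statement", call. = FALSE)
  tree$tip.label <- normalize_labels(gsub("^['\"]|['\"]$", "", tree$tip.label))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  n_edge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) {
    if (strict) stop("branch lengths missing and strict = TRUE", call. = FALSE)
    warning("no branch lengths in Newick; defaulting all to 1", call. = FALSE)
    tree$edge.length <- rep(1, n_edge)
  } else if (anyNA(tree$edge.length)) {
    if (strict) stop("branch lengths missing and strict = TRUE", call. = FALSE)
    warning(sum(is.na(tree$edge.length)),
      " missing branch length(s); defaulting to 1",
      call. = FALSE
    )
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(!is.finite(tree$edge.length))) {
    stop("non-finite branch length in tree", call. = FALSE)
  }
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    # name the offending token by the subtended tip/node
    child <- tree$edge[neg[1], 2]
    lab <- if (child <= length(tree$tip.label)) tree$tip.label[child] else paste0("node ", child)
    stop(sprintf(
      "negative branch length %g on branch to %s",
      tree$edge.length[neg[1]], lab
    ), call. = FALSE)
  }
  tree
}

#' Write a phylogeny as a Newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (default 10, enough to
#'   round-trip through [read_newick()]).
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly the requested tips, suppressing internal nodes of degree
#' two by summing their branch lengths, so patristic distances among the
#' retained tips are unchanged (pure sum-of-branch arithmetic, nothing is
#' re-estimated).
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to keep (at least 2). Matched
#'   after [normalize_labels()].
#' @return The pruned `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' write_newick(prune_to_taxa(tr, c("A", "C")))
prune_to_taxa <- function(tree, taxa) {
  taxa <- unique(normalize_labels(taxa))
  if (length(taxa) < 2) stop("need at least 2 taxa to prune to", call. = FALSE)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ape::keep.tip(tree, taxa)
}

#' Root-to-tip distances
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector of root-to-tip path lengths, one per tip.
#' @export
root_to_tip <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Test whether a tree is ultrametric
#'
#' A tree is ultrametric when all root-to-tip path lengths agree within a
#' relative tolerance. Non-ultrametric trees (e.g. molecular trees that are
#' not time-calibrated) need per-taxon fixed-variance weights in GLS because
#' their tip variances differ.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tol Relative tolerance on the spread of root-to-tip distances.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- root_to_tip(tree)
  (max(d) - min(d)) <= tol * max(max(d), .Machine$double.eps)
}

#' Phylogenetic variance-covariance matrix under Brownian motion
#'
#' Under Brownian motion the covariance of a trait between species i and j is
#' proportional to the depth of their most recent common ancestor: the
#' root-to-MRCA path length. This returns that matrix (the Brownian rate
#' sigma^2 is factored out and estimated later by the GLS machinery), with the
#' diagonal equal to root-to-tip path lengths.
#'
#' @param tree A `phylo` object with >= 2 tips and branch lengths.
#' @return A `phylo_vcv` object: the n x n matrix with taxa as dimnames and
#'   attributes `model_tag = "BM"` and `weights = NULL`.
#' @export
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
phylo_vcv <- function(tree) {
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 tips", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  V <- ape::vcv.phylo(tree)
  zero <- diag(V) <= 0
  if (any(zero)) {
    stop(
      "tip(s) at zero distance from the root (degenerate variance): ",
      paste(rownames(V)[zero], collapse = ", "),
      call. = FALSE
    )
  }
  new_phylo_vcv(V, model_tag = "BM")
}

new_phylo_vcv <- function(V, model_tag, weights = NULL) {
  structure(V, model_tag = model_tag, weights = weights, class = c("phylo_vcv", "matrix", "array"))
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat(
    "Phylogenetic covariance for", nrow(x), "taxa; model:",
    attr(x, "model_tag"),
    if (!is.null(attr(x, "weights"))) "(fixed-variance weights attached)" else "",
    "\n"
  )
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Build a composite tree from a backbone and per-clade subtrees
#'
#' Merges independently published clade trees on a fixed backbone cladogram.
#' Because the source trees are on incomparable branch-length scales, the
#' default mode sets every branch length of the merged tree to unity;
#' `mode = "retain-subtree-lengths"` keeps within-clade branch lengths and
#' uses unit lengths only for the backbone edges.
#'
#' @param backbone A `phylo` object or Newick string whose tips name the
#'   clades (default three-clade reptile arrangement
#'   `"(Squamata,(Testudines,Crocodilia));"`).
#' @param subtrees Named list of `phylo` objects, names matching backbone tips.
#'   Tip sets must be pairwise disjoint.
#' @param mode `"unit-all"` (default) or `"retain-subtree-lengths"`.
#' @return A `phylo` object whose tip set is the union of the subtree tips.
#' @export
build_composite <- function(backbone = "(Squamata,(Testudines,Crocodilia));",
                            subtrees,
                            mode = c("unit-all", "retain-subtree-lengths")) {
  mode <- match.arg(mode)
  if (is.character(backbone)) {
    backbone <- suppressWarnings(read_newick(backbone))
  }
  if (is.null(names(subtrees)) || any(!nzchar(names(subtrees)))) {
    stop("`subtrees` must be a fully named list", call. = FALSE)
  }
  names(subtrees) <- normalize_labels(names(subtrees))
  used <- intersect(backbone$tip.label, names(subtrees))
  orphan_tips <- setdiff(backbone$tip.label, names(subtrees))
  if (length(orphan_tips)) {
    stop("backbone tip(s) with no matching subtree: ",
      paste(orphan_tips, collapse = ", "),
      call. = FALSE
    )
  }
  all_tips <- unlist(lapply(subtrees[used], function(t) t$tip.label))
  dup <- unique(all_tips[duplicated(all_tips)])
  if (length(dup)) {
    stop("tip(s) present in more than one subtree: ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  # splice subtree Newick text into the backbone topology at each clade tip
  keep_lengths <- mode == "retain-subtree-lengths"
  if (length(backbone$tip.label) == 1) {
    out <- subtrees[[backbone$tip.label]]
    if (!keep_lengths) out$edge.length <- rep(1, nrow(out$edge))
    return(out)
  }
  skeleton <- ape::write.tree(backbone)
  skeleton <- gsub(":[0-9.eE+-]+", "", skeleton) # topology only
  for (clade in used) {
    sub <- subtrees[[clade]]
    if (length(sub$tip.label) == 1) {
      piece <- sub$tip.label
    } else {
      sub_txt <- if (keep_lengths) {
        ape::write.tree(sub, digits = 10)
      } else {
        tmp <- sub
        tmp$edge.length <- NULL
        ape::write.tree(tmp)
      }
      piece <- sub(";$", "", sub_txt)
    }
    clade_re <- gsub("([][{}()*+?.\\\\^$|])", "\\\\\\1", clade)
    skeleton <- sub(
      paste0("(?<=[(,])", clade_re, "(?=[,)])"),
      piece, skeleton,
      perl = TRUE
    )
  }
  out <- suppressWarnings(read_newick(skeleton))
  if (keep_lengths) {
    # unit lengths only where the spliced text carried none (backbone edges)
    # read_newick has already defaulted those to 1
  } else {
    out$edge.length <- rep(1, nrow(out$edge))
  }
  out
}

#' Per-tip depth summary of a tree
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A tibble with columns `tip`, `root_to_tip` (path length) and
#'   `depth_edges` (number of edges from the root).
#' @export
tree_summary <- function(tree) {
  ntip <- length(tree$tip.label)
  depth_len <- root_to_tip(tree)
  # edge counts from root to each node
  depth_edges <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    depth_edges[ord$edge[k, 2]] <- depth_edges[ord$edge[k, 1]] + 1L
  }
  tibble::tibble(
    tip = tree$tip.label,
    root_to_tip = unname(depth_len),
    depth_edges = depth_edges[seq_len(ntip)]
  )
}
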