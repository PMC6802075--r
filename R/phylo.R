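#' Read a time-calibrated tree from a Newick file
#'
#' Parses a Newick tree (branch lengths in million years), validates it as a
#' time tree and reports basic structure.  Quoted labels, square-bracket
#' comments and polytomies are accepted; the tree need not be strictly
#' ultrametric but the tip-depth spread is checked and a warning emitted when
#' it exceeds `1e-6` of the tree depth.
#'
#' @param path Path to a Newick file, or a Newick string ending in `;`.
#' @return An object of class `phylo` (from \pkg{ape}).
#' @export
read_time_tree <- function(path) {
  txt <- if (grepl(";\\s*$", path[1]) && !file.exists(path[1])) path[1] else {
    if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick: could not parse '", substr(txt, 1, 40), "'", call. = FALSE)
  validate_time_tree(tree)
  tree
}

#' Validate a phylogeny as a time tree
#'
#' Checks the invariants required downstream: unique tip labels, branch
#' lengths present, finite and non-negative, a single root, positive depth.
#' Reports (invisibly) the tip count, tree depth and tip-depth spread.
#'
#' @param tree A `phylo` object.
#' @return Invisibly, a list with `n_tips`, `depth` and `depth_spread`.
#' @export
validate_time_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("non-finite branch length present", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length present", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  depths <- node_heights(tree)[seq_along(tree$tip.label)]
  depth <- max(depths)
  if (depth <= 0) stop("tree depth must be > 0", call. = FALSE)
  spread <- depth - min(depths)
  if (spread > 1e-6 * depth)
    warning("tree is not ultrametric (tip-depth spread ", signif(spread, 4),
            " My); per-tip depths will be used", call. = FALSE)
  invisible(list(n_tips = length(tree$tip.label), depth = depth,
                 depth_spread = spread))
}

#' Node heights measured forward from the root
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over all nodes (tips first, in `tip.label` order,
#'   then internal nodes), each the time in My from the root.
#' @export
node_heights <- function(tree) {
  ape::node.depth.edgelength(tree) + root_edge_length(tree)
}

# basal branch retained by pruning so original root-to-tip times survive
root_edge_length <- function(tree) {
  if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Prune a time tree to a set of tips
#'
#' Returns the induced subtree on `keep`: root-to-tip distances of kept tips
#' are preserved exactly and internal degree-2 nodes are merged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip names to retain (at least 2).
#' @return A pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(keep) < 2) stop("need at least 2 tips to keep", call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  pr <- ape::keep.tip(tree, keep)
  # keep the path down to the original root as a root edge so root-to-tip
  # distances are preserved exactly
  mrca <- if (length(keep) == 1) match(keep, tree$tip.label) else
    ape::getMRCA(tree, keep)
  basal <- unname(node_heights(tree)[mrca])
  pr$root.edge <- if (basal > 0) basal else NULL
  pr
}

#' Describe a derived-regime clade for painting
#'
#' @param tips Character vector of tip names whose MRCA defines the clade
#'   (a single name gives a monotypic clade on that pendant branch).
#' @param regime Regime label for the clade.
#' @param include_stem Paint the clade's stem branch too (the regime shift is
#'   placed at the root of the stem lineage)?  Default `TRUE`.
#' @return A `regime_clade` specification.
#' @export
regime_clade <- function(tips, regime, include_stem = TRUE) {
  stopifnot(is.character(tips), length(tips) >= 1,
            is.character(regime), length(regime) == 1)
  structure(list(tips = tips, regime = regime, include_stem = include_stem),
            class = "regime_clade")
}

# child -> all nodes of the subtree rooted at `node` (including itself)
descendant_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    stack <- c(stack, tree$edge[tree$edge[, 1] == cur, 2])
  }
  out
}

resolve_mrca <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip name(s) in clade spec: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(tips) == 1) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Paint selective regimes onto a tree
#'
#' Assigns every branch of the tree to a selective regime.  Each clade in
#' `clades` (and, when `include_stem`, its stem branch) is painted with the
#' clade's regime; all remaining branches carry the background regime.
#' Clades must be disjoint and non-nested.
#'
#' @param tree A `phylo` object.
#' @param clades List of [regime_clade()] specifications (may be empty for a
#'   uniform painting).
#' @param background Label of the background (root) regime.
#' @return A `regime_painting`: a tibble with one row per branch segment
#'   (`edge`, `parent`, `child`, `start`, `end`, `regime`; heights forward
#'   from the root), with attributes `regimes` and `background`.
#' @export
paint_regimes <- function(tree, clades = list(), background = "background") {
  if (inherits(clades, "regime_clade")) clades <- list(clades)
  heights <- node_heights(tree)
  ne <- nrow(tree$edge)
  regime <- rep(background, ne)
  owner <- rep(NA_character_, ne)
  for (cl in clades) {
    if (!inherits(cl, "regime_clade"))
      stop("each clade must be a regime_clade()", call. = FALSE)
    mrca <- resolve_mrca(tree, cl$tips)
    if (mrca == ape::Ntip(tree) + 1)
      stop("clade '", cl$regime, "' spans the whole tree (no stem)", call. = FALSE)
    nodes <- descendant_nodes(tree, mrca)
    idx <- which(tree$edge[, 2] %in% nodes)   # includes the stem edge (child == mrca)
    if (!cl$include_stem) idx <- setdiff(idx, which(tree$edge[, 2] == mrca))
    clash <- !is.na(owner[idx])
    if (any(clash))
      stop("overlapping or nested clade assignments: '", cl$regime, "' vs '",
           unique(owner[idx][clash])[1], "'", call. = FALSE)
    owner[idx] <- cl$regime
    regime[idx] <- cl$regime
  }
  out <- tibble::tibble(
    edge = seq_len(ne),
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    start = heights[tree$edge[, 1]],
    end = heights[tree$edge[, 2]],
    regime = regime
  )
  structure(out,
            class = c("regime_painting", class(out)),
            regimes = unique(c(background, vapply(clades, `[[`, "", "regime"))),
            background = background)
}

#' Check painting invariants against a tree
#'
#' Verifies that every branch is fully painted by contiguous, non-overlapping
#' segments whose lengths sum exactly to the branch length.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_painting <- function(tree, painting) {
  ne <- nrow(tree$edge)
  by_edge <- split(painting[c("start", "end")], painting$edge)
  if (!setequal(names(by_edge), as.character(seq_len(ne))))
    stop("painting does not cover every branch", call. = FALSE)
  heights <- node_heights(tree)
  for (e in seq_len(ne)) {
    seg <- by_edge[[as.character(e)]]
    seg <- seg[order(seg$start), ]
    b0 <- heights[tree$edge[e, 1]]; b1 <- heights[tree$edge[e, 2]]
    ok <- abs(seg$start[1] - b0) < 1e-9 && abs(seg$end[nrow(seg)] - b1) < 1e-9 &&
      (nrow(seg) == 1 || all(abs(seg$start[-1] - seg$end[-nrow(seg)]) < 1e-9))
    if (!ok) stop("branch ", e, " not contiguously painted", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-lineage regime histories
#'
#' Walks each root-to-tip path and concatenates the painted segments along
#' it, giving the regime occupancy of every lineage through time.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting` for `tree`.
#' @return Tibble with columns `tip`, `t_start`, `t_end`, `regime`; for each
#'   tip the rows partition `[0, T_i]` in order.
#' @export
lineage_histories <- function(tree, painting) {
  n <- ape::Ntip(tree)
  re <- root_edge_length(tree)
  bg <- attr(painting, "background")
  parent_edge <- integer(max(tree$edge))        # node -> edge above it
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  res <- vector("list", n)
  pt <- as.data.frame(painting)
  for (i in seq_len(n)) {
    edges <- integer(0)
    node <- i
    while (node != root) {
      e <- parent_edge[node]
      edges <- c(e, edges)
      node <- tree$edge[e, 1]
    }
    seg <- pt[pt$edge %in% edges, c("edge", "start", "end", "regime")]
    seg <- seg[order(seg$start), ]
    if (re > 0)   # retained basal path carries the background regime
      seg <- rbind(data.frame(edge = 0L, start = 0, end = re, regime = bg),
                   seg)
    run <- cumsum(c(TRUE, seg$regime[-1] != seg$regime[-nrow(seg)]))
    res[[i]] <- tibble::tibble(
      tip = tree$tip.label[i],
      t_start = as.numeric(tapply(seg$start, run, min)),
      t_end = as.numeric(tapply(seg$end, run, max)),
      regime = seg$regime[!duplicated(run)])
  }
  dplyr::bind_rows(res)
}

#' Stem age of a clade
#'
#' Age, measured back from the present (the deepest tip), of the node at the
#' base of the clade's stem branch — i.e. the time the lineage leading to the
#' clade split from its sister group.
#'
#' @param tree A `phylo` object.
#' @param tips Tip names whose MRCA defines the clade.
#' @return Age in My before present.
#' @export
stem_age <- function(tree, tips) {
  mrca <- resolve_mrca(tree, tips)
  if (mrca == ape::Ntip(tree) + 1)
    stop("clade spans the whole tree: it has no stem", call. = FALSE)
  heights <- node_heights(tree)
  stem_parent <- tree$edge[tree$edge[, 2] == mrca, 1]
  max(heights[seq_len(ape::Ntip(tree))]) - heights[stem_parent]
}

#' Export a painting as a sidecar table
#'
#' @param painting A `regime_painting`.
#' @param path File to write (comma-separated: `branch_id,start,end,regime`).
#' @return The path, invisibly.
#' @export
write_painting <- function(painting, path) {
  readr::write_csv(
    tibble::tibble(branch_id = painting$edge, start = painting$start,
                   end = painting$end, regime = painting$regime),
    path)
  invisible(path)
}

#' Export a painted tree as SIMMAP-style annotated Newick
#'
#' Branches are annotated `{regime,length:...}` segments in the
#' tip-to-root order used by stochastic-map readers.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting` for `tree`.
#' @param path Optional file; when `NULL` the string is returned.
#' @return The annotated Newick string (invisibly when written to file).
#' @export
write_simmap <- function(tree, painting, path = NULL) {
  pt <- as.data.frame(painting)
  branch_lab <- function(e) {
    seg <- pt[pt$edge == e, ]
    seg <- seg[order(-seg$start), ]       # tip-to-root order
    paste0("{", paste(sprintf("%s,%.8g", seg$regime, seg$end - seg$start),
                      collapse = ":"), "}")
  }
  n <- ape::Ntip(tree)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  build <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    lab <- if (node <= n) tree$tip.label[node] else
      paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
    if (node == n + 1L) return(paste0(lab, ";"))
    paste0(lab, ":", branch_lab(parent_edge[node]))
  }
  s <- build(n + 1L)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
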