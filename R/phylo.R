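# Ortholog-group linking and parsimony-based assignment of the ancestor in
# which a lncRNA first appeared.

#' Link pairwise orthologs into ortholog groups
#'
#' Greedy transitive linking: given pairs \{A,B\} and \{B,C\}, the group is
#' \{A,B,C\} even if the pairing \{A,C\} was never observed.  Groups are the
#' connected components of the pair graph.
#'
#' @param pairs data.frame with columns `species_a`, `id_a`, `species_b`,
#'   `id_b`; ids must be unique within a species.
#' @return List of character vectors of `"species:id"` members, in
#'   deterministic order.
#' @export
link_ortholog_groups <- function(pairs) {
  if (nrow(pairs) == 0L) return(list())
  va <- paste0(pairs$species_a, ":", pairs$id_a)
  vb <- paste0(pairs$species_b, ":", pairs$id_b)
  g <- igraph::graph_from_data_frame(data.frame(from = va, to = vb),
                                     directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, function(x) sort(unname(x)))
  names(groups) <- NULL
  groups[order(vapply(groups, `[[`, "", 1L))]
}

# internal: children list, depths and labels for an ape phylo tree
tree_structure <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- vector("list", n_node)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; c <- tree$edge[r, 2]
    children[[p]] <- c(children[[p]], c)
  }
  root <- n_tip + 1L
  depth <- rep(NA_integer_, n_node)
  depth[root] <- 0L
  # preorder
  stack <- root
  order_pre <- integer(0)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    order_pre <- c(order_pre, v)
    for (c in children[[v]]) {
      depth[c] <- depth[v] + 1L
      stack <- c(c, stack)
    }
  }
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) && length(tree$node.label))
                tree$node.label
              else paste0("node", seq_len(tree$Nnode) + n_tip))
  labels[labels == "" | is.na(labels)] <-
    paste0("node", which(labels == "" | is.na(labels)))
  list(n_tip = n_tip, n_node = n_node, children = children, root = root,
       depth = depth, preorder = order_pre, labels = labels)
}

# ancestors of node v (inclusive), root first
ancestors_of <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- v
  while (!is.na(parent[v])) {
    v <- parent[v]
    path <- c(v, path)
  }
  path
}

#' Parsimony last common ancestor of a presence/absence profile
#'
#' Minimum-change (Fitch parsimony, computed by Sankoff dynamic programming
#' over the two states) reconstruction of presence/absence on a rooted
#' species tree.  The reported ancestor is the most recent node that (a) is
#' an ancestor of (or equal to) every present leaf and (b) carries the
#' "present" state in at least one minimum-change labeling.  When parsimony
#' alone cannot pin the origin to a single node, the most recent candidate is
#' chosen (a conservative age estimate) and `tie_broken` is set.
#'
#' @param tree An `ape` phylo object (rooted; multifurcations allowed) or a
#'   Newick string.
#' @param profile Named logical vector of presence, covering every tip.
#' @return List with `node` (label), `node_id`, `tie_broken`, `min_changes`.
#' @export
fitch_lca <- function(tree, profile) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  st <- tree_structure(tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(profile))) {
    stop("profile must cover all tree leaves; missing: ",
         paste(setdiff(tips, names(profile)), collapse = ", "))
  }
  pres <- as.logical(profile[tips])
  if (!any(pres)) stop("all-absent profile: no ancestor to assign")
  INF <- 1e9
  # states: 1 = absent, 2 = present; unit change cost
  up <- matrix(0, nrow = st$n_node, ncol = 2)
  for (i in seq_len(st$n_tip)) {
    up[i, ] <- if (pres[i]) c(INF, 0) else c(0, INF)
  }
  for (v in rev(st$preorder)) {
    if (v <= st$n_tip) next
    for (s in 1:2) {
      tot <- 0
      for (c in st$children[[v]]) {
        tot <- tot + min(up[c, s], up[c, 3 - s] + 1)
      }
      up[v, s] <- tot
    }
  }
  down <- matrix(0, nrow = st$n_node, ncol = 2)
  for (v in st$preorder) {
    if (v == st$root) { down[v, ] <- c(0, 0); next }
    # parent p, siblings b
    p <- ancestors_of(tree, v)
    p <- p[length(p) - 1L]
    sibs <- setdiff(st$children[[p]], v)
    for (s in 1:2) {
      best <- INF
      for (sp in 1:2) {
        val <- down[p, sp] + (if (sp != s) 1 else 0)
        for (b in sibs) val <- val + min(up[b, sp], up[b, 3 - sp] + 1)
        best <- min(best, val)
      }
      down[v, s] <- best
    }
  }
  global_min <- min(up[st$root, ])
  present_tips <- which(pres)
  mrca <- if (length(present_tips) == 1L) present_tips else {
    ape::getMRCA(tree, tips[present_tips])
  }
  path <- ancestors_of(tree, mrca)     # root ... mrca
  cand <- path[vapply(path, function(v) {
    up[v, 2] + down[v, 2] == global_min
  }, TRUE)]
  if (length(cand) == 0L) cand <- mrca   # mrca always ancestral to presents
  lca <- cand[which.max(st$depth[cand])]
  list(node = st$labels[lca], node_id = lca,
       tie_broken = length(cand) > 1L, min_changes = global_min)
}

#' Assign an ancestral origin to each ortholog group
#'
#' @param groups List from [link_ortholog_groups()] (members `"species:id"`).
#' @param tree Species tree (phylo or Newick string).
#' @return data.frame with `group`, `members`, `n_species`, `lca`,
#'   `tie_broken`.
#' @export
assign_group_lca <- function(groups, tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tips <- tree$tip.label
  rows <- lapply(seq_along(groups), function(i) {
    sp <- unique(sub(":.*$", "", groups[[i]]))
    profile <- setNames(tips %in% sp, tips)
    res <- fitch_lca(tree, profile)
    data.frame(group = i, members = paste(groups[[i]], collapse = ","),
               n_species = length(sp), lca = res$node,
               tie_broken = res$tie_broken)
  })
  do.call(rbind, rows)
}
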