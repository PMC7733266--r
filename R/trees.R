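# Newick I/O, neighbor-joining fallback tree builder, LCA gene-tree /
# species-tree reconciliation, clade-absence reporting and ortholog naming.
# Trees are ape "phylo" objects throughout.

#' Parse a Newick string (or file) into a rooted tree
#'
#' Internal node labels (e.g. support values) and branch lengths are
#' preserved. Multifurcations are resolved left-associatively into a
#' binary tree with zero-length internal branches, with a warning.
#'
#' @param text Newick string, or path to a file containing one.
#' @param resolve_multifurcations resolve polytomies (required by
#'   reconciliation)?
#' @return An ape `phylo` object.
#' @export
parse_newick <- function(text, resolve_multifurcations = TRUE) {
  tr <- if (file.exists(text) && !grepl("\\(", text))
    ape::read.tree(text) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!ape::is.binary(tr)) {
    if (!resolve_multifurcations) stop("tree is not binary")
    warning("multifurcating tree resolved left-associatively")
    tr <- ape::multi2di(tr, random = FALSE)
  }
  tr
}

#' Serialize a tree to Newick
#' @param tree an ape `phylo`.
#' @param path optional path; when given the text is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Neighbor-joining tree with midpoint rooting
#'
#' Desk-scale fallback tree builder (the pipeline treats published trees
#' as first-class inputs): classical neighbor joining on a symmetric
#' distance matrix, midpoint-rooted so it can feed reconciliation.
#'
#' @param dist symmetric non-negative distance matrix with taxon dimnames.
#' @return A rooted ape `phylo`.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop("need at least 3 taxa")
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix not symmetric")
  tr <- ape::nj(as.dist(dist))
  tr$edge.length[tr$edge.length < 0] <- 0
  phangorn::midpoint(tr)
}

# ---- tree utilities on phylo objects ---------------------------------------

tree_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent  # root has parent 0
}

tree_depths <- function(tree) {
  parent <- tree_parents(tree)
  n <- length(parent)
  depth <- rep(NA_integer_, n)
  root <- ape::Ntip(tree) + 1L
  depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    depth[kids] <- depth[v] + 1L
    queue <- c(queue, kids)
  }
  depth
}

# least common ancestor of a set of node indices
tree_lca <- function(parent, depth, nodes) {
  nodes <- unique(nodes)
  while (length(nodes) > 1L) {
    dmax <- max(depth[nodes])
    deepest <- which(depth[nodes] == dmax)[1]
    nodes[deepest] <- parent[nodes[deepest]]
    nodes <- unique(nodes)
  }
  nodes
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps each gene-tree node to the species-tree least common ancestor of
#' its descendant leaves' species. A node is a duplication iff its mapping
#' equals the mapping of at least one child; otherwise a speciation.
#' Losses are counted along each gene-tree edge by the path-depth rule:
#' for an edge from parent `g` to child `c`, `dist(M(g), M(c)) - 1` losses
#' under a speciation at `g` and `dist(M(g), M(c))` under a duplication,
#' where `dist` is the number of species-tree edges between the mappings.
#' The totals are the minimum duplication-loss reconciliation for the
#' given rooting.
#'
#' @param gene_tree rooted binary ape `phylo`.
#' @param species_tree rooted binary ape `phylo`.
#' @param leaf_map named character vector: gene leaf label -> species leaf
#'   label.
#' @param try_all_rootings when `TRUE`, rerooting on every edge is tried
#'   and the duplication-minimizing rooting (ties: fewest losses) is kept.
#' @return A `reconciliation` list: `events` data.frame (gene node index,
#'   label of mapped species node, event), `total_duplications`,
#'   `total_losses`, `loss_branches` (species-tree node indices below
#'   which a loss is inferred, with multiplicity), and the (possibly
#'   rerooted) `gene_tree`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map,
                          try_all_rootings = FALSE) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!ape::is.binary(gene_tree) || !ape::is.binary(species_tree))
    stop("reconciliation requires binary trees")
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_map))
  if (length(unmapped))
    stop("unmapped gene leaves: ", paste(unmapped, collapse = ", "))
  if (!all(leaf_map[gene_tree$tip.label] %in% species_tree$tip.label))
    stop("leaf_map targets absent from species tree")

  if (try_all_rootings) {
    cands <- list(gene_tree)
    ut <- ape::unroot(gene_tree)
    for (e in seq_len(nrow(ut$edge))) {
      node <- ut$edge[e, 2]
      rt <- tryCatch({
        if (node <= ape::Ntip(ut))
          ape::root(ut, outgroup = ut$tip.label[node], resolve.root = TRUE)
        else ape::root(ut, node = node, resolve.root = TRUE)
      }, error = function(e) NULL)
      if (!is.null(rt) && ape::is.binary(rt)) cands <- c(cands, list(rt))
    }
    recs <- lapply(cands, function(tr)
      lca_reconcile(tr, species_tree, leaf_map, try_all_rootings = FALSE))
    score <- vapply(recs, function(r)
      r$total_duplications * 1e6 + r$total_losses, numeric(1))
    return(recs[[which.min(score)]])
  }

  sp_parent <- tree_parents(species_tree)
  sp_depth <- tree_depths(species_tree)
  g_ntip <- ape::Ntip(gene_tree)
  g_n <- g_ntip + gene_tree$Nnode

  # mapping M: gene node -> species node index
  M <- integer(g_n)
  M[seq_len(g_ntip)] <-
    match(unname(leaf_map[gene_tree$tip.label]), species_tree$tip.label)
  po <- ape::reorder.phylo(gene_tree, "postorder")
  kids_of <- split(po$edge[, 2], po$edge[, 1])
  for (v in unique(po$edge[, 1])) {  # postorder: children before parents
    M[v] <- tree_lca(sp_parent, sp_depth, M[kids_of[[as.character(v)]]])
  }

  internal <- (g_ntip + 1L):g_n
  event <- vapply(internal, function(v) {
    if (any(M[kids_of[[as.character(v)]]] == M[v])) "duplication" else "speciation"
  }, character(1))
  names(event) <- internal

  losses <- 0L
  loss_branches <- integer(0)
  for (e in seq_len(nrow(gene_tree$edge))) {
    g <- gene_tree$edge[e, 1]; ch <- gene_tree$edge[e, 2]
    d <- sp_depth[M[ch]] - sp_depth[M[g]]
    dup <- event[[as.character(g)]] == "duplication"
    # walk the species path from M(ch) up to M(g); each step's sibling
    # branch hosts a loss, except (for speciations) the topmost step
    node <- M[ch]
    path <- integer(0)
    while (node != M[g]) { path <- c(path, node); node <- sp_parent[node] }
    skip_top <- if (dup) 0L else 1L
    if (length(path) > skip_top) {
      for (s in path[seq_len(length(path) - skip_top)]) {
        sibs <- setdiff(which(sp_parent == sp_parent[s]), s)
        loss_branches <- c(loss_branches, sibs)
        losses <- losses + length(sibs)
      }
    }
  }

  sp_labels <- c(species_tree$tip.label,
                 if (!is.null(species_tree$node.label) &&
                     length(species_tree$node.label) == species_tree$Nnode)
                   species_tree$node.label
                 else paste0("n", (ape::Ntip(species_tree) + 1L):
                               (ape::Ntip(species_tree) + species_tree$Nnode)))
  structure(list(
    events = data.frame(gene_node = internal,
                        species_node = sp_labels[M[internal]],
                        event = unname(event), stringsAsFactors = FALSE),
    mapping = M,
    total_duplications = sum(event == "duplication"),
    total_losses = losses,
    loss_branches = sp_labels[loss_branches],
    gene_tree = gene_tree),
    class = "reconciliation")
}

#' Report taxon groups absent from named gene clades
#'
#' For each named clade (a set of gene-tree leaf labels), lists which of
#' the supplied taxon groups (sets of species labels) have no
#' representative among that clade's species.
#'
#' @param gene_tree ape `phylo`.
#' @param species_tree ape `phylo` (all group members must be its leaves).
#' @param leaf_map gene leaf -> species leaf map.
#' @param clade_label_sets named list: clade name -> character vector of
#'   gene-tree leaf labels.
#' @param taxon_groups named list: group name -> species labels.
#' @return data.frame with columns `clade` and `absent_group` (one row per
#'   absence; zero rows when nothing is absent).
#' @export
clade_absence_report <- function(gene_tree, species_tree, leaf_map,
                                 clade_label_sets, taxon_groups) {
  out <- data.frame(clade = character(0), absent_group = character(0),
                    stringsAsFactors = FALSE)
  for (cl in names(clade_label_sets)) {
    leaves <- clade_label_sets[[cl]]
    if (!length(leaves)) next
    sp <- unname(leaf_map[leaves])
    for (g in names(taxon_groups)) {
      members <- intersect(taxon_groups[[g]], species_tree$tip.label)
      if (length(members) && !any(members %in% sp))
        out <- rbind(out, data.frame(clade = cl, absent_group = g,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

#' Name query genes after their reference orthologs
#'
#' Each query leaf is assigned the family name of the reference leaves in
#' the smallest clade containing the query and at least one reference.
#' When that clade holds references with several names, the majority name
#' wins and exact ties give `"ambiguous"`. Multiple same-species queries
#' sharing a name get numeric suffixes in gene-tree leaf order (e.g.
#' `CLC-C1`, `CLC-C2`).
#'
#' @param gene_tree ape `phylo`.
#' @param reference_labels named character vector: reference leaf label ->
#'   family name (e.g. `c("AtCLC-C" = "CLC-C")`).
#' @param queries character vector of query leaf labels.
#' @param leaf_map optional gene leaf -> species map used for the
#'   same-species suffix rule; by default every query counts as one
#'   species.
#' @return Named character vector: query -> assigned name.
#' @export
assign_ortholog_names <- function(gene_tree, reference_labels, queries,
                                  leaf_map = NULL) {
  stopifnot(all(queries %in% gene_tree$tip.label))
  refs <- names(reference_labels)
  if (!all(refs %in% gene_tree$tip.label))
    stop("reference leaves missing from gene tree")
  parent <- tree_parents(gene_tree)
  ntip <- ape::Ntip(gene_tree)
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    kids <- which(parent == node)
    unlist(lapply(kids, tips_below))
  }
  base <- vapply(queries, function(q) {
    v <- match(q, gene_tree$tip.label)
    repeat {
      v <- parent[v]
      if (v == 0L) return("ambiguous")  # no reference anywhere (degenerate)
      tl <- gene_tree$tip.label[tips_below(v)]
      hit <- intersect(tl, refs)
      if (length(hit)) {
        nm <- table(unname(reference_labels[hit]))
        top <- names(nm)[nm == max(nm)]
        return(if (length(top) == 1L) top else "ambiguous")
      }
    }
  }, character(1))
  # numeric suffixes for same-species queries sharing a name
  sp <- if (is.null(leaf_map)) setNames(rep("q", length(queries)), queries)
        else leaf_map[queries]
  ord <- match(queries, gene_tree$tip.label)
  out <- base
  for (key in unique(paste(base, sp[queries]))) {
    idx <- which(paste(base, sp[queries]) == key & base != "ambiguous")
    if (length(idx) > 1L) {
      idx <- idx[order(ord[idx])]
      out[idx] <- paste0(base[idx], seq_along(idx))
    }
  }
  setNames(out, queries)
}
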