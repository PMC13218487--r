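#' Tree height (root age)
#' @param tree A [TimeTree-class] object.
#' @export
treeHeight <- function(tree) {
  phy <- if (is(tree, "TimeTree")) tree@phy else tree
  max(ape::node.depth.edgelength(phy))
}

#' Total tree length (sum of branch durations)
#' @param tree A [TimeTree-class] object.
#' @export
treeLength <- function(tree) {
  phy <- if (is(tree, "TimeTree")) tree@phy else tree
  sum(phy$edge.length)
}

#' Number of tips
#' @param tree A [TimeTree-class] object.
#' @export
nTips <- function(tree) ape::Ntip(if (is(tree, "TimeTree")) tree@phy else tree)

#' Newick serialization
#' @param tree A [TimeTree-class] object.
#' @export
newick <- function(tree) ape::write.tree(if (is(tree, "TimeTree")) tree@phy else tree)

# ---- internal array representation used by the simulator and the sampler ----
# tips 1..ntip, internal nodes ntip+1 .. 2*ntip-1 (any of them may be root);
# parent[root] == 0; kids is an (2n-1) x 2 matrix with NA rows for tips;
# age[tips] == 0.

phyloToArrays <- function(phy) {
  ntip <- ape::Ntip(phy)
  nnode <- 2L * ntip - 1L
  parent <- integer(nnode)
  kids <- matrix(NA_integer_, nnode, 2)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    kids[p, if (is.na(kids[p, 1])) 1 else 2] <- c
  }
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(ntip)]) - depth
  age[seq_len(ntip)] <- 0
  list(ntip = ntip, nnode = nnode, parent = parent, kids = kids,
       age = age, root = ntip + 1L, tipLabels = phy$tip.label)
}

arraysToPhylo <- function(tr) {
  ntip <- tr$ntip
  newid <- integer(tr$nnode)
  newid[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip + 1L
  stack <- tr$root
  order <- integer(0)
  while (length(stack)) {       # preorder over internal nodes
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (k in tr$kids[v, ]) if (k > ntip) stack <- c(stack, k)
  }
  for (v in order) { newid[v] <- nxt; nxt <- nxt + 1L }
  edge <- matrix(0L, 2L * ntip - 2L, 2)
  elen <- numeric(2L * ntip - 2L)
  r <- 1L
  for (v in seq_len(tr$nnode)) {
    p <- tr$parent[v]
    if (p == 0L) next
    edge[r, ] <- c(newid[p], newid[v])
    elen[r] <- tr$age[p] - tr$age[v]
    r <- r + 1L
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tr$tipLabels, Nnode = ntip - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# postorder internal node ids and matching children rows (0-based, for C++)
postorderInfo <- function(tr) {
  ntip <- tr$ntip
  nint <- ntip - 1L
  stack <- integer(nint); stack[1] <- tr$root; sp <- 1L
  pre <- integer(nint); np <- 0L
  while (sp > 0L) {                # preorder over internal nodes
    v <- stack[sp]; sp <- sp - 1L
    np <- np + 1L; pre[np] <- v
    k1 <- tr$kids[v, 1]; k2 <- tr$kids[v, 2]
    if (k1 > ntip) { sp <- sp + 1L; stack[sp] <- k1 }
    if (k2 > ntip) { sp <- sp + 1L; stack[sp] <- k2 }
  }
  post <- pre[nint:1]              # reverse preorder is a valid postorder
  list(internalIdx = as.integer(post - 1L),
       children = matrix(as.integer(tr$kids[post, ] - 1L), ncol = 2))
}

# clade key per internal node excluding the root: sorted tip labels joined ";"
cladeKeys <- function(tr) {
  ntip <- tr$ntip
  tipsets <- vector("list", tr$nnode)
  for (v in seq_len(ntip)) tipsets[[v]] <- tr$tipLabels[v]
  po <- postorderInfo(tr)
  ids <- po$internalIdx + 1L
  for (v in ids)
    tipsets[[v]] <- c(tipsets[[tr$kids[v, 1]]], tipsets[[tr$kids[v, 2]]])
  keys <- vapply(ids[ids != tr$root],
                 function(v) paste(sort(tipsets[[v]]), collapse = ";"), "")
  keys
}

# duration of the edge above each node (0 for the root)
edgeDurations <- function(tr) {
  d <- numeric(tr$nnode)
  has <- tr$parent != 0L
  d[has] <- tr$age[tr$parent[has]] - tr$age[has]
  d
}
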