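#' Construct a directed acyclic graph over named variables
#'
#' @param nodes Character vector of variable names.
#' @param arcs Two-column character matrix (or data frame) of directed arcs
#'   `from -> to`; may have zero rows.
#' @return An object of class `bn_dag`.
#' @examples
#' g <- bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' markov_blanket(g, "B")
#' @export
bn_dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(arcs) || NROW(arcs) == 0) {
    arcs <- matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  } else {
    arcs <- as.matrix(arcs)
    colnames(arcs) <- c("from", "to")
    storage.mode(arcs) <- "character"
  }
  if (any(!(arcs %in% nodes))) stop("arc endpoints must be declared nodes")
  if (any(arcs[, 1] == arcs[, 2])) stop("self-arcs are not allowed")
  if (anyDuplicated(paste(arcs[, 1], arcs[, 2]))) stop("duplicate arcs")
  g <- structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
  if (is.null(dag_topo_sort(g))) stop("graph contains a cycle")
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("<bn_dag> ", length(x$nodes), " nodes, ", nrow(x$arcs), " arcs\n", sep = "")
  if (nrow(x$arcs)) {
    apply(x$arcs, 1, function(a) cat("  ", a[1], "->", a[2], "\n"))
  }
  invisible(x)
}

#' Adjacency matrix of a DAG
#' @param dag A `bn_dag`.
#' @return Logical matrix `A[i, j]` = TRUE iff arc `i -> j` exists.
#' @export
amat <- function(dag) {
  p <- length(dag$nodes)
  A <- matrix(FALSE, p, p, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$arcs)) A[dag$arcs] <- TRUE
  A
}

#' Parent and child sets
#' @param dag A `bn_dag`.
#' @param node A node name.
#' @return Character vector of parents (children).
#' @export
dag_parents <- function(dag, node) {
  check_node(dag, node)
  unname(dag$arcs[dag$arcs[, 2] == node, 1])
}

#' @rdname dag_parents
#' @export
dag_children <- function(dag, node) {
  check_node(dag, node)
  unname(dag$arcs[dag$arcs[, 1] == node, 2])
}

check_node <- function(dag, node) {
  missing <- setdiff(node, dag$nodes)
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(node)
}

# Topological order, or NULL if cyclic.
dag_topo_sort <- function(dag) {
  A <- amat(dag)
  p <- nrow(A)
  indeg <- colSums(A)
  order <- character(0)
  active <- rep(TRUE, p)
  for (step in seq_len(p)) {
    i <- which(active & indeg == 0)[1]
    if (is.na(i)) return(NULL)
    order <- c(order, rownames(A)[i])
    active[i] <- FALSE
    indeg <- indeg - A[i, ]
    A[i, ] <- FALSE
  }
  order
}

#' Topological ordering of a DAG
#' @param dag A `bn_dag`.
#' @return Character vector of nodes in topological order.
#' @export
topo_sort <- function(dag) {
  ord <- dag_topo_sort(dag)
  if (is.null(ord)) stop("graph contains a cycle")
  ord
}

#' Markov blanket of a node
#'
#' The Markov blanket of a node is the union of its parents, its children,
#' and the other parents of its children (co-parents), excluding the node
#' itself. Conditioned on its blanket, the node is independent of every other
#' variable in the network.
#'
#' @param dag A `bn_dag`.
#' @param node A node name.
#' @return Character vector (sorted) of blanket members.
#' @export
markov_blanket <- function(dag, node) {
  check_node(dag, node)
  ch <- dag_children(dag, node)
  coparents <- unlist(lapply(ch, function(c) dag_parents(dag, c)))
  sort(setdiff(unique(c(dag_parents(dag, node), ch, coparents)), node))
}

#' Test d-separation
#'
#' Returns `TRUE` iff every path between `x` and `y` is blocked given the
#' conditioning set `z` (chains and forks blocked when their middle node is
#' in `z`; colliders blocked unless the collider or one of its descendants is
#' in `z`). Implemented by moralizing the ancestral subgraph of
#' `{x, y} U z` and checking undirected separation.
#'
#' @param dag A `bn_dag`.
#' @param x,y Node names (must not be in `z`).
#' @param z Character vector of conditioning nodes (may be empty).
#' @return Logical scalar.
#' @export
d_separated <- function(dag, x, y, z = character()) {
  check_node(dag, c(x, y, z))
  if (x %in% z || y %in% z) stop("x and y must not be in the conditioning set")
  if (x == y) return(FALSE)
  A <- amat(dag)
  # ancestral set of x, y, z
  anc <- union(c(x, y), z)
  repeat {
    pa <- rownames(A)[rowSums(A[, anc, drop = FALSE]) > 0]
    new <- union(anc, pa)
    if (length(new) == length(anc)) break
    anc <- new
  }
  Aa <- A[anc, anc, drop = FALSE]
  # moralize: marry parents of each node, drop direction
  U <- Aa | t(Aa)
  for (j in seq_len(ncol(Aa))) {
    pa <- which(Aa[, j])
    if (length(pa) > 1) U[pa, pa] <- TRUE
  }
  diag(U) <- FALSE
  # remove conditioning nodes and check connectivity x ~ y
  keep <- setdiff(anc, z)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  U <- U[keep, keep, drop = FALSE]
  reach <- x
  frontier <- x
  while (length(frontier)) {
    nb <- rownames(U)[rowSums(U[frontier, , drop = FALSE]) > 0]
    frontier <- setdiff(nb, reach)
    reach <- union(reach, frontier)
    if (y %in% reach) return(FALSE)
  }
  TRUE
}

#' Undirected skeleton and structural Hamming distance
#'
#' `skeleton()` returns the set of unordered adjacent pairs of a DAG;
#' `shd_skeleton()` counts the symmetric difference between the skeletons of
#' two DAGs over the same node set (edge insertions plus deletions).
#'
#' @param dag,dag1,dag2 `bn_dag` objects.
#' @return `skeleton()`: a two-column matrix of sorted pairs;
#'   `shd_skeleton()`: an integer.
#' @export
skeleton <- function(dag) {
  if (!nrow(dag$arcs)) return(matrix(character(), ncol = 2))
  pairs <- t(apply(dag$arcs, 1, sort))
  unique(pairs)
}

#' @rdname skeleton
#' @export
shd_skeleton <- function(dag1, dag2) {
  key <- function(d) {
    s <- skeleton(d)
    if (!nrow(s)) return(character())
    paste(s[, 1], s[, 2], sep = "~")
  }
  k1 <- key(dag1); k2 <- key(dag2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Moral graph adjacency of a DAG
#'
#' Undirected adjacency after marrying co-parents; used to calibrate which
#' bootstrap arc strengths should stay below the averaging threshold.
#'
#' @param dag A `bn_dag`.
#' @return Logical symmetric adjacency matrix.
#' @export
moral_adjacency <- function(dag) {
  A <- amat(dag)
  U <- A | t(A)
  for (j in seq_len(ncol(A))) {
    pa <- which(A[, j])
    if (length(pa) > 1) U[pa, pa] <- TRUE
  }
  diag(U) <- FALSE
  U
}

#' @export
tidy.bn_dag <- function(x, ...) {
  tibble::tibble(from = x$arcs[, 1], to = x$arcs[, 2])
}

#' @export
glance.bn_dag <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_arcs = nrow(x$arcs))
}
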