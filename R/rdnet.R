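# Assembly of the heterogeneous RDnet graph: binary association matrix,
# similarity thresholding, block weight matrix and row-stochastic
# transition operator.

#' Build the binary miRNA-disease association matrix
#'
#' Materializes the association indicator: entry `(i, j)` is 1 when miRNA
#' `i` is known-associated with disease `j`, otherwise 0. Row and column
#' order follow the supplied label vectors exactly.
#'
#' @param assoc an [association_set()].
#' @param mirna_labels,disease_labels label vectors fixing row/column order;
#'   every id in `assoc` must appear in the corresponding vector.
#' @return An `n_mirna x n_disease` 0/1 matrix with labels as dimnames.
#' @export
build_association_matrix <- function(assoc, mirna_labels, disease_labels) {
  stopifnot(inherits(assoc, "association_set"))
  missing_m <- setdiff(assoc$mirna_labels, mirna_labels)
  if (length(missing_m) > 0L)
    stop("association miRNA id not in label list: ", missing_m[1L])
  missing_d <- setdiff(assoc$disease_labels, disease_labels)
  if (length(missing_d) > 0L)
    stop("association disease id not in label list: ", missing_d[1L])
  A <- matrix(0, length(mirna_labels), length(disease_labels),
              dimnames = list(mirna_labels, disease_labels))
  if (nrow(assoc$pairs) > 0L)
    A[cbind(match(assoc$pairs$mirna, mirna_labels),
            match(assoc$pairs$disease, disease_labels))] <- 1
  A
}

#' Threshold a similarity matrix
#'
#' Zeroes every off-diagonal entry strictly below `tau`; edges at least as
#' strong as the threshold keep their similarity value as edge weight. The
#' diagonal is untouched here (it is removed later during network
#' assembly).
#'
#' @param S a [similarity_matrix()].
#' @param tau similarity cut-off in \[0, 1\].
#' @return A thresholded [similarity_matrix()]-shaped matrix.
#' @export
apply_similarity_threshold <- function(S, tau) {
  stopifnot(inherits(S, "similarity_matrix"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("tau must be a single value in [0, 1]")
  V <- unclass(S)
  d <- diag(V)
  V[V < tau] <- 0
  diag(V) <- d
  structure(V, class = class(S))
}

#' Assemble the heterogeneous RDnet network
#'
#' Combines the miRNA similarity network, the disease similarity network
#' and the bipartite association edges into one undirected weighted graph
#' over `n_mirna + n_disease` vertices. Similarity edges carry their
#' (thresholded) similarity score as weight, association edges carry
#' weight 1, self-loops are removed, and the transition operator is the
#' row normalization of the weight matrix: the walker leaves a node along
#' an incident edge with probability proportional to its weight. A node
#' left with no edges keeps the walker in place (self-transition 1).
#'
#' @param MM miRNA functional [similarity_matrix()].
#' @param DD disease phenotype [similarity_matrix()].
#' @param A binary association matrix from [build_association_matrix()];
#'   rows must match `MM` labels, columns `DD` labels.
#' @param tau similarity threshold applied to both similarity blocks
#'   (default 0 keeps every positive similarity edge).
#' @return An object of class `hetero_network`: list with `node_labels`
#'   (miRNAs then diseases), `mirna_labels`, `disease_labels`, `weights`
#'   (symmetric block matrix), `transition` (row-stochastic), `tau`.
#' @export
build_hetero_network <- function(MM, DD, A, tau = 0) {
  stopifnot(inherits(MM, "similarity_matrix"), inherits(DD, "similarity_matrix"))
  A <- as.matrix(A)
  if (nrow(A) != nrow(MM) || ncol(A) != nrow(DD))
    stop(sprintf("dimension mismatch: A is %dx%d but MM has %d and DD has %d nodes",
                 nrow(A), ncol(A), nrow(MM), nrow(DD)))
  if (!identical(rownames(A), rownames(MM)) ||
      !identical(colnames(A), rownames(DD)))
    stop("association matrix labels do not match similarity matrix labels")
  if (!all(A %in% c(0, 1))) stop("association matrix must be binary")
  MMt <- unclass(apply_similarity_threshold(MM, tau))
  DDt <- unclass(apply_similarity_threshold(DD, tau))
  diag(MMt) <- 0
  diag(DDt) <- 0
  W <- rbind(cbind(MMt, A), cbind(t(A), DDt))
  labels <- c(rownames(MM), rownames(DD))
  dimnames(W) <- list(labels, labels)
  if (all(W == 0)) stop("empty network: no edges survive assembly")
  deg <- rowSums(W)
  P <- W / ifelse(deg > 0, deg, 1)
  dangling <- which(deg == 0)
  if (length(dangling) > 0L) P[cbind(dangling, dangling)] <- 1
  structure(list(node_labels = labels,
                 mirna_labels = rownames(MM),
                 disease_labels = rownames(DD),
                 n_mirna = nrow(MM),
                 n_disease = nrow(DD),
                 weights = W,
                 transition = P,
                 tau = tau),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("hetero_network: %d miRNAs + %d diseases, %d edges (tau = %g)\n",
              x$n_mirna, x$n_disease, n_edges, x$tau))
  invisible(x)
}

#' Dump the weight matrix as labeled TSV
#'
#' Debug output: the full symmetric weight matrix with node labels.
#'
#' @param network a [build_hetero_network()] result.
#' @param path output path.
#' @export
write_weight_matrix <- function(network, path) {
  stopifnot(inherits(network, "hetero_network"))
  labels <- network$node_labels
  header <- paste(c("", labels), collapse = "\t")
  body <- vapply(seq_along(labels), function(i)
    paste(c(labels[i], format(network$weights[i, ], digits = 10,
                              trim = TRUE)), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}
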