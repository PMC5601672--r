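# Shared fixtures: the worked toy network (5 miRNAs, 5 diseases) and a
# generator of small random heterogeneous networks for property tests.

# Toy network: associations d1-m5, d1-m3, d3-m2, d4-m2; similarity edges
# m5-m1, m5-m3, m5-m4, m2-m1, m2-m3 (weight 0.5); no disease-disease edges.
toy_network <- function() {
  m <- paste0("m", 1:5)
  d <- paste0("d", 1:5)
  MM <- diag(5)
  dimnames(MM) <- list(m, m)
  for (e in list(c("m5", "m1"), c("m5", "m3"), c("m5", "m4"),
                 c("m2", "m1"), c("m2", "m3"))) {
    MM[e[1], e[2]] <- 0.5
    MM[e[2], e[1]] <- 0.5
  }
  MM <- similarity_matrix(m, MM)
  DD <- similarity_matrix(d, diag(5))
  assoc <- association_set(c("m5", "m3", "m2", "m2"),
                           c("d1", "d1", "d3", "d4"))
  A <- build_association_matrix(assoc, m, d)
  list(MM = MM, DD = DD, assoc = assoc,
       network = build_hetero_network(MM, DD, A))
}

# Random small heterogeneous network with at least one edge; returns the
# pieces plus the assembled network.
random_network <- function(n_mirna, n_disease, p_edge = 0.4) {
  repeat {
    m <- sprintf("m%02d", seq_len(n_mirna))
    d <- sprintf("d%02d", seq_len(n_disease))
    rand_sim <- function(labels) {
      n <- length(labels)
      V <- matrix(0, n, n)
      if (n > 1) {
        ut <- upper.tri(V)
        vals <- ifelse(stats::runif(sum(ut)) < p_edge,
                       stats::runif(sum(ut)), 0)
        V[ut] <- vals
        V[lower.tri(V)] <- t(V)[lower.tri(V)]
      }
      diag(V) <- 1
      similarity_matrix(labels, V)
    }
    MM <- rand_sim(m)
    DD <- rand_sim(d)
    A <- matrix(stats::rbinom(n_mirna * n_disease, 1, p_edge),
                n_mirna, n_disease, dimnames = list(m, d))
    W_off <- rbind(cbind(unclass(MM), A), cbind(t(A), unclass(DD)))
    diag(W_off) <- 0
    if (any(W_off > 0))
      return(list(MM = MM, DD = DD, A = A,
                  network = build_hetero_network(MM, DD, A)))
  }
}

# Independent closed-form oracle for the restart walk:
# p = M * (I - (1 - M) * t(P))^-1 %*% p0, computed by a direct solve.
rwr_closed_form <- function(network, p0, M) {
  n <- length(p0)
  as.numeric(solve(diag(n) - (1 - M) * t(network$transition), M * p0))
}

# Brute-force AUC oracle: P(score_pos > score_neg) + 0.5 * P(tie) over all
# positive/negative pairs.
auc_pairwise <- function(scores, positives) {
  is_pos <- names(scores) %in% positives
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

random_scores_instance <- function(n = 30) {
  # discretized scores so ties occur
  scores <- stats::setNames(round(stats::runif(n), 1),
                            sprintf("c%03d", seq_len(n)))
  n_pos <- sample(seq_len(n - 1), 1)
  list(scores = scores,
       positives = sample(names(scores), n_pos))
}
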