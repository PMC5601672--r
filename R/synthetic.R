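# Synthetic RDnet generator with planted module structure. Encodes the
# core biological assumption behind network-based miRNA prioritization:
# miRNAs with similar functions tend to associate with a common disease.
# Each miRNA module is matched one-to-one with a disease module; within
# matched modules similarities are high and associations frequent, across
# modules both are low. The planted membership is the ground truth that
# makes the whole pipeline testable offline.

#' Configuration for the synthetic RDnet generator
#'
#' Defaults define the benchmark used throughout the test suite: 100
#' miRNAs and 20 diseases in 4 matched modules, a clear similarity
#' contrast (0.6 within vs 0.1 between, noise sd 0.05) and sparse
#' preferential attachment (association probability 0.5 within a matched
#' module pair vs 0.01 across).
#'
#' @param n_mirna,n_disease node counts.
#' @param n_modules number of matched miRNA/disease modules.
#' @param sim_in,sim_out mean similarity within / between modules, each in
#'   \[0, 1\] with `sim_in >= sim_out` (equality gives the null model).
#' @param sim_noise standard deviation of the similarity noise (clipped
#'   normal).
#' @param p_in,p_out association probability for matched / unmatched
#'   module pairs, `p_in >= p_out`.
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_mirna = 100L, n_disease = 20L, n_modules = 4L,
                         sim_in = 0.6, sim_out = 0.1, sim_noise = 0.05,
                         p_in = 0.5, p_out = 0.01, seed = 1L) {
  n_mirna <- as.integer(n_mirna); n_disease <- as.integer(n_disease)
  n_modules <- as.integer(n_modules)
  if (is.na(n_modules) || n_modules < 1L) stop("n_modules must be >= 1")
  if (n_mirna < n_modules || n_disease < n_modules)
    stop("need n_mirna and n_disease >= n_modules")
  probs <- c(sim_in = sim_in, sim_out = sim_out, p_in = p_in, p_out = p_out)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (sim_in < sim_out) stop("sim_in must be >= sim_out")
  if (p_in < p_out) stop("p_in must be >= p_out")
  if (sim_noise < 0) stop("sim_noise must be >= 0")
  structure(list(n_mirna = n_mirna, n_disease = n_disease,
                 n_modules = n_modules, sim_in = sim_in, sim_out = sim_out,
                 sim_noise = sim_noise, p_in = p_in, p_out = p_out,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Symmetric similarity matrix: means by module match, independent noise on
# the upper triangle only (so sim_noise = 0 leaves exactly two off-diagonal
# values), clipped to [0, 1], unit diagonal.
planted_similarity <- function(labels, modules, sim_in, sim_out, sim_noise) {
  n <- length(labels)
  same <- outer(modules, modules, `==`)
  mu <- ifelse(same, sim_in, sim_out)
  V <- mu
  if (n > 1L) {
    ut <- upper.tri(V)
    V[ut] <- pmin(pmax(mu[ut] + stats::rnorm(sum(ut), 0, sim_noise), 0), 1)
    V[lower.tri(V)] <- t(V)[lower.tri(V)]
  }
  diag(V) <- 1
  similarity_matrix(labels, V)
}

#' Simulate a heterogeneous RDnet with planted structure
#'
#' miRNAs and diseases are assigned round-robin to `n_modules` modules;
#' miRNA module *i* is matched to disease module *i*. Pairwise
#' similarities are drawn from a normal centred on `sim_in` (same module)
#' or `sim_out` (different modules), clipped to \[0, 1\], symmetric, unit
#' diagonal. Each miRNA-disease pair is observed as a known association
#' with probability `p_in` when their modules match, `p_out` otherwise.
#' The matched-module indicator is returned as ground truth.
#'
#' @param config a [synth_config()].
#' @return List with `MM`, `DD` ([similarity_matrix()] objects),
#'   `associations` (the observed [association_set()]), `truth`
#'   (miRNA x disease 0/1 matrix of matched-module pairs), and the module
#'   assignments `mirna_modules`, `disease_modules`.
#' @export
simulate_rdnet <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    m_labels <- sprintf("m%04d", seq_len(config$n_mirna))
    d_labels <- sprintf("d%04d", seq_len(config$n_disease))
    m_mod <- (seq_len(config$n_mirna) - 1L) %% config$n_modules
    d_mod <- (seq_len(config$n_disease) - 1L) %% config$n_modules
    MM <- planted_similarity(m_labels, m_mod, config$sim_in, config$sim_out,
                             config$sim_noise)
    DD <- planted_similarity(d_labels, d_mod, config$sim_in, config$sim_out,
                             config$sim_noise)
    truth <- 1 * outer(m_mod, d_mod, `==`)
    dimnames(truth) <- list(m_labels, d_labels)
    p <- ifelse(truth == 1, config$p_in, config$p_out)
    observed <- matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p))
    idx <- which(observed == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      stop("simulation produced no observed associations; raise p_in/p_out")
    associations <- association_set(m_labels[idx[, 1L]], d_labels[idx[, 2L]])
    list(MM = MM, DD = DD, associations = associations, truth = truth,
         mirna_modules = stats::setNames(m_mod, m_labels),
         disease_modules = stats::setNames(d_mod, d_labels),
         config = config)
  })
}

#' Discoverable positives and negatives per disease
#'
#' Given the planted truth and the observed associations, splits each
#' disease's unobserved miRNAs into positives (matched-module, hence
#' discoverable) and negatives (unmatched-module). With `p_out = 0` the
#' two sets are disjoint and together cover every unobserved candidate.
#'
#' @param truth ground-truth 0/1 matrix from [simulate_rdnet()].
#' @param observed the observed [association_set()].
#' @return Named list (one element per disease) of lists with `positives`
#'   and `negatives` character vectors.
#' @export
holdout_truth <- function(truth, observed) {
  stopifnot(inherits(observed, "association_set"))
  m_labels <- rownames(truth)
  out <- lapply(colnames(truth), function(d) {
    seen <- observed$pairs$mirna[observed$pairs$disease == d]
    unseen <- setdiff(m_labels, seen)
    list(positives = unseen[truth[unseen, d] == 1],
         negatives = unseen[truth[unseen, d] == 0])
  })
  stats::setNames(out, colnames(truth))
}

#' Write the simulated inputs as the standard file bundle
#'
#' Writes `mirna_similarity.tsv`, `disease_similarity.tsv`,
#' `associations.tsv` (the three pipeline inputs) and `truth.tsv`
#' (matched-module pairs) into `dir`.
#'
#' @param sim a [simulate_rdnet()] result.
#' @param dir output directory (created if absent).
#' @return Named character vector of the four file paths.
#' @export
write_rdnet_inputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mirna_sim = file.path(dir, "mirna_similarity.tsv"),
             disease_sim = file.path(dir, "disease_similarity.tsv"),
             associations = file.path(dir, "associations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_similarity_matrix(sim$MM, paths[["mirna_sim"]])
  write_similarity_matrix(sim$DD, paths[["disease_sim"]])
  write_association_table(sim$associations, paths[["associations"]])
  idx <- which(sim$truth == 1, arr.ind = TRUE)
  writeLines(c("mirna\tdisease",
               sprintf("%s\t%s", rownames(sim$truth)[idx[, 1L]],
                       colnames(sim$truth)[idx[, 2L]])),
             paths[["truth"]])
  paths
}
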