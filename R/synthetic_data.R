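# Synthetic drug-disease-gene networks with planted group structure. Each
# entity belongs to one of a few latent therapeutic groups; the gene graph
# is a stochastic block model, drug/disease gene profiles sample
# preferentially from the own group's genes, fingerprints share group bits,
# the phenotype matrix is drawn around group-dependent means, and treatment
# positives appear only between group-matched drugs and diseases, sampled
# with probability increasing in the pair's gene-profile overlap (treatments
# follow target-gene mechanisms). This makes all three layers informative
# but noisy, complementary views of the latent structure -- the base layer a
# deliberately weak group detector, the treatment layer the strongest, gene
# overlap carrying within-group signal -- and makes the guilt-by-association
# assumption true by construction, so every pipeline stage and the
# end-to-end ranking claim are testable without any external data.

#' Synthetic network configuration
#'
#' Defaults define the package's reference benchmark: 60 drugs, 40 diseases
#' and 200 genes in 4 latent groups; gene-graph edge probabilities 0.06
#' within / 0.005 between groups; gene-association probabilities 0.12
#' within / 0.01 between; on average 30% of group-matched drug-disease
#' pairs labeled as treatments, preferring pairs with high gene-profile
#' overlap; 64 fingerprint bits with own-group bits set at rate 0.25
#' (other-group bits at a quarter of that, so the structural layer is a
#' noisy group detector); phenotype similarity means 0.35 within / 0.15
#' between with Gaussian noise sd 0.15.
#'
#' @param m,n,l drug, disease and gene counts.
#' @param n_groups latent group count.
#' @param p_gene_within,p_gene_between gene-graph edge probabilities.
#' @param assoc_within,assoc_between drug-gene / disease-gene association
#'   probabilities conditioned on group match.
#' @param treat_rate mean fraction of group-matched pairs labeled positive;
#'   within the matched set a pair's probability scales with its
#'   gene-profile overlap.
#' @param fp_bits fingerprint length in bits.
#' @param fp_within_overlap probability a drug carries each of its group's
#'   bits (other groups' bits at `fp_within_overlap / 4`).
#' @param pheno_within,pheno_between phenotype similarity means.
#' @param noise_sd phenotype perturbation scale.
#' @param seed integer seed; all randomness flows from it.
#' @return validated config list of class `ssgc_synth_config`.
#' @export
synthetic_config <- function(m = 60, n = 40, l = 200, n_groups = 4,
                             p_gene_within = 0.06, p_gene_between = 0.005,
                             assoc_within = 0.12, assoc_between = 0.01,
                             treat_rate = 0.3,
                             fp_bits = 64, fp_within_overlap = 0.25,
                             pheno_within = 0.35, pheno_between = 0.15,
                             noise_sd = 0.15, seed = 1) {
  cfg <- list(m = m, n = n, l = l, n_groups = n_groups,
              p_gene_within = p_gene_within, p_gene_between = p_gene_between,
              assoc_within = assoc_within, assoc_between = assoc_between,
              treat_rate = treat_rate, fp_bits = fp_bits,
              fp_within_overlap = fp_within_overlap,
              pheno_within = pheno_within, pheno_between = pheno_between,
              noise_sd = noise_sd, seed = seed)
  probs <- c(p_gene_within, p_gene_between, assoc_within, assoc_between,
             treat_rate, fp_within_overlap, pheno_within, pheno_between)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_gene_within <= p_gene_between || assoc_within <= assoc_between ||
      pheno_within <= pheno_between)
    stop("within-group parameters must exceed between-group parameters")
  if (min(m, n, l) < n_groups) stop("entity counts must be >= n_groups")
  if (fp_bits < n_groups) stop("need at least one fingerprint bit per group")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "ssgc_synth_config")
}

#' Generate a synthetic drug-disease-gene network
#'
#' Fully reproducible from `config$seed`; the global RNG state is restored
#' afterwards.
#'
#' @param config a [synthetic_config()].
#' @return dataset list: registries (`drugs`, `diseases`, `genes`), group
#'   labels (`drug_group`, `disease_group`, `gene_group`), `fingerprints`,
#'   `S_pheno`, `gene_adj`, `C` (drug-gene), `D` (disease-gene), `Y`
#'   (drug-disease treatments) and the `config`.
#' @export
generate_network <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "ssgc_synth_config"))
  local_seed(config$seed, with(config, {
    drugs <- sprintf("DR%04d", seq_len(m))
    diseases <- sprintf("DI%04d", seq_len(n))
    genes <- sprintf("G%05d", seq_len(l))
    drug_group <- sample(rep(seq_len(n_groups), length.out = m))
    disease_group <- sample(rep(seq_len(n_groups), length.out = n))
    gene_group <- sample(rep(seq_len(n_groups), length.out = l))

    # gene graph: stochastic block model, undirected, no self-loops
    same_gene <- outer(gene_group, gene_group, "==")
    pmat <- ifelse(same_gene, p_gene_within, p_gene_between)
    up <- upper.tri(pmat)
    gene_adj <- matrix(0, l, l, dimnames = list(genes, genes))
    gene_adj[up] <- as.numeric(stats::runif(sum(up)) < pmat[up])
    gene_adj <- gene_adj + t(gene_adj)

    # bipartite gene profiles: preferential sampling from the own group
    draw_profiles <- function(groups, ids) {
      pm <- ifelse(outer(groups, gene_group, "=="), assoc_within, assoc_between)
      A <- matrix(as.numeric(stats::runif(length(pm)) < pm), nrow(pm),
                  dimnames = list(ids, genes))
      A
    }
    C <- draw_profiles(drug_group, drugs)
    D <- draw_profiles(disease_group, diseases)

    # fingerprints: each group owns an equal share of the bit positions
    bit_group <- rep(seq_len(n_groups), length.out = fp_bits)
    fps <- lapply(seq_len(m), function(i) {
      p <- ifelse(bit_group == drug_group[i], fp_within_overlap,
                  fp_within_overlap / 4)
      which(stats::runif(fp_bits) < p) - 1L
    })
    names(fps) <- drugs

    # phenotype similarity: group-mean matrix plus symmetric noise
    S_pheno <- ifelse(outer(disease_group, disease_group, "=="),
                      pheno_within, pheno_between)
    noise <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    S_pheno <- S_pheno + (noise + t(noise)) / 2
    S_pheno[S_pheno < 0] <- 0
    S_pheno[S_pheno > 1] <- 1
    diag(S_pheno) <- 1
    dimnames(S_pheno) <- list(diseases, diseases)

    # treatments: positives only among group-matched pairs, preferring
    # pairs whose gene profiles overlap (treatments follow target genes);
    # the mean positive rate over matched pairs stays at treat_rate
    matched <- outer(drug_group, disease_group, "==")
    if (treat_rate > 0 && !any(matched))
      stop("infeasible config: no group-matched drug-disease pairs")
    cn <- sqrt(rowSums(C)); dn <- sqrt(rowSums(D))
    overlap <- (C %*% t(D)) / pmax(outer(cn, dn), 1)
    w <- 0.1 + overlap[matched]
    prob <- pmin(treat_rate * w / mean(w), 1)
    Y <- matrix(0, m, n, dimnames = list(drugs, diseases))
    Y[matched] <- as.numeric(stats::runif(sum(matched)) < prob)

    list(drugs = drugs, diseases = diseases, genes = genes,
         drug_group = drug_group, disease_group = disease_group,
         gene_group = gene_group, fingerprints = fps, S_pheno = S_pheno,
         gene_adj = gene_adj, C = C, D = D, Y = Y, config = config)
  }))
}

#' Hold out a fraction of the known positives
#'
#' Uniformly removes `ceiling(fraction * n_positives)` positive labels,
#' reproducibly from `seed`.
#'
#' @param Y binary treatment matrix.
#' @param fraction fraction of positives to hold out, in (0, 1).
#' @param seed integer seed.
#' @return list with `Y_train` and `held_out` (two-column index matrix).
#' @export
hold_out <- function(Y, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  check_binary_matrix(Y, "treatment matrix")
  pos <- which(Y == 1, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("no positives to hold out")
  nh <- ceiling(fraction * nrow(pos))
  take <- local_seed(seed, sample.int(nrow(pos), nh))
  held <- pos[take, , drop = FALSE]
  Y_train <- Y
  Y_train[held] <- 0
  list(Y_train = Y_train, held_out = held)
}

#' Write a dataset to a directory in the package's text formats
#'
#' Files: `drugs.txt`, `diseases.txt`, `genes.txt` (registries),
#' `fingerprints.tsv`, `phenotype.tsv`, `gene_edges.tsv`, `drug_gene.tsv`,
#' `disease_gene.tsv`, `treatment.tsv`.
#'
#' @param dataset dataset list.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(dataset$drugs, file.path(dir, "drugs.txt"))
  writeLines(dataset$diseases, file.path(dir, "diseases.txt"))
  writeLines(dataset$genes, file.path(dir, "genes.txt"))
  write_fingerprints(dataset$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_similarity_matrix(dataset$S_pheno, file.path(dir, "phenotype.tsv"))
  write_edge_list(dataset$gene_adj, file.path(dir, "gene_edges.tsv"))
  write_edge_list(dataset$C, file.path(dir, "drug_gene.tsv"))
  write_edge_list(dataset$D, file.path(dir, "disease_gene.tsv"))
  write_edge_list(dataset$Y, file.path(dir, "treatment.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory path.
#' @return dataset list (without group labels, which are generator-only).
#' @export
read_dataset <- function(dir) {
  drugs <- readLines(file.path(dir, "drugs.txt"))
  diseases <- readLines(file.path(dir, "diseases.txt"))
  genes <- readLines(file.path(dir, "genes.txt"))
  gene_adj <- read_edge_list(file.path(dir, "gene_edges.tsv"), genes, genes)
  gene_adj <- pmax(gene_adj, t(gene_adj))  # gene interactions are undirected
  list(drugs = drugs, diseases = diseases, genes = genes,
       fingerprints = read_fingerprints(file.path(dir, "fingerprints.tsv")),
       S_pheno = read_similarity_matrix(file.path(dir, "phenotype.tsv")),
       gene_adj = gene_adj,
       C = read_edge_list(file.path(dir, "drug_gene.tsv"), drugs, genes),
       D = read_edge_list(file.path(dir, "disease_gene.tsv"), diseases, genes),
       Y = read_edge_list(file.path(dir, "treatment.tsv"), drugs, diseases))
}
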