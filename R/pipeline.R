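# Assembly of the three similarity layers into the fused matrices S_c and
# S_d, and the end-to-end scoring pipeline used by the CLI commands and the
# cross-validation driver. The base and gene layers do not depend on the
# treatment labels, so they can be precomputed once and reused across folds;
# the treatment layer, the fusion weights and the prior are label-dependent
# and are rebuilt from the training labels.

#' Pipeline options with the method defaults
#'
#' Kernel parameters: gene layer `a = 0.3, b = 1.0`; treatment layer
#' `a = 0.9, b = 1.0`. Similarity thresholds (small scores are mostly noise
#' and are cut off): drug structure 0.1, drug gene-profile 0.01, disease
#' phenotype 0.14, disease gene-profile 0.01, treatment layer 0 (it already
#' has the cleanest guilt-by-association signal). Solver: `mu = 4`,
#' `xi = 0.67`, tolerance 1e-6, at most 1000 iterations.
#'
#' @param ... overrides for any option (unknown names are an error).
#' @return named list of options.
#' @export
pipeline_options <- function(...) {
  opts <- list(
    gene_a = 0.3, gene_b = 1.0,
    treat_a = 0.9, treat_b = 1.0,
    tau_base_drug = 0.1, tau_gene_drug = 0.01,
    tau_base_disease = 0.14, tau_gene_disease = 0.01,
    tau_treat_drug = 0, tau_treat_disease = 0,
    k_neighbors = 5,
    weights = "auto",
    mu = 4, xi = 0.67, tol = 1e-6, max_iter = 1000,
    degree_floor = 1e-12
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(opts))
  if (length(unknown)) stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(opts, over)
}

#' Precompute the label-independent similarity layers
#'
#' Base layer: Tanimoto drug similarity from fingerprints and the phenotype
#' disease similarity. Gene layer: exponential kernel on gene-graph shortest
#' paths, then kernel-cosine profile similarities. Returns both raw and
#' thresholded matrices (raw base matrices serve as the reference space for
#' projecting the treatment layer).
#'
#' @param dataset dataset list (fields `fingerprints`, `S_pheno`,
#'   `gene_adj`, `C`, `D`, `Y`).
#' @param opts options from [pipeline_options()].
#' @return list of layer matrices and the gene kernel `Sg`.
#' @export
precompute_static_layers <- function(dataset, opts = pipeline_options()) {
  S_bc_raw <- tanimoto_similarity(dataset$fingerprints)
  S_bd_raw <- validate_similarity_matrix(dataset$S_pheno)
  Dg <- shortest_path_distances(dataset$gene_adj, "unipartite")
  Sg <- perlman_kernel(Dg, opts$gene_a, opts$gene_b)
  S_gc_raw <- profile_kernel_similarity(dataset$C, Sg)
  S_gd_raw <- profile_kernel_similarity(dataset$D, Sg)
  list(
    Sg = Sg,
    S_bc_raw = S_bc_raw, S_bd_raw = S_bd_raw,
    S_gc_raw = S_gc_raw, S_gd_raw = S_gd_raw,
    S_bc = apply_threshold(S_bc_raw, opts$tau_base_drug),
    S_bd = apply_threshold(S_bd_raw, opts$tau_base_disease),
    S_gc = apply_threshold(S_gc_raw, opts$tau_gene_drug),
    S_gd = apply_threshold(S_gd_raw, opts$tau_gene_disease)
  )
}

#' @keywords internal
offdiag_mean <- function(S) {
  n <- nrow(S)
  (sum(S) - sum(diag(S))) / (n * (n - 1))
}

#' Fuse the selected layers into comprehensive similarities
#'
#' Computes the treatment layer from the training labels (when selected),
#' projects it to the full registries using the raw base-layer similarity as
#' reference, thresholds every selected layer, derives equal-contribution
#' weights from the layers' off-diagonal means (unless fixed weights are
#' supplied) and returns the convex combinations `S_c` and `S_d`.
#'
#' @param static output of [precompute_static_layers()].
#' @param Y_train binary training label matrix (needed when `"treatment"`
#'   is selected).
#' @param layers subset of `c("base", "gene", "treatment")`.
#' @param opts options from [pipeline_options()].
#' @return list with `Sc`, `Sd`, per-layer matrices and the weights used.
#' @export
assemble_similarities <- function(static, Y_train = NULL,
                                  layers = c("base", "gene", "treatment"),
                                  opts = pipeline_options()) {
  layers <- match.arg(layers, c("base", "gene", "treatment"), several.ok = TRUE)
  drug_layers <- list(base = static$S_bc)
  disease_layers <- list(base = static$S_bd)
  if ("gene" %in% layers) {
    drug_layers$gene <- static$S_gc
    disease_layers$gene <- static$S_gd
  }
  S_tc <- S_td <- NULL
  if ("treatment" %in% layers) {
    if (is.null(Y_train)) stop("treatment layer needs the training label matrix")
    ts <- treatment_similarity(Y_train, opts$treat_a, opts$treat_b)
    S_tc <- apply_threshold(
      project_to_full(ts$drug, static$S_bc_raw, opts$k_neighbors),
      opts$tau_treat_drug)
    S_td <- apply_threshold(
      project_to_full(ts$disease, static$S_bd_raw, opts$k_neighbors),
      opts$tau_treat_disease)
    drug_layers$treatment <- S_tc
    disease_layers$treatment <- S_td
  }
  mix <- function(mats) {
    if (length(mats) == 1)
      return(list(S = mats[[1]], w = stats::setNames(1, names(mats))))
    if (identical(opts$weights, "auto")) {
      w <- weights_from_means(vapply(mats, offdiag_mean, 1))
    } else {
      w <- opts$weights[seq_along(mats)]
      w <- w / sum(w)
    }
    S <- Reduce(`+`, Map(`*`, w, mats))
    list(S = validate_similarity_matrix(S), w = w)
  }
  dm <- mix(drug_layers); sm <- mix(disease_layers)
  list(Sc = dm$S, Sd = sm$S, drug_weights = dm$w, disease_weights = sm$w,
       drug_layers = drug_layers, disease_layers = disease_layers)
}

#' Run the full scoring pipeline on one training label matrix
#'
#' Assembles the fused similarities, builds the gene-overlap prior from the
#' training labels (when `prior = TRUE`), and propagates.
#'
#' @param dataset dataset list.
#' @param Y_train binary training labels (defaults to `dataset$Y`).
#' @param static optional precomputed [precompute_static_layers()] result.
#' @param layers layers to fuse.
#' @param prior logical; use the gene-overlap prior.
#' @param opts options from [pipeline_options()].
#' @param mode `"ssgc"` (default) or `"hgbi"` (self-loop reduction).
#' @return list with `result` (an `ssgc_result`), `similarities`
#'   (from [assemble_similarities()]) and `P`.
#' @export
ssgc_pipeline <- function(dataset, Y_train = dataset$Y, static = NULL,
                          layers = c("base", "gene", "treatment"),
                          prior = TRUE, opts = pipeline_options(),
                          mode = c("ssgc", "hgbi")) {
  mode <- match.arg(mode)
  if (is.null(static)) static <- precompute_static_layers(dataset, opts)
  sims <- assemble_similarities(static, Y_train, layers = layers, opts = opts)
  P <- if (prior) compute_prior(dataset$C, dataset$D, static$Sg, Y_train)
       else matrix(0, nrow(Y_train), ncol(Y_train), dimnames = dimnames(Y_train))
  result <- if (mode == "ssgc")
    ssgc_solve(sims$Sc, sims$Sd, Y_train, P, mu = opts$mu, xi = opts$xi,
               tol = opts$tol, max_iter = opts$max_iter,
               degree_floor = opts$degree_floor)
  else
    hgbi_mode_solve(sims$Sc, sims$Sd, Y_train, mu = opts$mu, tol = opts$tol,
                    max_iter = opts$max_iter, degree_floor = opts$degree_floor)
  list(result = result, similarities = sims, P = P)
}
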