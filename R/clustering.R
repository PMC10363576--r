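# Acoustic and neural hierarchical clustering, dendrogram-cut search and
# adjusted Rand index comparisons against call-type / acoustic labels.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pairwise agreement (Hubert-Arabie): with `a` pairs
#' grouped together in both partitions and `b` pairs separated in both,
#' `RI = (a + b) / choose(n, 2)` and
#' `ARI = (RI - E[RI]) / (max RI - E[RI])`, computed via the contingency
#' table.  ARI is 1 for identical groupings and near 0 for independent
#' random labelings.  When both partitions are trivial (the adjusted
#' index is undefined), 0 is returned with attribute `"degenerate"`.
#'
#' @param p1,p2 Label vectors over the same items (any label type).
#' @return ARI value.
#' @export
adjusted_rand <- function(p1, p2) {
  if (length(p1) != length(p2))
    voc_stop("partitions cover different item sets", "vocnet_input_error")
  tab <- table(p1, p2)
  n <- length(p1)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sum_i * sum_j / tot
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (sum_ij - expected) / (maxidx - expected)
}

# internal: standardize columns, mean-impute NAs first
.standardize_features <- function(X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    if (anyNA(col)) col[is.na(col)] <- mean(col, na.rm = TRUE)
    s <- sd(col)
    X[, j] <- if (is.finite(s) && s > 0) (col - mean(col)) / s else 0
  }
  X
}

#' Hierarchical clustering of vocalizations by bioacoustic features
#'
#' Mean-imputes missing values (unvoiced F0 statistics), standardizes
#' each feature column, optionally applies a user-supplied nonlinear
#' embedding, and runs hierarchical agglomerative clustering.  A 2D PCA
#' projection is attached for visualization.
#'
#' @param features Numeric feature matrix/data.frame (rows = stimuli;
#'   e.g. the 20 columns of [bioacoustic_feature_table()]), or that
#'   table itself (id/label columns are dropped automatically).
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"ward.D2"`).
#' @param embed_fun Optional embedding function `X -> matrix` applied to
#'   the standardized features before clustering (contract for UMAP-like
#'   algorithms); `NULL` clusters the standardized features directly,
#'   which is the fully deterministic path.
#' @param seed Seed set around `embed_fun` for stochastic embeddings.
#' @return Object of class `voc_dendrogram`: `hclust`, `coords2d`,
#'   `items`, `linkage`.
#' @export
cluster_acoustic <- function(features, linkage = "ward.D2",
                             embed_fun = NULL, seed = 1) {
  df <- as.data.frame(features)
  items <- if ("stimulus_id" %in% names(df)) df$stimulus_id
           else rownames(df) %||% as.character(seq_len(nrow(df)))
  num <- df[vapply(df, is.numeric, TRUE)]
  X <- .standardize_features(num)
  if (anyNA(X))
    voc_stop("missing values remain after imputation", "vocnet_input_error")
  if (!is.null(embed_fun)) X <- with_seed(seed, embed_fun(X))
  hc <- hclust(dist(X), method = linkage)
  coords <- prcomp(X, rank. = 2)$x
  structure(list(hclust = hc, coords2d = coords, items = items,
                 linkage = linkage),
            class = "voc_dendrogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flat partition from a dendrogram cut
#'
#' @param dendro A `voc_dendrogram` (or `hclust`).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer label vector (named by item where available).
#' @export
cut_partition <- function(dendro, k) {
  hc <- if (inherits(dendro, "voc_dendrogram")) dendro$hclust else dendro
  n <- length(hc$order)
  if (k < 1 || k > n) voc_stop("invalid number of clusters", "vocnet_input_error")
  labels <- cutree(hc, k = k)
  if (inherits(dendro, "voc_dendrogram")) names(labels) <- dendro$items
  labels
}

#' Per-stimulus neural feature matrix for an ensemble
#'
#' Trial-averaged `[Z, T1..T5]` per unit, concatenated across the k
#' ensemble units: one row per stimulus, 6k columns.
#'
#' @param features Per-trial feature table from [trial_features()].
#' @param units Ensemble unit ids.
#' @return Numeric matrix (rownames = stimulus ids).
#' @export
neural_feature_matrix <- function(features, units) {
  ft <- data.table::as.data.table(features)
  ft <- ft[ft$unit_id %in% units, ]
  cols <- c("Z", grep("^T[0-9]+$", names(ft), value = TRUE))
  mean_ft <- ft[, lapply(.SD, mean), by = c("unit_id", "stimulus_id"),
                .SDcols = cols]
  wide <- data.table::dcast(mean_ft, stimulus_id ~ unit_id, value.var = cols)
  if (anyNA(wide))
    voc_stop("missing (unit, stimulus) features", "vocnet_input_error")
  wd <- as.data.frame(wide)
  X <- as.matrix(wd[, -1, drop = FALSE])
  rownames(X) <- wd$stimulus_id
  X
}

#' Best dendrogram cut against a reference partition
#'
#' Computes the ARI between every cut `k = 1..n` of the dendrogram and
#' the reference labels; returns the full table and the argmax (smallest
#' k on ties).
#'
#' @param dendro A `voc_dendrogram` or `hclust` over the reference items.
#' @param reference Reference label vector in item order.
#' @return List with `best_k`, `best_ari`, `ari_by_k` (data.frame).
#' @export
optimal_cut_ari <- function(dendro, reference) {
  hc <- if (inherits(dendro, "voc_dendrogram")) dendro$hclust else dendro
  n <- length(hc$order)
  if (length(reference) != n)
    voc_stop("reference length does not match the dendrogram", "vocnet_input_error")
  aris <- vapply(seq_len(n), function(k)
    as.numeric(adjusted_rand(cutree(hc, k = k), reference)), 0)
  best <- which.max(aris)     # which.max takes the first (smallest k) on ties
  list(best_k = best, best_ari = aris[best],
       ari_by_k = data.frame(k = seq_len(n), ari = aris))
}

#' Compare neural clustering against call-type and acoustic labels
#'
#' For each ensemble: build the stimulus x 6k neural feature matrix,
#' cluster it hierarchically, find the best cut against the call-type
#' labels (`ARI_call`) and against the acoustic cluster labels
#' (`ARI_acoustic`), and test the paired difference with the
#' ensemble-corrected t-test (df = `neff - 1`).
#'
#' @param ensembles List of unit-id vectors.
#' @param features Per-trial feature table.
#' @param call_labels Call-type label per stimulus (named by stimulus id
#'   or in the row order of the neural matrix).
#' @param acoustic_labels Acoustic cluster label per stimulus (same
#'   convention).
#' @param ns,ne Pool and ensemble sizes for the corrected test.
#' @param linkage Linkage method.
#' @return List with `table` (per-ensemble ARI_call, ARI_acoustic,
#'   best_k_call, best_k_acoustic) and `test` (`voc_corrected_stat` for
#'   the paired difference).
#' @export
compare_ari_call_vs_acoustic <- function(ensembles, features, call_labels,
                                         acoustic_labels, ns, ne,
                                         linkage = "ward.D2") {
  rows <- lapply(seq_along(ensembles), function(i) {
    X <- neural_feature_matrix(features, ensembles[[i]])
    ids <- rownames(X)
    cl <- if (!is.null(names(call_labels))) call_labels[ids] else call_labels
    al <- if (!is.null(names(acoustic_labels))) acoustic_labels[ids]
          else acoustic_labels
    hc <- hclust(dist(.standardize_features(X)), method = linkage)
    rc <- optimal_cut_ari(hc, cl)
    ra <- optimal_cut_ari(hc, al)
    data.frame(ensemble = i, ari_call = rc$best_ari,
               ari_acoustic = ra$best_ari,
               best_k_call = rc$best_k, best_k_acoustic = ra$best_k)
  })
  tab <- do.call(rbind, rows)
  test <- corrected_t_test(tab$ari_call, tab$ari_acoustic, ns = ns, ne = ne,
                           paired = TRUE)
  list(table = tab, test = test)
}
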