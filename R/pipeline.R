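# End-to-end orchestration: modality-specific integration, graph building,
# HGT graph-autoencoder training, clustering, Steiner-forest gene networks
# and (for paired RNA+ATAC) regulon/GRN inference, with deterministic
# per-stage seeds fanned out from one master seed.

#' Pipeline configuration
#'
#' @param data_type \code{"multi_rna"}, \code{"cite"} or \code{"rna_atac"};
#'   selects the integration path (CCA, CLR or velocity-weighted activity).
#' @param qc_min_nonzero_fraction QC threshold (default 0.001).
#' @param hvg_n highly variable genes kept (default 2000).
#' @param ae_hidden,ae_epochs autoencoder width / epochs for the initial
#'   embeddings.
#' @param hgt an [hgt_config()]; its \code{d} is also the initial embedding
#'   dimension.
#' @param knn_k,resolution clustering parameters (defaults 20, 0.4).
#' @param cluster_method \code{"louvain"} (default) or \code{"leiden"}.
#' @param gas_clip_negative,beta_normalize activity-score options.
#' @param ras_denominator \code{"subset"} or \code{"global"}.
#' @param seed master seed; stage seeds derive from it.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(data_type = c("multi_rna", "cite", "rna_atac"),
                            qc_min_nonzero_fraction = 0.001, hvg_n = 2000,
                            ae_hidden = 512, ae_epochs = 100,
                            hgt = NULL, knn_k = 20, resolution = 0.4,
                            cluster_method = "louvain",
                            gas_clip_negative = TRUE, beta_normalize = TRUE,
                            ras_denominator = "subset", seed = 1) {
  data_type <- match.arg(data_type)
  if (is.null(hgt)) hgt <- hgt_config(seed = seed + 2)
  structure(list(data_type = data_type,
                 qc_min_nonzero_fraction = qc_min_nonzero_fraction,
                 hvg_n = hvg_n, ae_hidden = ae_hidden,
                 ae_epochs = ae_epochs, hgt = hgt, knn_k = knn_k,
                 resolution = resolution, cluster_method = cluster_method,
                 gas_clip_negative = gas_clip_negative,
                 beta_normalize = beta_normalize,
                 ras_denominator = ras_denominator, seed = seed),
            class = "pipeline_config")
}

# integration stage: inputs -> integrated matrix (+ preprocessing products)
integrate_inputs <- function(inputs, cfg) {
  switch(cfg$data_type,
    multi_rna = {
      mats <- lapply(inputs$rna_list, function(m)
        select_hvg(log_normalize(
          qc_filter(m, cfg$qc_min_nonzero_fraction)), cfg$hvg_n))
      list(X = cca_align(mats))
    },
    cite = {
      rna <- select_hvg(log_normalize(
        qc_filter(inputs$rna, cfg$qc_min_nonzero_fraction)), cfg$hvg_n)
      prot <- log_normalize(qc_filter(inputs$protein,
                                      cfg$qc_min_nonzero_fraction))
      cells <- intersect(colnames(rna$values), colnames(prot$values))
      comb <- named_matrix(rbind(rna$values[, cells, drop = FALSE],
                                 prot$values[, cells, drop = FALSE]),
                           modality = "rna")
      clr <- clr_transform(comb)
      list(X = integrated_matrix(
        clr$values, source = "cite",
        feature_kind = c(rep("gene", nrow(rna$values)),
                         rep("protein", nrow(prot$values)))))
    },
    rna_atac = {
      rna <- log_normalize(qc_filter(inputs$rna,
                                     cfg$qc_min_nonzero_fraction))
      atac <- qc_filter(inputs$atac, cfg$qc_min_nonzero_fraction)
      cells <- intersect(colnames(rna$values), colnames(atac$values))
      rna <- nm_subset(rna, cols = cells)
      atac <- nm_subset(atac, cols = cells)
      w <- peak_gene_weights(inputs$peaks, inputs$genes)
      regpot <- regulatory_potential(atac, w,
                                     genes = rownames(rna$values))
      vel <- if (!is.null(inputs$velocity)) {
        nm_subset(inputs$velocity, cols = cells)
      } else {
        steady_state_velocity(nm_subset(inputs$spliced, cols = cells),
                              nm_subset(inputs$unspliced, cols = cells))
      }
      vel <- nm_subset(vel, rows = intersect(rownames(vel$values),
                                             rownames(rna$values)))
      # joint gene removal: all-zero regulatory potential or velocity rows
      keep <- intersect(rownames(rna$values), rownames(vel$values))
      zero_rp <- attr(regpot, "zero_genes")
      zero_v <- rownames(vel$values)[rowSums(vel$values != 0) == 0]
      keep <- setdiff(keep, union(zero_rp, zero_v))
      if (!length(keep)) stop("integrate_inputs: no gene survives joint removal")
      rna <- nm_subset(rna, rows = keep)
      regpot <- nm_subset(regpot, rows = keep)
      vel <- nm_subset(vel, rows = keep)
      ltmg <- ltmg_discretize(rna)
      vw <- velocity_weights(vel, ltmg, normalize = cfg$beta_normalize)
      X <- gas_matrix(rna, regpot, vw,
                      clip_negative = cfg$gas_clip_negative)
      list(X = X, w = w, atac = atac, ltmg = ltmg, vw = vw,
           velocity = vel)
    })
}

#' Run the full pipeline
#'
#' Integration, heterogeneous-graph construction, autoencoder
#' initialization, HGT graph-autoencoder training, cell clustering,
#' per-cluster Steiner-forest gene association networks, and (for paired
#' RNA+ATAC input) regulon assembly with CTSR testing and master-TF
#' ranking.
#'
#' @param inputs named list of inputs. \code{multi_rna}: \code{rna_list}
#'   (list of \code{named_matrix}). \code{cite}: \code{rna},
#'   \code{protein}. \code{rna_atac}: \code{rna}, \code{atac},
#'   \code{peaks}, \code{genes}, plus \code{velocity} or
#'   \code{spliced}/\code{unspliced}, optional \code{motifs}.
#' @param cfg a [pipeline_config()].
#' @param output_dir optional directory; when given, labels, embeddings,
#'   attention, networks, regulons and a JSON run manifest are written.
#' @return a \code{schgt_run}: integrated matrix, fitted \code{hgt_gae}
#'   model, \code{labels}, per-cluster \code{networks}, \code{regulons} +
#'   \code{ctsr} + \code{master_tfs} (rna_atac only), \code{metrics}.
#' @export
run_pipeline <- function(inputs, cfg = pipeline_config(), output_dir = NULL) {
  t0 <- Sys.time()
  stage <- "integrate"
  res <- list(cfg = cfg)
  ok <- tryCatch({
    intg <- integrate_inputs(inputs, cfg)
    res$X <- intg$X
    stage <- "graph"
    graph <- build_graph(intg$X)
    res$graph <- graph
    stage <- "init_embeddings"
    emb0 <- init_embeddings(intg$X, d_hidden = cfg$ae_hidden,
                            d_out = cfg$hgt$d, epochs = cfg$ae_epochs,
                            seed = cfg$seed + 1)
    stage <- "hgt_train"
    fit <- hgt_train(graph, emb0, intg$X, cfg$hgt)
    res$fit <- fit
    stage <- "cluster"
    cg <- knn_graph(fit$embedding$cell, k = cfg$knn_k)
    labels <- louvain_cluster(cg, resolution = cfg$resolution,
                              seed = cfg$seed + 3,
                              method = cfg$cluster_method)
    res$labels <- labels
    stage <- "networks"
    res$networks <- list()
    for (z in seq_len(labels$Z)) {
      ag <- tryCatch(
        build_augmented_graph(fit$embedding$gene, fit$attention, labels, z),
        error = function(e) NULL)
      if (is.null(ag)) next
      sol <- solve_sfp(ag)
      res$networks[[z]] <- extract_network(sol, ag, fit$attention, labels, z)
    }
    if (cfg$data_type == "rna_atac" && !is.null(inputs$motifs)) {
      stage <- "grn"
      aff <- binding_affinity(inputs$motifs, inputs$peaks)
      regs <- assemble_regulons(res$networks[!vapply(res$networks, is.null,
                                                     logical(1))],
                                aff, intg$w, intg$atac, labels)
      res$regulons <- regs
      res$ctsr <- ctsr_test(regs, aff, intg$w, intg$atac, intg$X, labels)
      res$master_tfs <- lapply(seq_len(labels$Z), function(z)
        master_tfs(Filter(function(r) r$cluster == z, regs)))
    }
    stage <- "metrics"
    res$metrics <- evaluate_metrics(fit$embedding$cell, labels$assignment)
    TRUE
  }, error = function(e) {
    res$error <<- conditionMessage(e)
    FALSE
  })
  res$manifest <- list(
    data_type = cfg$data_type, seed = cfg$seed,
    hgt = unclass(cfg$hgt), resolution = cfg$resolution,
    package_version = as.character(utils::packageVersion("scHGTnet")),
    completed = ok, failed_stage = if (!ok) stage,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(res) <- "schgt_run"
  if (!is.null(output_dir)) write_run(res, output_dir)
  if (!ok) warning("run_pipeline: failed at stage '", stage, "': ",
                   res$error)
  res
}

#' @export
print.schgt_run <- function(x, ...) {
  cat("<schgt_run>", if (isTRUE(x$manifest$completed)) "completed"
      else paste("FAILED at", x$manifest$failed_stage), "\n")
  if (!is.null(x$labels)) print(x$labels)
  invisible(x)
}

# write pipeline artifacts + manifest
write_run <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$labels))
    write_labels(res$labels, file.path(dir, "labels.tsv"))
  if (!is.null(res$fit)) {
    write_embeddings(res$fit$embedding, file.path(dir, "embeddings.tsv"))
    Matrix::writeMM(res$fit$attention, file.path(dir, "attention.mtx"))
    utils::write.table(
      data.frame(iteration = seq_along(res$fit$loss_trace),
                 loss = res$fit$loss_trace),
      file.path(dir, "loss_trace.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  for (z in seq_along(res$networks)) {
    net <- res$networks[[z]]
    if (is.null(net) || nrow(net$edges) == 0) next
    write_edge_list(stats::setNames(net$edges, c("from", "to", "weight")),
                    file.path(dir, sprintf("network_cluster%d.tsv", z)))
  }
  if (!is.null(res$regulons))
    write_regulons(res$regulons, file.path(dir, "regulons.tsv"))
  if (!is.null(res$ctsr))
    utils::write.table(res$ctsr, file.path(dir, "ctsr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$metrics))
    jsonlite::write_json(res$metrics, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Enumerate a hyperparameter grid
#'
#' Cartesian product of embedding/head pairs, learning rates and epoch
#' settings, in deterministic order (pairs vary slowest).
#'
#' @param embed_head_pairs list of c(d, H) pairs (default the four tested
#'   pairs 91/13, 104/13, 112/16, 128/16).
#' @param learning_rates numeric vector (default 1e-4, 1e-3, 1e-2).
#' @param epoch_settings integer vector (default 50, 75, 100).
#' @return list of [hgt_config()] objects; length = product of the input
#'   lengths.
#' @export
enumerate_grid <- function(embed_head_pairs = list(c(91, 13), c(104, 13),
                                                   c(112, 16), c(128, 16)),
                           learning_rates = c(1e-4, 1e-3, 1e-2),
                           epoch_settings = c(50, 75, 100)) {
  stopifnot(length(embed_head_pairs) > 0, length(learning_rates) > 0,
            length(epoch_settings) > 0)
  out <- list()
  for (pair in embed_head_pairs)
    for (lr in learning_rates)
      for (ep in epoch_settings)
        out[[length(out) + 1]] <- hgt_config(d = pair[1], n_heads = pair[2],
                                             lr = lr,
                                             epochs_per_subgraph = ep)
  out
}
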