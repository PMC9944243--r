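#' Build the bipartite cell-gene heterogeneous graph
#'
#' One unweighted edge per non-zero entry of the integrated matrix: edge
#' (gene i, cell j) exists iff x_ij > 0. Two node types (gene, cell), one
#' edge type, hence two directed meta-relations (gene->cell, cell->gene).
#'
#' @param X an \code{integrated_matrix} (QC-filtered, so no isolated nodes).
#' @return a \code{hetero_graph}: gene/cell node names, integer edge index
#'   matrix (gene_idx, cell_idx), edge values x_ij, and the meta-relation
#'   registry.
#' @export
build_graph <- function(X) {
  v <- X$values
  if (length(v) == 0 || all(v == 0)) stop("build_graph: empty matrix")
  idx <- which(v > 0, arr.ind = TRUE)
  structure(list(
    gene_nodes = rownames(v),
    cell_nodes = colnames(v),
    edges = cbind(gene = unname(idx[, 1]), cell = unname(idx[, 2])),
    edge_values = v[idx],
    meta_relations = list(
      gene_to_cell = c(source = "gene", edge = "gene_cell", target = "cell"),
      cell_to_gene = c(source = "cell", edge = "gene_cell", target = "gene"))),
    class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("<hetero_graph> %d genes, %d cells, %d edges\n",
              length(x$gene_nodes), length(x$cell_nodes), nrow(x$edges)))
  invisible(x)
}

#' Initial node embeddings from two autoencoders
#'
#' The cell autoencoder is trained on the columns of X (each cell described
#' by its gene profile), the gene autoencoder on the columns of t(X); the
#' bottleneck activations of both are returned as the layer-0 embedding
#' table. Training is seed-deterministic; the gene block depends only on
#' t(X) and the cell block only on X.
#'
#' @param X an \code{integrated_matrix}.
#' @param d_hidden hidden width (default 512).
#' @param d_out bottleneck/embedding width (default 256).
#' @param epochs autoencoder epochs (default 100).
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return an \code{embedding_table}: list with \code{gene} (genes x d_out),
#'   \code{cell} (cells x d_out), \code{layer} = 0 and the two loss traces.
#' @export
init_embeddings <- function(X, d_hidden = 512, d_out = 256, epochs = 100,
                            lr = 1e-3, seed = 1) {
  v <- X$values
  if (d_out >= min(dim(v)))
    warning("init_embeddings: bottleneck not smaller than data dimension")
  cell_ae <- train_autoencoder(t(v), d_hidden = d_hidden, d_out = d_out,
                               epochs = epochs, lr = lr, seed = seed)
  gene_ae <- train_autoencoder(v, d_hidden = d_hidden, d_out = d_out,
                               epochs = epochs, lr = lr, seed = seed + 1)
  structure(list(gene = gene_ae$embedding, cell = cell_ae$embedding,
                 layer = 0L,
                 loss_trace = list(cell = cell_ae$loss_trace,
                                   gene = gene_ae$loss_trace)),
            class = "embedding_table")
}

#' Export node embeddings as TSV (node id + embedding columns)
#'
#' @param emb an \code{embedding_table} (or a list with gene/cell matrices).
#' @param path output TSV path.
#' @export
write_embeddings <- function(emb, path) {
  tab <- rbind(emb$gene, emb$cell)
  df <- data.frame(node = c(rownames(emb$gene), rownames(emb$cell)),
                   type = c(rep("gene", nrow(emb$gene)),
                            rep("cell", nrow(emb$cell))),
                   tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
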