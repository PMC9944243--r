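make_toy_hgt <- function(n_genes = 4, n_cells = 3, d = 8, H = 2, L = 2,
                         seed = 3, density = 1) {
  set.seed(seed)
  X <- matrix(runif(n_genes * n_cells), n_genes, n_cells,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("c%d", seq_len(n_cells))))
  if (density < 1) X[runif(length(X)) > density] <- 0
  X[1, 1] <- max(X[1, 1], 0.5)  # keep the graph non-empty
  Xi <- integrated_matrix(X, source = "multi_rna")
  g <- build_graph(Xi)
  cfg <- hgt_config(n_layers = L, n_heads = H, d = d, seed = seed + 1)
  list(X = X, graph = g,
       cfg = cfg, params = hgt_init_params(cfg),
       Hg = matrix(rnorm(n_genes * d), n_genes, d),
       Hc = matrix(rnorm(n_cells * d), n_cells, d))
}

test_that("graph construction mirrors the support of the integrated matrix", {
  X <- matrix(c(1, 0, 0, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  g <- build_graph(integrated_matrix(X, source = "multi_rna"))
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]), c("1 1", "2 2"))
  # dense matrix -> complete bipartite edge set; random support conserved
  set.seed(4)
  Xd <- matrix(runif(30) + 0.1, 5, 6,
               dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  expect_equal(nrow(build_graph(integrated_matrix(Xd,
    source = "multi_rna"))$edges), 30)
  Xs <- Xd; Xs[runif(30) < 0.4] <- 0
  expect_equal(nrow(build_graph(integrated_matrix(Xs,
    source = "multi_rna"))$edges), sum(Xs > 0))
  expect_error(build_graph(integrated_matrix(Xs * 0, source = "multi_rna")),
               "empty")
  expect_equal(names(g$meta_relations), c("gene_to_cell", "cell_to_gene"))
})

test_that("typed projections split heads and differ between node types", {
  d <- 8; H <- 2
  W <- diag(d)
  h <- rnorm(d)
  ph <- project_qkv(h, W, H)
  expect_length(ph, H)
  expect_equal(drop(ph[[1]]), h[1:4])
  expect_equal(drop(ph[[2]]), h[5:8])
  expect_equal(drop(project_qkv(rep(0, d), W, H)[[1]]), rep(0, 4))
  # distinct type weights give distinct projections of equal embeddings
  Wg <- diag(d) * 2
  expect_false(isTRUE(all.equal(project_qkv(h, W, H), project_qkv(h, Wg, H))))
  expect_error(project_qkv(h, diag(9), 2), "divisible")
})

test_that("mutual attention is a per-head softmax over sources", {
  d <- 8; H <- 2
  Wa <- diag(d / H)
  Q <- project_qkv(rnorm(d), diag(d), H)
  # single source -> weight 1 in every head
  K1 <- project_qkv(matrix(rnorm(d), 1), diag(d), H)
  a1 <- mutual_attention(K1, Q, Wa, mu = 1, d = d)
  expect_equal(unname(a1), matrix(1, 1, H))
  # weights sum to 1 per head
  set.seed(5)
  K <- project_qkv(matrix(rnorm(5 * d), 5), diag(d), H)
  a <- mutual_attention(K, Q, Wa, mu = 1, d = d)
  expect_equal(unname(colSums(a)), rep(1, H))
  expect_true(all(a >= 0))
  # identical sources share the weight equally
  Keq <- project_qkv(matrix(rep(rnorm(d), 2), 2, byrow = TRUE), diag(d), H)
  aeq <- mutual_attention(Keq, Q, Wa, mu = 1, d = d)
  expect_equal(unname(aeq), matrix(0.5, 2, H))
})

test_that("messages are linear in the source values", {
  d <- 8; H <- 2
  V <- project_qkv(matrix(rnorm(3 * d), 3), diag(d), H)
  Wm <- diag(d / H)
  expect_equal(message_passing(V, Wm), do.call(cbind, V))
  V0 <- project_qkv(matrix(0, 3, d), diag(d), H)
  expect_true(all(message_passing(V0, Wm) == 0))
  # additivity
  set.seed(6)
  Wm2 <- matrix(rnorm(16), 4, 4)
  A <- matrix(rnorm(3 * d), 3); B <- matrix(rnorm(3 * d), 3)
  expect_equal(
    message_passing(project_qkv(A + B, diag(d), H), Wm2),
    message_passing(project_qkv(A, diag(d), H), Wm2) +
      message_passing(project_qkv(B, diag(d), H), Wm2))
})

test_that("aggregation applies the gate and residual under both conventions", {
  d <- 4; H <- 2
  att <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, H)
  msg <- matrix(rnorm(2 * d), 2, d)
  prev <- rnorm(d)
  arep <- att[, rep(1:2, each = 2)]
  htilde <- colSums(arep * msg)
  # theta = 1: both conventions give ReLU(aggregated)
  expect_equal(aggregate_target(att, msg, prev, 1, "standard"),
               pmax(htilde, 0))
  expect_equal(aggregate_target(att, msg, prev, 1, "paper"),
               pmax(htilde, 0))
  # theta = 0: standard -> identity, paper -> negated residual
  expect_equal(aggregate_target(att, msg, prev, 0, "standard"), prev)
  expect_equal(aggregate_target(att, msg, prev, 0, "paper"), -prev)
})

test_that("vectorized forward agrees with single-target operator composition", {
  toy <- make_toy_hgt(L = 1, seed = 11)
  cfg <- toy$cfg; p <- toy$params
  fwd <- hgt_forward(toy$graph$edges, toy$Hg, toy$Hc, p, cfg)
  # recompute cell 2's update by hand from the reference operators
  j <- 2
  nbr <- toy$graph$edges[toy$graph$edges[, 2] == j, 1]
  Q <- project_qkv(toy$Hc[j, ], p$WQ_cell, cfg$n_heads)
  K <- project_qkv(toy$Hg[nbr, , drop = FALSE], p$WK_gene, cfg$n_heads)
  V <- project_qkv(toy$Hg[nbr, , drop = FALSE], p$WV_gene, cfg$n_heads)
  att <- mutual_attention(K, Q, p$WATT_g2c, p$mu_g2c, cfg$d)
  msg <- message_passing(V, p$WMSG_g2c)
  manual <- aggregate_target(att, msg, toy$Hc[j, ], p$theta, "standard")
  expect_equal(unname(fwd$Hc[j, ]), unname(manual), tolerance = 1e-12)
})

test_that("forward pass is permutation-equivariant", {
  toy <- make_toy_hgt(n_genes = 6, n_cells = 5, seed = 12, density = 0.7)
  fwd <- hgt_forward(toy$graph$edges, toy$Hg, toy$Hc, toy$params, toy$cfg)
  set.seed(13)
  pg <- sample(6); pc <- sample(5)
  Xp <- toy$X[pg, pc]
  gp <- build_graph(integrated_matrix(Xp, source = "multi_rna"))
  fwp <- hgt_forward(gp$edges, toy$Hg[pg, ], toy$Hc[pc, ], toy$params,
                     toy$cfg)
  expect_equal(fwp$Hg, fwd$Hg[pg, ], tolerance = 1e-12)
  expect_equal(fwp$Hc, fwd$Hc[pc, ], tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  toy <- make_toy_hgt(seed = 21, density = 0.8)
  cfg <- toy$cfg; p <- toy$params
  loss_fn <- function(pp) {
    fw <- hgt_forward(toy$graph$edges, toy$Hg, toy$Hc, pp, cfg)
    gae_kl_loss(fw$Hg %*% t(fw$Hc), toy$X)$loss
  }
  fwd <- hgt_forward(toy$graph$edges, toy$Hg, toy$Hc, p, cfg,
                     keep_cache = TRUE)
  kl <- gae_kl_loss(fwd$Hg %*% t(fwd$Hc), toy$X)
  bk <- scHGTnet:::hgt_backward(kl$dXhat %*% fwd$Hc,
                                t(kl$dXhat) %*% fwd$Hg, fwd, p, cfg)
  eps <- 1e-6
  for (nm in c("WQ_cell", "WK_gene", "WATT_g2c", "WMSG_c2g", "mu_g2c",
               "theta")) {
    pa <- p[[nm]]
    idx <- seq_len(min(length(pa), 6))
    num <- vapply(idx, function(i) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
    }, numeric(1))
    expect_equal(unname(as.vector(bk$g[[nm]])[idx]), num, tolerance = 1e-5,
                 label = nm)
  }
})

test_that("the KL graph-autoencoder loss is a divergence", {
  set.seed(31)
  X <- matrix(runif(20), 4, 5)
  expect_equal(gae_kl_loss(X, X)$loss, 0)
  for (i in 1:5) {
    Y <- X + matrix(rnorm(20, 0, 0.5), 4, 5)
    expect_gte(gae_kl_loss(Y, X)$loss, 0)
  }
  # gradient check
  Y <- X + 0.3
  kl <- gae_kl_loss(Y, X)
  eps <- 1e-6
  num <- (gae_kl_loss(Y + matrix(c(eps, rep(0, 19)), 4, 5), X)$loss -
            gae_kl_loss(Y - matrix(c(eps, rep(0, 19)), 4, 5), X)$loss) /
    (2 * eps)
  expect_equal(kl$dXhat[1, 1], num, tolerance = 1e-6)
})

test_that("subgraph sampling respects expression-proportional probabilities", {
  # cell with a single neighbor gene is sampled with probability 1
  X <- matrix(c(2, 0, 0, 1, 1, 1), 3, 2,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
  g <- build_graph(integrated_matrix(X, source = "multi_rna"))
  set.seed(41)
  expect_equal(sample_neighbor_genes(g, cell = 1, size = 1), 1L)
  # Monte-Carlo: frequencies match x / sum(x) within 3 binomial sigmas
  probs <- X[, 2] / sum(X[, 2])
  draws <- replicate(10000, sample_neighbor_genes(g, cell = 2, size = 1))
  for (gene in 1:3) {
    p_hat <- mean(draws == gene)
    se <- sqrt(probs[gene] * (1 - probs[gene]) / 10000)
    expect_lt(abs(p_hat - probs[gene]), 3 * se + 1e-9)
  }
})

test_that("subgraph sampler hits the requested sizes and coverage", {
  set.seed(42)
  X <- matrix(runif(60 * 40), 60, 40,
              dimnames = list(sprintf("g%d", 1:60), sprintf("c%d", 1:40)))
  X[runif(length(X)) < 0.3] <- 0
  g <- build_graph(integrated_matrix(X, source = "multi_rna"))
  cfg <- hgt_config(n_subgraphs = 10, coverage_fraction = 0.5, d = 8,
                    n_heads = 2, seed = 43)
  subs <- sample_subgraphs(g, cfg)
  expect_length(subs, 10)
  expect_gte(attr(subs, "coverage_genes"), 0.5)
  expect_gte(attr(subs, "coverage_cells"), 0.5)
  gene_target <- ceiling(0.5 * 60 / 10)
  for (sg in subs) {
    expect_lte(length(sg$genes), gene_target)
    expect_equal(length(sg$cells), ceiling(0.5 * 40 / 10))
  }
  # too-small graph errors with a suggestion
  Xs <- X[1:5, 1:5]
  gs <- build_graph(integrated_matrix(Xs, source = "multi_rna"))
  expect_error(sample_subgraphs(gs, hgt_config(n_subgraphs = 50, d = 8,
                                               n_heads = 2)),
               "n_subgraphs")
})

test_that("the training schedule performs n_subgraphs x epochs iterations", {
  cfg <- hgt_config()
  expect_equal(cfg$n_subgraphs * cfg$epochs_per_subgraph, 5000)
})

test_that("GAE training reduces the loss and separates a planted two-block matrix", {
  set.seed(51)
  # 30 genes x 24 cells, two blocks
  X <- matrix(runif(30 * 24, 0, 0.3), 30, 24)
  X[1:15, 1:12] <- X[1:15, 1:12] + 2
  X[16:30, 13:24] <- X[16:30, 13:24] + 2
  dimnames(X) <- list(sprintf("g%d", 1:30), sprintf("c%d", 1:24))
  Xi <- integrated_matrix(X, source = "multi_rna")
  g <- build_graph(Xi)
  cfg <- hgt_config(d = 16, n_heads = 4, n_subgraphs = 6,
                    epochs_per_subgraph = 40, coverage_fraction = 0.5,
                    lr = 1e-3, seed = 52)
  emb0 <- init_embeddings(Xi, d_hidden = 64, d_out = 16, epochs = 60,
                          seed = 53)
  fit <- hgt_train(g, emb0, Xi, cfg)
  expect_true(all(is.finite(fit$loss_trace)))
  expect_true(all(fit$loss_trace >= 0))
  # 5-epoch moving average is non-increasing in trend (start vs end)
  ma <- stats::filter(fit$loss_trace, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(utils::tail(ma, 1), utils::head(ma, 1))
  blocks <- rep(1:2, each = 12)
  expect_gt(asw(fit$embedding$cell, blocks), 0)
  # attention lives on graph edges only, and is non-negative
  att <- fit$attention
  expect_equal(length(att@x), nrow(g$edges))
  expect_true(all(att@x >= 0))
})

test_that("training is deterministic given the seed", {
  toy <- make_toy_hgt(n_genes = 12, n_cells = 10, d = 8, H = 2, seed = 61,
                      density = 0.9)
  emb0 <- list(gene = toy$Hg, cell = toy$Hc)
  cfg <- hgt_config(d = 8, n_heads = 2, n_subgraphs = 3,
                    epochs_per_subgraph = 10, coverage_fraction = 0.5,
                    seed = 62)
  f1 <- hgt_train(toy$graph, emb0, toy$X, cfg)
  f2 <- hgt_train(toy$graph, emb0, toy$X, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$embedding, f2$embedding)
})

test_that("final attention is the per-head L2 norm on each edge", {
  alpha <- matrix(c(0.3, 0.4, 0.1, 0.2), 2, 2)
  X <- matrix(c(1, 2, 0, 0, 3, 4), 3, 2,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
  g <- build_graph(integrated_matrix(X, source = "multi_rna"))
  # g has 4 edges; fabricate a 4 x 2 head matrix
  a4 <- rbind(alpha, alpha)
  att <- final_attention(a4, g)
  expect_equal(length(att@x), 4)
  expect_equal(max(abs(att@x - sqrt(rowSums(a4^2)))), 0, tolerance = 1e-12)
  # single head: absolute value; equal heads: w * sqrt(H)
  a1 <- matrix(c(-0.5, 0.25, 0.5, 0.75), 4, 1)
  expect_equal(final_attention(a1, g)@x, abs(a1[, 1]))
  aw <- matrix(0.3, 4, 4)
  expect_equal(unique(final_attention(aw, g)@x), 0.3 * 2)
  # norm dominates the per-head maximum for non-negative heads
  expect_true(all(final_attention(a4, g)@x >= apply(a4, 1, max)))
})

test_that("hgt_gae model object supports the standard S3 verbs", {
  toy <- make_toy_hgt(n_genes = 12, n_cells = 10, d = 8, H = 2, seed = 71,
                      density = 0.9)
  emb0 <- list(gene = toy$Hg, cell = toy$Hc)
  cfg <- hgt_config(d = 8, n_heads = 2, n_subgraphs = 3,
                    epochs_per_subgraph = 5, coverage_fraction = 0.5,
                    seed = 72)
  fit <- hgt_train(toy$graph, emb0, toy$X, cfg)
  expect_s3_class(fit, "hgt_gae")
  expect_output(print(fit), "HGT graph autoencoder")
  expect_output(summary(fit), "coverage")
  expect_named(coef(fit)["theta"], "theta")
  pr <- predict(fit, toy$graph, emb0)
  expect_equal(pr$cell, fit$embedding$cell, tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
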