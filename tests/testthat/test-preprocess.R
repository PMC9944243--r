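test_that("qc_filter removes sparse rows/columns, keeps the threshold case, and is idempotent", {
  set.seed(1)
  v <- matrix(rpois(50 * 1000, 3), 50, 1000)
  v[1, ] <- 0                               # never detected -> removed
  v[2, ] <- 0; v[2, 1] <- 5                 # exactly 0.1% of 1000 -> retained
  m <- toy_named_matrix(v)
  f <- qc_filter(m, min_nonzero_fraction = 0.001)
  expect_false("g1" %in% rownames(f$values))
  expect_true("g2" %in% rownames(f$values))
  f2 <- qc_filter(f, min_nonzero_fraction = 0.001)
  expect_equal(f2$values, f$values)
  expect_error(qc_filter(toy_named_matrix(matrix(0, 3, 3) + 0),
                         min_nonzero_fraction = 0.5),
               "removed")
})

test_that("log_normalize scales cells to a fixed depth and is depth-invariant", {
  m <- toy_named_matrix(matrix(c(10, 0, 3, 1), 2, 2))
  ln <- log_normalize(m, scale = 10)
  expect_equal(ln$values[, 1], c(g1 = log(11), g2 = 0))
  expect_equal(colSums(expm1(ln$values)), c(c1 = 10, c2 = 10))
  # doubling a cell's counts leaves it unchanged
  m2 <- toy_named_matrix(matrix(c(20, 0, 3, 1), 2, 2))
  expect_equal(log_normalize(m2, 10)$values[, 1], ln$values[, 1])
  expect_error(log_normalize(toy_named_matrix(matrix(c(1, 0, 0, 0), 2, 2))),
               "all-zero")
})

test_that("select_hvg keeps everything when short, ranks variance correctly", {
  m <- log_normalize(toy_counts(30, 20, seed = 2))
  expect_identical(select_hvg(m, 2000), m)     # fewer genes than n
  # Poisson-like mean-variance trend, one variance spike-in, one constant
  set.seed(3)
  ng <- 60; nc <- 40
  mu <- rlnorm(ng, 1, 0.6)
  v <- matrix(rpois(ng * nc, mu), ng, nc) +
    matrix(abs(rnorm(ng * nc, 0, 0.01)), ng, nc)
  v[7, ] <- rep(c(0.1, 9), each = nc / 2) * mean(mu) / 3  # spike-in
  v[9, ] <- 2                                             # constant
  m2 <- toy_named_matrix(v)
  top1 <- select_hvg(m2, 1)
  expect_equal(rownames(top1$values), "g7")
  expect_false("g9" %in% rownames(select_hvg(m2, ng - 1)$values))
  expect_error(select_hvg(m2, 0), "positive")
})

test_that("cca_align passes through one batch, preserves identical batches, and corrects shifts", {
  m <- log_normalize(toy_counts(40, 25, seed = 4))
  single <- cca_align(list(m))
  expect_equal(single$values, m$values)

  m2 <- m
  colnames(m2$values) <- paste0("b2_", colnames(m2$values))
  both <- cca_align(list(m, named_matrix(m2$values, modality = "rna")))
  expect_equal(both$values[, colnames(m$values)], m$values,
               tolerance = 1e-6)

  # constant additive per-gene shift: inter-batch gene-mean difference
  # reduced by >= 50% vs naive concatenation
  shift <- runif(40, 0.5, 1.5)
  m3 <- named_matrix(m$values + shift,
                     rownames(m$values), paste0("b3_", colnames(m$values)),
                     modality = "rna")
  ali <- cca_align(list(m, m3))
  naive_gap <- mean(abs(rowMeans(m3$values) - rowMeans(m$values)))
  got_gap <- mean(abs(
    rowMeans(ali$values[, colnames(m3$values)]) -
      rowMeans(ali$values[, colnames(m$values)])))
  expect_lt(got_gap, 0.5 * naive_gap)
  expect_true(all(ali$values >= 0))
  expect_error(cca_align(list(toy_counts(10, 5), toy_counts(10, 5))),
               "30 shared genes|duplicate")
})

test_that("clr_transform matches the closed form and acts per cell", {
  m <- toy_named_matrix(matrix(c(0, 1, 1, 1), 2, 2))
  ct <- clr_transform(m)
  expect_equal(ct$values[1, 1], 0)            # zero maps to zero
  # all-ones cell: geometric mean of (1+x) = 2 -> log(1 + 1/2)
  expect_equal(ct$values[, 2], c(g1 = log(1.5), g2 = log(1.5)))
  # scaling one cell changes only that column
  m2 <- m; m2$values[, 2] <- m2$values[, 2] * 5
  expect_equal(clr_transform(m2)$values[, 1], ct$values[, 1])
  expect_error(clr_transform(toy_named_matrix(matrix(c(1, 1, 0, 0), 2, 2))),
               "no non-zero")
})

test_that("peak_gene_weights implements the distance-decay with exon and truncation cases", {
  g <- list(toy_gene("gA", exons = data.frame(start = 100000,
                                              end = 101000)))
  tss <- 100000
  peaks <- toy_peaks(
    starts = c(tss - 100,          # overlaps the exon -> 1/exon_length
               tss - 5200,         # centre 5 kb away
               tss - 10200,        # centre exactly 10 kb -> 0.5
               tss + 149000,       # centre 149.2 kb -> kept, tiny
               tss + 150801),      # centre 150001+ -> truncated to 0
    ends = c(tss + 300, tss - 4800, tss - 9800, tss + 149400,
             tss + 151201))
  w <- peak_gene_weights(peaks, g, d0 = 10000, dmax = 150000)
  wv <- stats::setNames(w$weight, w$peak)
  expect_equal(unname(wv[peaks$name[1]]), 1 / 1000)
  expect_equal(unname(wv[peaks$name[2]]), 2^(-5000 / 10000))
  expect_equal(unname(wv[peaks$name[3]]), 0.5)
  expect_false(peaks$name[5] %in% w$peak)
  # monotone non-increasing in distance outside exons
  expect_true(wv[peaks$name[2]] > wv[peaks$name[3]])
  expect_true(wv[peaks$name[3]] > wv[peaks$name[4]])
})

test_that("a peak centred at the TSS but not exonic has weight 1", {
  g <- list(toy_gene("gA", exons = data.frame(start = 5000, end = 6000)))
  g[[1]]$tss <- 2000; g[[1]]$span <- c(5000, 6000)  # promoter outside span
  peaks <- toy_peaks(1800, 2200)
  w <- peak_gene_weights(peaks, g)
  expect_equal(w$weight, 1)                  # 2^0
})

test_that("peaks inside a different gene's body are excluded", {
  gA <- toy_gene("gA", exons = data.frame(start = 0, end = 1000))
  gB <- toy_gene("gB", exons = data.frame(start = 20000, end = 30000))
  # peak centre 25 kb: inside gB's span, 25 kb from gA's TSS
  peaks <- toy_peaks(24800, 25200)
  w <- peak_gene_weights(peaks, list(gA, gB))
  expect_false(any(w$gene == "gA"))
  expect_true(any(w$gene == "gB"))           # exonic for gB itself
})

test_that("regulatory_potential sums weighted peak counts and flags zero genes", {
  atac <- named_matrix(matrix(c(2, 4), 2, 1,
                              dimnames = list(c("p1", "p2"), "c1")),
                       modality = "atac_peak")
  w <- data.frame(gene = c("gA", "gA"), peak = c("p1", "p2"),
                  weight = c(1, 0.5))
  rp <- regulatory_potential(atac, w, genes = c("gA", "gB"))
  expect_equal(unname(rp$values["gA", 1]), 2 * 1 + 4 * 0.5)
  expect_equal(unname(rp$values["gB", 1]), 0)
  expect_equal(attr(rp, "zero_genes"), "gB")
  expect_error(regulatory_potential(atac, w[0, ]), "no peak")
})

test_that("ltmg discretization recovers component structure", {
  set.seed(5)
  n <- 60
  # one-component genes
  one <- matrix(abs(rnorm(30 * n, 5, 0.5)), 30, n)
  # two well-separated components (delta mu = 5 sigma)
  two <- t(replicate(10, sample(c(rnorm(n / 2, 2, 0.4),
                                  rnorm(n / 2, 4, 0.4)))))
  two <- abs(two)
  const <- matrix(3, 2, n)
  m <- toy_named_matrix(rbind(one, two, const),
                        rn = sprintf("g%d", 1:42))
  lt <- ltmg_discretize(m, max_components = 4)
  expect_gte(mean(lt$n_components[1:30] == 1), 0.9)
  expect_gte(mean(lt$n_components[31:40] == 2), 0.8)
  expect_equal(unname(lt$n_components[41:42]), c(1L, 1L))
  expect_true(all(lt$labels[41, ] == 1))
  # labels within the per-gene range
  expect_true(all(lt$labels <= lt$n_components[row(lt$labels)]))
  # two-component genes: labels agree with the planted split
  g2 <- which(lt$n_components == 2)[1]
  truth <- as.integer(m$values[g2, ] > 3) + 1L
  agree <- max(mean(lt$labels[g2, ] == truth),
               mean(lt$labels[g2, ] == 3L - truth))
  expect_gte(agree, 0.95)
})

test_that("velocity weights follow the rank formula with smoothing and normalization off", {
  # gene g1 positive in exactly one cell, that cell positive in only g1
  v <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  v[1, 1] <- 2
  vw <- velocity_weights(named_matrix(v, modality = "velocity"),
                         normalize = FALSE)
  expect_equal(unname(vw$beta[1, 1]), sqrt(2))   # a=b=1, |sets|=1
  expect_equal(unname(vw$beta[1, 2]), 0)
  expect_equal(unname(vw$sign[1, 1]), 1)

  # negative case: ranks start at 0
  v2 <- matrix(0, 1, 2, dimnames = list("g1", c("c1", "c2")))
  v2[1, ] <- c(-3, -1)       # |v| descending: c1 rank 0, c2 rank 1
  vw2 <- velocity_weights(named_matrix(v2, modality = "velocity"),
                          normalize = FALSE)
  # c1: a=0 (gene rank), b=0 (cell set {g1} rank 0); |Xi-|=2, |Xj-|=1
  expect_equal(unname(vw2$beta[1, 1]), sqrt((2 - 0 - 1)^2 + (1 - 0 - 1)^2))
  expect_equal(unname(vw2$sign[1, 1]), -1)

  # permutation invariance: beta stays attached to (gene, cell) pairs
  set.seed(6)
  v3 <- matrix(rnorm(30), 5, 6,
               dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  vw3 <- velocity_weights(named_matrix(v3, modality = "velocity"))
  perm <- sample(6)
  v3p <- v3[, perm]
  vw3p <- velocity_weights(named_matrix(v3p, modality = "velocity"))
  expect_equal(vw3p$beta, vw3$beta[, perm])
  # normalized mode is bounded by sqrt(2)
  expect_lte(max(vw3$beta), sqrt(2))
})

test_that("velocity group-mean smoothing uses discretization labels", {
  v <- matrix(c(1, 3, -2, 5), 1, 4,
              dimnames = list("g1", paste0("c", 1:4)))
  labs <- matrix(c(1L, 1L, 2L, 2L), 1, 4,
                 dimnames = dimnames(v))
  lt <- structure(list(labels = labs, n_components = c(g1 = 2L)),
                  class = "ltmg_labels")
  vw <- velocity_weights(named_matrix(v, modality = "velocity"), lt)
  expect_equal(unname(vw$smoothed_velocity[1, ]), c(2, 2, 1.5, 1.5))
})

test_that("gas matrix combines expression and regulatory potential by velocity sign", {
  rn <- list("g1", "c1")
  rna <- named_matrix(matrix(1, 1, 1, dimnames = rn), modality = "rna")
  rp <- named_matrix(matrix(2, 1, 1, dimnames = rn), modality = "gas")
  g0 <- gas_matrix(rna, rp, NULL)
  expect_equal(unname(g0$values[1, 1]), 3)     # velocity 0: x^R + x^A'
  vw <- list(beta = matrix(sqrt(2), 1, 1, dimnames = rn),
             sign = matrix(1, 1, 1, dimnames = rn))
  rp1 <- named_matrix(matrix(1, 1, 1, dimnames = rn), modality = "gas")
  gp <- gas_matrix(rna, rp1, vw)
  expect_equal(unname(gp$values[1, 1]), 1 + (1 + sqrt(2)) * 1)
  # large negative beta with zero expression clips at 0 by default
  vw2 <- list(beta = matrix(3, 1, 1, dimnames = rn),
              sign = matrix(-1, 1, 1, dimnames = rn))
  rna0 <- named_matrix(matrix(0, 1, 1, dimnames = rn), modality = "rna")
  gn <- gas_matrix(rna0, rp, vw2)
  expect_equal(unname(gn$values[1, 1]), 0)
  gn2 <- gas_matrix(rna0, rp, vw2, clip_negative = FALSE)
  expect_equal(unname(gn2$values[1, 1]), (1 - 3) * 2)
  expect_error(gas_matrix(rna, named_matrix(matrix(1, 2, 1,
    dimnames = list(c("g1", "g2"), "c1")), modality = "gas"), NULL),
    "mismatch")
})

test_that("GAS dominates expression wherever velocity is non-negative", {
  set.seed(7)
  dn <- list(paste0("g", 1:6), paste0("c", 1:8))
  rna <- named_matrix(matrix(runif(48), 6, 8, dimnames = dn),
                      modality = "rna")
  rp <- named_matrix(matrix(runif(48), 6, 8, dimnames = dn),
                     modality = "gas")
  vel <- named_matrix(matrix(rnorm(48), 6, 8, dimnames = dn),
                      modality = "velocity")
  vw <- velocity_weights(vel)
  gas <- gas_matrix(rna, rp, vw)
  nonneg <- vw$sign >= 0
  expect_true(all(gas$values[nonneg] >= rna$values[nonneg] - 1e-12))
})

test_that("steady-state velocity recovers induction and repression", {
  set.seed(8)
  n <- 100
  # steady cells express highly (anchor the gamma fit); induced/repressed
  # cells sit at lower expression with unspliced excess or deficit
  s <- matrix(rpois(2 * n, 30), 2, n,
              dimnames = list(c("g1", "g2"), paste0("c", 1:n)))
  s[, 1:30] <- matrix(rpois(2 * 30, 8), 2, 30)
  gamma <- 0.5
  u1 <- gamma * s[1, ]; u1[1:30] <- u1[1:30] * 3      # induced cells
  u2 <- gamma * s[2, ]; u2[1:30] <- u2[1:30] * 0.1    # repressed cells
  u <- rbind(g1 = u1, g2 = u2)
  v <- steady_state_velocity(
    named_matrix(s, modality = "rna"),
    named_matrix(round(u), modality = "rna"), quantile = 0.8)
  expect_gt(mean(v$values[1, 1:30] > 0), 0.85)
  expect_lt(mean(v$values[2, 1:30] > 0), 0.15)
})
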