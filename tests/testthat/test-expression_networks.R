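test_that("row Z-scores have zero mean and unit population sd", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- zscore_rows(m), "constant")
  expect_equal(unname(z["a", ]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(unname(z["b", ]), c(0, 0, 0))

  set.seed(401)
  r <- matrix(rnorm(50), 5)
  zr <- zscore_rows(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 5))
  expect_equal(unname(apply(zr, 1, function(x) sqrt(mean((x - mean(x))^2)))),
               rep(1, 5))
})

test_that("identical groups yield no DEGs and split fractions match", {
  mat <- matrix(5, nrow = 4, ncol = 6,
                dimnames = list(paste0("g", 1:4),
                                paste("leaf", rep(c("CK", "LN"), each = 3),
                                      1:3, sep = "_")))
  samples <- parse_sample_ids(colnames(mat))
  degs <- call_degs(mat, samples, "leaf", "LN")
  expect_equal(sum(degs$deg), 0L)
  expect_error(call_degs(mat, samples, "root", "LN"), "missing group")

  # printed worked example: 55 of 65 upregulated is 84.6%
  expect_equal(percent_of(55, 65, 1), 84.6)
})

test_that("BH adjustment is monotone in the raw p-values", {
  corpus <- default_corpus()
  expr <- corpus$expression
  d <- call_degs(expr$matrix, expr$samples, "leaf", "LP")
  ord <- order(d$p)
  expect_true(all(diff(d$fdr[ord]) >= -1e-12))
})

test_that("Venn regions partition the union", {
  v <- venn_partition(list(A = c("a", "b"), B = c("b", "c")))
  expect_setequal(v$regions$region, c("A", "B", "A&B"))
  expect_equal(sort(v$regions$size), c(1L, 1L, 1L))
  expect_equal(sum(v$regions$size), 3L)

  dis <- venn_partition(list(A = "x", B = "y"))
  expect_equal(dis$regions$size[dis$regions$region == "A&B"], 0L)

  set.seed(402)
  pool <- paste0("g", 1:30)
  sets <- list(A = sample(pool, 12), B = sample(pool, 8),
               C = sample(pool, 15))
  v3 <- venn_partition(sets)
  expect_equal(sum(v3$regions$size), length(unique(unlist(sets))))
  # brute-force enumeration oracle
  for (g in unique(unlist(sets))) {
    membership <- names(sets)[vapply(sets, function(s) g %in% s, TRUE)]
    region <- paste(membership, collapse = "&")
    expect_identical(v3$membership$region[v3$membership$gene == g], region)
  }
  expect_error(venn_partition(list(A = "x")), ">= 2")
})

test_that("universal responders are the intersection of all sets", {
  sets <- list(a = c("g1", "g2"), b = c("g2", "g3"), c = c("g2"))
  expect_identical(universal_responders(sets), "g2")
  expect_identical(universal_responders(c(sets, list(d = character(0)))),
                   character(0))
  ur <- universal_responders(sets)
  expect_true(all(vapply(sets, function(s) all(ur %in% s), TRUE)))
})

test_that("the network applies the |r| cutoff over the selected samples", {
  base <- c(1, 2, 3, 4, 5, 6)
  mat <- rbind(g1 = base, g2 = base * 2, g3 = 7 - base,
               g4 = c(1, 1, 2, 2, 1, 2))
  colnames(mat) <- paste("leaf", rep(c("CK", "LN"), each = 3), 1:3, sep = "_")
  samples <- parse_sample_ids(colnames(mat))
  net <- build_network(mat, samples, cutoff = 0.6)
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_true("g1 g2" %in% key)
  expect_equal(net$edges$r[key == "g1 g2"], 1)
  expect_true("g1 g3" %in% key)  # r = -1 edges count under |r|
  expect_equal(net$edges$r[key == "g1 g3"], -1)
  expect_equal(sum(net$degree), 2L * nrow(net$edges))

  expect_error(build_network(mat[, 1:2], samples[1:2, ]), ">= 3 samples")
})

test_that("network correlations match a brute-force computation", {
  set.seed(403)
  mat <- matrix(runif(30, 1, 50), nrow = 5,
                dimnames = list(paste0("g", 1:5),
                                paste("leaf", rep(c("CK", "LN"), each = 3),
                                      1:3, sep = "_")))
  samples <- parse_sample_ids(colnames(mat))
  net <- build_network(mat, samples, cutoff = 0)
  brute_r <- function(x, y) {
    n <- length(x)
    sxy <- sum(x * y) - sum(x) * sum(y) / n
    sxx <- sum(x^2) - sum(x)^2 / n
    syy <- sum(y^2) - sum(y)^2 / n
    sxy / sqrt(sxx * syy)
  }
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    expect_equal(e$r, brute_r(mat[e$gene_a, ], mat[e$gene_b, ]),
                 tolerance = 1e-12)
  }
  # the edge set is invariant to gene order
  net2 <- build_network(mat[5:1, ], samples, cutoff = 0)
  expect_equal(net$edges, net2$edges)
})

test_that("hub ranking is by degree with lexicographic ties", {
  net <- structure(list(
    nodes = c("hub", "x1", "x2", "x3", "b", "a"),
    edges = NULL,
    degree = c(hub = 33L, x1 = 1L, x2 = 1L, x3 = 1L, b = 32L, a = 32L)
  ), class = "coexpression_network")
  h <- hub_genes(net, k = 3L)
  expect_identical(h$gene_id, c("hub", "a", "b"))  # 33 above 32; a before b
  expect_identical(h$degree, c(33L, 32L, 32L))
})

test_that("ddCt folds follow the analytic identities", {
  ct <- expand.grid(gene_id = c("EF1a", "t1"), tissue = "root",
                    treatment = c("CK", "LN"), replicate = 1:3,
                    stringsAsFactors = FALSE)
  ct$ct <- ifelse(ct$gene_id == "EF1a", 20, 26)
  ct$ct[ct$gene_id == "t1" & ct$treatment == "LN"] <- 24  # ddCt = -2
  res <- ddct(ct, "EF1a", c("root", "CK"))
  expect_equal(res$fold[res$treatment == "CK"], 1)
  expect_equal(res$fold[res$treatment == "LN"], 4)
  expect_equal(res$ddct[res$treatment == "LN"], -2)
  expect_error(ddct(ct[ct$gene_id != "EF1a", ], "EF1a", c("root", "CK")),
               "not in table")
})
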