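test_that("read_expression parses delimited tables and rejects bad input", {
  m <- matrix(c(1, 0, 5, 2, 3, 4), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  x <- read_expression(write_expr_file(m), unit = "counts")
  expect_s3_class(x, "expression_matrix")
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(unclass(x), m, ignore_attr = TRUE)
  expect_identical(expr_unit(x), "counts")

  # CSV round-trips the same values
  xc <- read_expression(write_expr_file(m, sep = ","), unit = "counts")
  expect_equal(unclass(xc)[, ], unclass(x)[, ])

  # duplicated gene id
  md <- m; rownames(md) <- c("g1", "g1", "g3")
  expect_error(read_expression(write_expr_file(md), "counts"), "duplicate gene")

  # empty file
  empty <- tempfile(fileext = ".tsv"); file.create(empty)
  expect_error(read_expression(empty, "counts"), "empty")

  # negative values
  mn <- m; mn[1, 1] <- -1
  expect_error(read_expression(write_expr_file(mn), "counts"), "non-negative")
})

test_that("read_expression accepts MatrixMarket triplets with id files", {
  m <- matrix(c(0, 2, 1, 0, 0, 7), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  gid <- tempfile(); writeLines(rownames(m), gid)
  sid <- tempfile(); writeLines(colnames(m), sid)
  x <- read_expression(mtx, "counts", gene_ids = gid, sample_ids = sid)
  expect_equal(unclass(x)[, ], m)
  expect_error(read_expression(mtx, "counts"), "requires")
})

test_that("prevalence filter keeps genes expressed in >= ceil(f*N) samples", {
  m <- rbind(g1 = c(1, 2, 3, 0),   # 3/4 expressed: boundary, retained
             g2 = c(1, 2, 0, 0),   # 2/4: dropped
             g3 = c(1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  x <- expression_matrix(m, "counts")
  kept <- filter_genes(x, 0.75)
  expect_identical(rownames(kept), c("g1", "g3"))
  expect_identical(colnames(kept), colnames(m))
  # idempotence
  expect_equal(unclass(filter_genes(kept, 0.75)), unclass(kept))
  # everything filtered out is an error
  expect_error(filter_genes(x, 1, threshold = 10), "all genes removed")
  expect_error(filter_genes(x, 0), "min_fraction")
})

test_that("counts_to_tpm matches the hand-computed TPM formula", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  x <- expression_matrix(m, "counts")
  len <- setNames(rep(1000, 3), rownames(m))
  tpm <- counts_to_tpm(x, len)
  expect_equal(unname(unclass(tpm)[, 1]), c(250000, 250000, 500000))
  expect_identical(expr_unit(tpm), "TPM")

  # length-aware: halving a length doubles its rate share
  len2 <- setNames(c(500, 1000, 1000), rownames(m))
  tpm2 <- counts_to_tpm(x, len2)
  expect_equal(unname(unclass(tpm2)[, 1]), c(2, 1, 2) / 5 * 1e6)

  # all-zero sample column stays zero without division errors
  mz <- cbind(m, s2 = c(0, 0, 0))
  tpmz <- counts_to_tpm(expression_matrix(mz, "counts"), len)
  expect_equal(unname(unclass(tpmz)[, "s2"]), c(0, 0, 0))

  # normalization identity on random nonzero columns
  set.seed(42)
  mr <- matrix(rpois(50, 20) + 1, 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  lenr <- setNames(runif(10, 200, 5000), rownames(mr))
  tr <- counts_to_tpm(expression_matrix(mr, "counts"), lenr)
  expect_equal(colSums(unclass(tr)), rep(1e6, 5), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(counts_to_tpm(x, len[1:2]), "missing gene lengths")
  expect_error(counts_to_tpm(tpm, len), "expects unit 'counts'")
})

test_that("fpkm_to_tpm renormalizes each sample to one million", {
  m <- matrix(c(2, 2, 1, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tpm <- fpkm_to_tpm(expression_matrix(m, "FPKM"))
  expect_equal(unname(unclass(tpm)[, "s1"]), c(500000, 500000))
  expect_equal(unname(unclass(tpm)[, "s2"]), c(250000, 750000))
  # a column already summing to 1e6 is a fixed point
  mf <- matrix(c(4e5, 6e5), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unclass(fpkm_to_tpm(expression_matrix(mf, "FPKM"))),
               mf, ignore_attr = TRUE)
})

test_that("TPM is a fixed point of renormalization after count conversion", {
  set.seed(7)
  m <- matrix(rpois(60, 15), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  len <- setNames(runif(12, 300, 8000), rownames(m))
  tpm <- counts_to_tpm(expression_matrix(m, "counts"), len)
  renorm <- sweep(unclass(tpm), 2, colSums(unclass(tpm)), "/") * 1e6
  expect_equal(renorm, unclass(tpm), tolerance = 1e-12)
})

test_that("log transform is log2(TPM+1) and strictly monotone", {
  m <- matrix(c(0, 1, 3, 7), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  lt <- log_transform(expression_matrix(m, "TPM"))
  expect_equal(unname(unclass(lt)[, 1]), c(0, 1, 2, 3))
  expect_identical(expr_unit(lt), "log2TPM")
  # monotone on random entries
  set.seed(1)
  v <- matrix(runif(100, 0, 1e5), 20, 5,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:5)))
  l <- unclass(log_transform(expression_matrix(v, "TPM")))
  expect_identical(order(as.vector(v)), order(as.vector(l)))
  expect_error(log_transform(expression_matrix(m, "counts")), "expects unit 'TPM'")
})

test_that("as_log2tpm routes every unit to log2TPM", {
  m <- matrix(c(5, 10, 0, 20), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  len <- setNames(c(1000, 2000), rownames(m))
  for (u in c("counts", "FPKM", "TPM")) {
    out <- as_log2tpm(expression_matrix(m, u), lengths = len)
    expect_identical(expr_unit(out), "log2TPM")
  }
  lt <- as_log2tpm(expression_matrix(m, "log2TPM"))
  expect_equal(unclass(lt), m, ignore_attr = TRUE)
  expect_error(as_log2tpm(expression_matrix(m, "counts")), "gene-length")
})

test_that("align_genes enforces the coverage contract", {
  m <- matrix(1:6, 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  x <- expression_matrix(m + 0, "log2TPM")
  train <- c("g3", "g1", "g2")
  al <- align_genes(x, train)
  expect_identical(rownames(al), train)
  expect_equal(unclass(al)["g3", ], unclass(x)["g3", ])
  # below coverage threshold: error
  expect_error(align_genes(x, c(train, "g4", "g5")), "training genes present")
  # missing genes only fill with the explicit flag
  expect_error(align_genes(x, c(train, "g4"), min_coverage = 0.7),
               "fill_missing")
  filled <- align_genes(x, c(train, "g4"), min_coverage = 0.7,
                        fill_missing = TRUE)
  expect_equal(unname(unclass(filled)["g4", ]), c(0, 0))
})

test_that("label harmonization merges, excludes, and accounts for every sample", {
  raw <- c(a = "ZNF384-like", b = "KMT2A-like", c = "CRLF2(non-Ph-like)",
           d = "Ph-like", e = "other", f = "Ph;DUX4", g = "ZNF384",
           h = "KMT2A")
  out <- harmonize_labels(raw)
  expect_identical(unname(out$labels["a"]), "ZNF384 Group")
  expect_identical(unname(out$labels["g"]), "ZNF384 Group")
  expect_identical(unname(out$labels["b"]), "KMT2A Group")
  expect_identical(unname(out$labels["h"]), "KMT2A Group")
  expect_false("c" %in% names(out$labels))
  expect_setequal(out$dropped$sample, c("c", "e", "f"))
  expect_identical(out$dropped$reason[out$dropped$sample == "c"],
                   "excluded subtype")
  expect_identical(out$dropped$reason[out$dropped$sample == "f"],
                   "two subtype calls")
  # conservation + membership invariants
  expect_equal(length(out$labels) + nrow(out$dropped), length(raw))
  expect_true(all(out$labels %in% ball_scheme()$labels))
  expect_error(harmonize_labels(c(z = "not-a-subtype")), "not covered")
})

test_that("the default scheme has 20 categories in four disjoint groups", {
  sc <- ball_scheme()
  expect_length(sc$labels, 20L)
  expect_identical(sort(unique(unname(sc$group_map))),
                   sort(c("Fusion Gene", "TF Alteration", "Ploidy",
                          "Rare Subtype")))
  expect_true(all(sc$labels %in% names(sc$group_map)))
  expect_identical(unname(sc$group_map["Ph-like"]), "Fusion Gene")
  expect_identical(unname(sc$group_map["PAX5alt"]), "TF Alteration")
  expect_false(any(sc$exclusions %in% sc$labels))
})
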