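test_that("co-occurrence counts within-window cross pairs", {
  a <- site_set("A", c("chr1", "chr1"), c(100, 500))
  b <- site_set("B", c("chr1", "chr1"), c(250, 2000))
  m <- pairwise_cooccurrence(list(a, b), window = 200)
  expect_equal(m["A", "B"], 1L)               # only |100 - 250| = 150 <= 200
  expect_equal(m["A", "A"], 2L)               # diagonal = site count
  expect_equal(m["B", "B"], 2L)

  # identical tracks: two zero-distance pairs, 400 > 200 excluded
  a2 <- site_set("A", c("chr1", "chr1"), c(100, 500))
  b2 <- site_set("B", c("chr1", "chr1"), c(100, 500))
  m2 <- pairwise_cooccurrence(list(a2, b2), window = 200)
  expect_equal(m2["A", "B"], 2L)

  # sites on different chromosomes never pair
  m3 <- pairwise_cooccurrence(list(site_set("A", "chr1", 100),
                                   site_set("B", "chr2", 100)), window = 200)
  expect_equal(m3["A", "B"], 0L)

  expect_error(pairwise_cooccurrence(list(a, a)), "duplicate TF labels")
})

test_that("the sweep matches the double-loop oracle and is symmetric", {
  for (seed in 1:30) {
    inst <- random_instance(seed + 900, n_tfs = 5L, max_sites = 80L)
    if (length(inst) < 2L) next
    m <- pairwise_cooccurrence(inst, window = 200)
    expect_identical(unclass(m)[, , drop = FALSE],
                     oracle_coocc(inst, 200)[rownames(m), colnames(m)],
                     ignore_attr = TRUE)
    expect_identical(unclass(m), t(unclass(m)))
    expect_equal(unname(diag(m)), vapply(inst, nrow, 0L))
  }
})

test_that("permuting the input site sets permutes the matrix consistently", {
  inst <- random_instance(77, n_tfs = 5L, max_sites = 80L)
  m <- pairwise_cooccurrence(inst, window = 150)
  perm <- rev(seq_along(inst))
  m2 <- pairwise_cooccurrence(inst[perm], window = 150)
  expect_equal(unclass(m2), unclass(m)[rownames(m2), colnames(m2)],
               ignore_attr = TRUE)
})

test_that("row correlation matches the textbook Pearson formula", {
  set.seed(42)
  m <- matrix(sample.int(50, 64, replace = TRUE), 8, 8)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dimnames(m) <- list(LETTERS[1:8], LETTERS[1:8])
  class(m) <- c("cooccurrence_matrix", class(m))
  cm <- correlation_matrix(m)
  for (i in 1:8) {
    for (j in 1:8) {
      keep <- setdiff(1:8, c(i, j))
      expect_equal(cm[i, j], oracle_pearson(unclass(m)[i, keep],
                                            unclass(m)[j, keep]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(max(abs(cm - t(cm)), na.rm = TRUE), 0, tolerance = 1e-12)
  expect_true(all(is.na(cm) | (cm >= -1 - 1e-12 & cm <= 1 + 1e-12)))
  dg <- diag(cm)
  expect_equal(unname(dg[!is.na(dg)]), rep(1, sum(!is.na(dg))),
               tolerance = 1e-12)
})

test_that("identical rows correlate at 1 and constant rows are undefined", {
  labels <- c("A", "B", "C", "D", "E")
  m <- matrix(0, 5, 5, dimnames = list(labels, labels))
  m[1, 3:5] <- m[3:5, 1] <- c(2, 7, 4)   # rows A and B agree outside (A, B)
  m[2, 3:5] <- m[3:5, 2] <- c(2, 7, 4)
  m[1, 2] <- m[2, 1] <- 6
  m[3, 4] <- m[4, 3] <- 1
  m[4, 5] <- m[5, 4] <- 8
  diag(m) <- c(9, 5, 7, 11, 13)
  cm <- correlation_matrix(m, drop_self_indices = TRUE)
  expect_equal(cm["A", "B"], 1, tolerance = 1e-12)

  # a row constant on every kept index is undefined, not an error
  const <- matrix(3, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  set.seed(2)
  v <- matrix(sample.int(9, 25, replace = TRUE), 5, 5)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  const[2:5, 2:5] <- v[2:5, 2:5]   # row/col "a" stays constant
  expect_no_error(cmc <- correlation_matrix(const))
  expect_true(all(is.na(cmc["a", ])))
  expect_false(is.na(cmc["b", "c"]))

  expect_error(correlation_matrix(m[1:2, 1:2]), ">= 3 labels")
})

test_that("hierarchical ordering keeps correlated blocks contiguous", {
  labels <- c("A", "B", "C", "D", "E")
  cm <- matrix(0.1, 5, 5, dimnames = list(labels, labels))
  cm[1:3, 1:3] <- 0.9
  cm[4:5, 4:5] <- 0.9
  diag(cm) <- 1
  ord <- hierarchical_order(cm)
  pos_abc <- sort(match(c("A", "B", "C"), ord$order))
  pos_de <- sort(match(c("D", "E"), ord$order))
  expect_equal(pos_abc, seq(pos_abc[1], length.out = 3))
  expect_equal(pos_de, seq(pos_de[1], length.out = 2))
})

test_that("ties resolve to lexicographic order and NAs warn", {
  labels <- c("delta", "alpha", "charlie", "bravo")
  cm <- diag(4)
  dimnames(cm) <- list(labels, labels)
  ord <- hierarchical_order(cm)
  expect_equal(sort(ord$order), ord$order)  # all distances tied -> lexicographic

  cm[1, 2] <- cm[2, 1] <- NA
  expect_warning(hierarchical_order(cm), "undefined correlations")

  single <- matrix(1, 1, 1, dimnames = list("A", "A"))
  expect_equal(hierarchical_order(single)$order, "A")
})

test_that("duplicate co-located tracks correlate at 1 and sit adjacent", {
  set.seed(31)
  inst <- lapply(paste0("TF", 1:4), function(t) {
    site_set(t, sample(c("c1", "c2"), 60, replace = TRUE),
             sample.int(5e4, 60))
  })
  twin <- site_set("TWIN", inst[[1]]$chrom, inst[[1]]$position)
  all_sets <- c(inst, list(twin))
  m <- pairwise_cooccurrence(all_sets, window = 200)
  cm <- correlation_matrix(m)
  lab <- tf_label(inst[[1]])
  expect_equal(cm[lab, "TWIN"], 1, tolerance = 1e-12)
  ord <- hierarchical_order(cm)$order
  expect_equal(abs(match(lab, ord) - match("TWIN", ord)), 1)
})

test_that("heatmap rendering is a deterministic vector image", {
  cm <- diag(3)
  dimnames(cm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  render_heatmap(cm, path = p1)
  render_heatmap(cm, path = p2)
  expect_gt(file.size(p1), 0)
  expect_identical(readLines(p1), readLines(p2))  # byte-stable output
  expect_match(readLines(p1)[1], "^<svg")

  # a larger matrix with an explicit ordering and block outlines renders too
  set.seed(8)
  big <- matrix(runif(28 * 28, -1, 1), 28, 28)
  big[lower.tri(big)] <- t(big)[lower.tri(big)]
  diag(big) <- 1
  dimnames(big) <- list(sprintf("TF%02d", 1:28), sprintf("TF%02d", 1:28))
  ord <- hierarchical_order(big)
  render_heatmap(big, ord, p1, blocks = list(ord$order[1:5]))
  expect_gt(file.size(p1), 1000)
  expect_error(render_heatmap(cm, ordering = c("A", "B"), path = p1),
               "permutation")
})
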