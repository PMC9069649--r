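test_that("sites chain when closer than the gap and split otherwise", {
  ss <- list(site_set("A", "chr1", 100),
             site_set("B", "chr1", 250),
             site_set("C", "chr1", 600))
  cs <- build_clusters(ss, cluster_params(gap = 200, span_cap = NULL))
  expect_equal(nrow(cs$clusters), 2L)          # 150 < 200 merges, 350 splits
  expect_equal(cs$clusters$tf_labels, c("A,B", "C"))
  expect_equal(cs$clusters$start, c(100, 600))
  expect_equal(cs$clusters$end, c(250, 600))
  expect_equal(cs$clusters$n_tfs, c(2L, 1L))

  # distance exactly equal to the gap splits (strict "less than")
  cs2 <- build_clusters(list(site_set("A", "chr1", c(0, 200))),
                        cluster_params(gap = 200, span_cap = NULL))
  expect_equal(nrow(cs2$clusters), 2L)
})

test_that("the span cap closes a chain that grows too wide", {
  ss <- lapply(1:5, function(i) site_set(paste0("T", i), "chr1", (i - 1) * 150))
  cs <- build_clusters(ss, cluster_params(gap = 200, span_cap = 500))
  expect_equal(cs$clusters$n_sites, c(4L, 1L))  # 600 - 0 > 500 forces a split
  expect_equal(cs$clusters$start, c(0, 600))
  expect_equal(cs$clusters$end, c(450, 600))
  expect_true(all(cs$clusters$end - cs$clusters$start <= 500))

  # without the cap the whole chain is one cluster
  cs_nocap <- build_clusters(ss, cluster_params(gap = 200, span_cap = NULL))
  expect_equal(nrow(cs_nocap$clusters), 1L)
})

test_that("equal positions always co-cluster, ordered by TF label", {
  ss <- list(site_set("Z", "chr1", 100), site_set("A", "chr1", 100))
  cs <- build_clusters(ss, cluster_params())
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$members$tf, c("A", "Z"))
  expect_equal(cs$clusters$tf_labels, "A,Z")
})

test_that("cluster sizes count distinct TFs or total sites", {
  ss <- list(site_set("A", "chr1", c(100, 150)), site_set("B", "chr1", 120))
  cs <- build_clusters(ss, cluster_params())
  expect_equal(cluster_sizes(cs, "distinct_tfs"), 2L)
  expect_equal(cluster_sizes(cs, "total_sites"), 3L)

  single <- build_clusters(list(site_set("A", "chr1", 5)), cluster_params())
  expect_equal(cluster_sizes(single, "distinct_tfs"), 1L)
  expect_equal(cluster_sizes(single, "total_sites"), 1L)

  set.seed(11)
  inst <- random_instance(11, n_tfs = 4L, max_sites = 60L)
  cs <- build_clusters(inst, cluster_params())
  recount <- vapply(split(cs$members$tf, cs$members$cluster_id),
                    function(t) length(unique(t)), 0L)
  expect_equal(cluster_sizes(cs, "distinct_tfs"),
               unname(recount[as.character(cs$clusters$cluster_id)]))
})

test_that("clustering partitions the site pool", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    cs <- build_clusters(inst, cluster_params())
    expect_equal(sum(cs$clusters$n_sites), sum(vapply(inst, nrow, 0L)))
    expect_equal(anyDuplicated(cs$members[c("chrom", "position", "tf")]) > 0,
                 anyDuplicated(pool_of(inst)[c("chrom", "position", "tf")]) > 0)
    expect_true(all(cs$clusters$n_tfs >= 1L &
                      cs$clusters$n_tfs <= cs$clusters$n_sites))
  }
})

test_that("increasing the gap never increases the number of clusters", {
  for (seed in 1:10) {
    inst <- random_instance(seed + 100)
    n_prev <- Inf
    for (gap in c(20, 100, 200, 500)) {
      cs <- build_clusters(inst, cluster_params(gap = gap, span_cap = NULL))
      expect_lte(nrow(cs$clusters), n_prev)
      n_prev <- nrow(cs$clusters)
    }
  }
})

test_that("a narrower gap shrinks the maximum cluster size", {
  spec <- hub_fixture_spec(seed = 3L)
  gen <- generate_sitesets(spec)
  wide <- build_clusters(gen$sitesets, cluster_params(gap = 200))
  narrow <- build_clusters(gen$sitesets, cluster_params(gap = 20, span_cap = 500))
  expect_lte(max(cluster_sizes(narrow, "total_sites")),
             max(cluster_sizes(wide, "total_sites")))
})

test_that("cluster composition is invariant under chromosome-wide shifts", {
  inst <- random_instance(5)
  shifted <- lapply(inst, function(s) {
    site_set(tf_label(s), s$chrom, s$position + 1234)
  })
  a <- build_clusters(inst, cluster_params())
  b <- build_clusters(shifted, cluster_params())
  expect_equal(b$clusters$n_sites, a$clusters$n_sites)
  expect_equal(b$clusters$n_tfs, a$clusters$n_tfs)
  expect_equal(b$clusters$start, a$clusters$start + 1234)
  expect_equal(b$clusters$tf_labels, a$clusters$tf_labels)
})

test_that("chaining matches the transitive brute-force oracle", {
  for (seed in 1:40) {
    inst <- random_instance(seed + 500)
    for (cap in list(NULL, 500)) {
      cs <- build_clusters(inst, cluster_params(gap = 200, span_cap = cap))
      expect_identical(partition_of(cs), oracle_chain(pool_of(inst), 200, cap))
    }
  }
})

test_that("degenerate inputs are handled explicitly", {
  empty <- build_clusters(list(site_set("A")), cluster_params())
  expect_equal(nrow(empty$clusters), 0L)
  expect_equal(nrow(empty$members), 0L)
  expect_error(cluster_params(gap = -5), "positive")
  expect_error(cluster_params(gap = 200, span_cap = 100), ">= `gap`")
})
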