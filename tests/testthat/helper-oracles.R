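# Independent brute-force oracles used to cross-check the implementation.

# Transitive-chaining oracle: per chromosome, build the adjacency graph of
# site pairs at distance < gap and take connected components by breadth-first
# search; with a span cap, split each component by scanning its sorted
# positions and closing a cluster when a site is farther than `cap` from the
# first site of the open cluster. Returns a canonical partition: a list of
# "chrom:pos:tf" member vectors, one per cluster, lexicographically sorted.
oracle_chain <- function(pool, gap, cap = NULL) {
  out <- list()
  for (ch in unique(pool$chrom)) {
    sub <- pool[pool$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$position, sub$tf), , drop = FALSE]
    n <- nrow(sub)
    adj <- abs(outer(sub$position, sub$position, "-")) < gap
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (k in unique(comp)) {
      idx <- which(comp == k)
      pos <- sub$position[idx]
      if (is.null(cap)) {
        groups <- list(idx)
      } else {
        groups <- list()
        first <- pos[1]
        cur <- idx[1]
        for (t in seq_along(idx)[-1]) {
          # consecutive distance is < gap inside a component only if no split
          # occurred; re-check both rules from the open cluster's first site
          if (pos[t] - pos[t - 1] < gap && pos[t] - first <= cap) {
            cur <- c(cur, idx[t])
          } else {
            groups <- c(groups, list(cur))
            cur <- idx[t]
            first <- pos[t]
          }
        }
        groups <- c(groups, list(cur))
      }
      for (g in groups) {
        out <- c(out, list(sort(paste(ch, sub$position[g], sub$tf[g], sep = ":"))))
      }
    }
  }
  out[order(vapply(out, `[[`, "", 1L))]
}

# Canonical partition of a cluster_set, comparable with oracle_chain output.
partition_of <- function(cs) {
  keys <- paste(cs$members$chrom, cs$members$position, cs$members$tf, sep = ":")
  parts <- lapply(split(keys, cs$members$cluster_id), sort)
  parts <- unname(parts)
  parts[order(vapply(parts, `[[`, "", 1L))]
}

# Quadratic double-loop co-occurrence oracle.
oracle_coocc <- function(sitesets, window) {
  labels <- vapply(sitesets, tf_label, "")
  m <- length(labels)
  cells <- matrix(0L, m, m, dimnames = list(labels, labels))
  diag(cells) <- vapply(sitesets, nrow, 0L)
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      a <- sitesets[[i]]
      b <- sitesets[[j]]
      tot <- 0L
      for (r in seq_len(nrow(a))) {
        for (s in seq_len(nrow(b))) {
          if (a$chrom[r] == b$chrom[s] &&
              abs(a$position[r] - b$position[s]) <= window) {
            tot <- tot + 1L
          }
        }
      }
      cells[i, j] <- cells[j, i] <- tot
    }
  }
  cells
}

# Textbook Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# A size_histogram built directly from size/count vectors.
new_hist <- function(size, count, metric = "distinct_tfs") {
  h <- data.frame(size = as.integer(size), count = as.integer(count))
  attr(h, "metric") <- metric
  class(h) <- c("size_histogram", "data.frame")
  h
}

# Random multi-TF instance on a small genome.
random_instance <- function(seed, n_tfs = 5L, max_sites = 100L,
                            layout = genome_layout(c("c1", "c2", "c3"),
                                                   c(5e4, 3e4, 2e4))) {
  set.seed(seed)
  n_total <- sample.int(max_sites, 1L)
  labels <- paste0("TF", seq_len(sample.int(n_tfs, 1L)))
  tf <- sample(labels, n_total, replace = TRUE)
  ci <- sample.int(nrow(layout), n_total, replace = TRUE,
                   prob = layout$length)
  pos <- floor(runif(n_total) * layout$length[ci])
  lapply(unique(tf), function(t) {
    sel <- tf == t
    site_set(t, layout$name[ci[sel]], pos[sel])
  })
}

pool_of <- function(sitesets) {
  do.call(rbind, lapply(sitesets, function(s) {
    data.frame(chrom = s$chrom, position = s$position,
               tf = rep(tf_label(s), nrow(s)), stringsAsFactors = FALSE)
  }))
}
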