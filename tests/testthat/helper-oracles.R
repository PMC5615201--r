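# Independent oracles used across the suite. Each re-derives the quantity it
# checks by the most literal route available (explicit loops, exhaustive
# enumeration, closed forms), never by calling the code path under test.

# literal rank-rule redness: sort brightnesses, read the cut values off the
# sorted vector, walk the pixels one by one
redness_oracle <- function(pixels, low = 0.10, high = 0.10) {
  n <- nrow(pixels)
  b <- apply(pixels, 1, function(px) (px[1] + px[2] + px[3]) / 3)
  sorted <- sort(b)
  lo <- if (low > 0) sorted[ceiling(low * n)] else -Inf
  hi <- if (high > 0) sorted[ceiling((1 - high) * n)] else Inf
  vals <- c()
  for (i in seq_len(n)) {
    if (b[i] >= lo && b[i] <= hi)
      vals <- c(vals, pixels[i, 1] - b[i])
  }
  list(index = mean(vals), n_used = length(vals))
}

# exhaustive least-squares tree oracle: enumerate every unrooted topology,
# fit branch lengths by (non-negative) least squares, return the best fit
ls_exhaustive_tree <- function(d) {
  labels <- rownames(d)
  topos <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  best <- NULL; best_ss <- Inf
  for (i in seq_along(topos)) {
    # [[-indexing expands the multiPhylo's compressed TipLabel attribute
    fit <- phangorn::nnls.tree(as.dist(d), topos[[i]], method = "unrooted")
    ss <- sum((as.matrix(ape::cophenetic.phylo(fit))[labels, labels] - d)^2)
    if (ss < best_ss) { best_ss <- ss; best <- fit }
  }
  list(tree = best, ss = best_ss)
}

# random strictly-positive-branch-length tree for additivity checks
random_additive_tree <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
    tr
  })
}

# literal relative-rate point estimates: complete deletion by a column loop,
# pairwise distances from hand-counted transitions/transversions, triplets
# enumerated with nested for loops
naive_rrt_oracle <- function(aln, l1, l2, og, model = "k2p") {
  m <- unclass(as_alignment(aln))
  ok_base <- c("A", "C", "G", "T")
  keep <- apply(m, 2, function(col) all(col %in% ok_base))
  m <- m[, keep, drop = FALSE]
  pdist <- function(a, b) {
    ts <- 0; tv <- 0
    for (s in seq_len(ncol(m))) {
      x <- m[a, s]; y <- m[b, s]
      if (x != y) {
        if ((x %in% c("A", "G")) == (y %in% c("A", "G"))) ts <- ts + 1
        else tv <- tv + 1
      }
    }
    P <- ts / ncol(m); Q <- tv / ncol(m)
    if (model == "jc69") -0.75 * log(1 - 4 * (P + Q) / 3)
    else -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  }
  k1s <- c(); k2s <- c()
  for (a in l1) for (b in l2) for (o in og) {
    dab <- pdist(a, b); dao <- pdist(a, o); dbo <- pdist(b, o)
    k1s <- c(k1s, (dab + dao - dbo) / 2)
    k2s <- c(k2s, (dab + dbo - dao) / 2)
  }
  list(K1 = mean(k1s), K2 = mean(k2s), n_sites = ncol(m))
}

# small uniform-random pixel matrix
random_pixels <- function(n, seed) {
  withr::with_seed(seed,
    matrix(sample.int(256, n * 3, replace = TRUE) - 1L, ncol = 3))
}
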