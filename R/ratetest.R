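# Two-lineage relative rate test: compares substitution accumulation since
# the last common ancestor of two ingroup lineages, using an outgroup to
# locate that ancestor on the path between them. Implemented over site
# patterns: alignment columns are collapsed to unique patterns with counts,
# and the column bootstrap becomes a multinomial draw over pattern
# frequencies — exactly the distribution of resampling columns with
# replacement, at a fraction of the cost.

# distance from per-pair (shared, transition, transversion) counts;
# returns NA on saturation instead of erroring (bootstrap replicates with
# saturated distances are skipped and counted by the caller)
dist_from_class_counts <- function(n_sh, n_ts, n_tv, model) {
  P <- n_ts / n_sh
  Q <- n_tv / n_sh
  if (model == "jc69") {
    w <- 1 - 4 * (P + Q) / 3
    d <- ifelse(n_sh > 0 & w > 0, -0.75 * log(pmax(w, .Machine$double.xmin)), NA_real_)
  } else {
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    ok <- n_sh > 0 & w1 > 0 & w2 > 0
    d <- ifelse(ok,
                -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                  0.25 * log(pmax(w2, .Machine$double.xmin)),
                NA_real_)
  }
  d
}

#' Relative rate test between two lineages
#'
#' Tests whether two lineages have accumulated substitutions at the same rate
#' since their last common ancestor. For every triplet (a in `lineage1`,
#' b in `lineage2`, o in `outgroup`) the model-corrected pairwise distances
#' are decomposed via [triplet_decompose()] into `K1` (lineage-1 branch) and
#' `K2` (lineage-2 branch); `K1` and `K2` are the unweighted means over
#' triplets. The standard error of `K1 - K2` is estimated by a nonparametric
#' bootstrap over alignment columns; the test statistic `z = (K1 - K2) / se`
#' is referred to the standard normal for a two-sided P value.
#'
#' @param aln an `nt_alignment` (or coercible input).
#' @param lineage1,lineage2,outgroup character vectors of taxon ids; must be
#'   disjoint and nonempty.
#' @param model `"k2p"` (default) or `"jc69"`.
#' @param n_bootstrap bootstrap replicates for the variance of `K1 - K2`
#'   (default 2000; must be >= 2).
#' @param seed optional integer seed for the bootstrap.
#' @param site_filter passed to [filter_sites()]; default complete deletion,
#'   so every distance uses one common site set.
#' @return Object of class `rate_test` with fields `K1`, `K2`, `diff`
#'   (`K1 - K2`), `ratio` (`K1 / K2`), `se_diff`, `z`, `p_two_sided`,
#'   `n_sites`, `n_triplets`, `n_bootstrap`, `n_skipped` (saturated bootstrap
#'   replicates), `negative` (any per-triplet branch distance < 0), `model`,
#'   `seed`.
#' @export
relative_rate_test <- function(aln, lineage1, lineage2, outgroup,
                               model = c("k2p", "jc69"), n_bootstrap = 2000,
                               seed = NULL,
                               site_filter = "complete_deletion") {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  groups <- list(lineage1 = lineage1, lineage2 = lineage2, outgroup = outgroup)
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0L) stop(g, " is empty", call. = FALSE)
    absent <- setdiff(groups[[g]], rownames(aln))
    if (length(absent))
      stop(g, " taxa not in alignment: ", paste(absent, collapse = ", "),
           call. = FALSE)
  }
  if (anyDuplicated(unlist(groups)))
    stop("lineage1, lineage2 and outgroup must be disjoint", call. = FALSE)
  if (n_bootstrap < 2) stop("n_bootstrap must be >= 2", call. = FALSE)

  filtered <- filter_sites(aln, mode = site_filter)
  code <- nt_codes(filtered)
  pat <- site_patterns(code)
  n_sites <- sum(pat$counts)

  # all pairs any triplet needs, deduplicated
  triplets <- expand.grid(a = lineage1, b = lineage2, o = outgroup,
                          stringsAsFactors = FALSE)
  pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  keys <- unique(c(pair_key(triplets$a, triplets$b),
                   pair_key(triplets$a, triplets$o),
                   pair_key(triplets$b, triplets$o)))
  pairs <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))

  # per-pattern, per-pair site-class indicators
  npat <- ncol(pat$patterns)
  S <- TS <- TV <- matrix(0, npat, length(keys))
  for (k in seq_along(keys)) {
    x <- pat$patterns[pairs[k, 1], ]
    y <- pat$patterns[pairs[k, 2], ]
    sh <- !is.na(x) & !is.na(y)
    df <- sh & x != y
    ts <- df & ((x %% 2L) == (y %% 2L))
    S[, k] <- as.numeric(sh)
    TS[, k] <- as.numeric(ts)
    TV[, k] <- as.numeric(df & !ts)
  }

  dist_for_counts <- function(cnt) {
    # cnt: pattern-count vector or npat x B matrix -> npairs x B distances
    cnt <- as.matrix(cnt)
    dist_from_class_counts(crossprod(S, cnt), crossprod(TS, cnt),
                           crossprod(TV, cnt), model)
  }

  summarize <- function(dmat, col) {
    da_b <- dmat[match(pair_key(triplets$a, triplets$b), keys), col]
    da_o <- dmat[match(pair_key(triplets$a, triplets$o), keys), col]
    db_o <- dmat[match(pair_key(triplets$b, triplets$o), keys), col]
    k1 <- (da_b + da_o - db_o) / 2
    k2 <- (da_b + db_o - da_o) / 2
    c(K1 = mean(k1), K2 = mean(k2), neg = any(k1 < 0 | k2 < 0))
  }

  d0 <- dist_for_counts(pat$counts)
  if (anyNA(d0))
    stop("saturated distances in the full alignment: relative rate test ",
         "undefined under ", model, call. = FALSE)
  est <- summarize(d0, 1L)
  K1 <- est[["K1"]]; K2 <- est[["K2"]]
  diff <- K1 - K2

  boot_counts <- if (is.null(seed)) {
    stats::rmultinom(n_bootstrap, n_sites, pat$counts / n_sites)
  } else {
    withr::with_seed(seed,
      stats::rmultinom(n_bootstrap, n_sites, pat$counts / n_sites))
  }
  db <- dist_for_counts(boot_counts)
  boot_diff <- vapply(seq_len(n_bootstrap), function(j) {
    if (anyNA(db[, j])) return(NA_real_)
    s <- summarize(db, j)
    s[["K1"]] - s[["K2"]]
  }, numeric(1))
  n_skipped <- sum(is.na(boot_diff))
  if (n_skipped > 0.01 * n_bootstrap)
    warning(n_skipped, " of ", n_bootstrap,
            " bootstrap replicates skipped (saturated distances)")
  se <- stats::sd(boot_diff, na.rm = TRUE)

  if (is.na(se) || se == 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / se
  }
  p <- 2 * stats::pnorm(-abs(z))

  structure(
    list(K1 = K1, K2 = K2, diff = diff,
         ratio = if (K2 != 0) K1 / K2 else NA_real_,
         se_diff = se, z = z, p_two_sided = p,
         n_sites = n_sites, n_triplets = nrow(triplets),
         n_bootstrap = n_bootstrap, n_skipped = n_skipped,
         negative = as.logical(est[["neg"]]),
         model = model, seed = seed,
         lineage1 = lineage1, lineage2 = lineage2, outgroup = outgroup),
    class = "rate_test"
  )
}

#' @export
print.rate_test <- function(x, ...) {
  cat("Relative rate test (", x$model, ", ", x$n_sites, " sites, ",
      x$n_triplets, " triplet(s))\n", sep = "")
  cat(sprintf("  K1 = %.4f  K2 = %.4f  K1-K2 = %+.4f  K1/K2 = %.3g\n",
              x$K1, x$K2, x$diff, x$ratio))
  cat(sprintf("  z = %.3f, two-sided P = %.3g  (bootstrap se %.5f, %d reps",
              x$z, x$p_two_sided, x$se_diff, x$n_bootstrap))
  if (x$n_skipped > 0) cat(", ", x$n_skipped, " skipped", sep = "")
  cat(")\n")
  if (x$negative)
    cat("  note: a per-triplet branch distance was negative (sampling noise)\n")
  invisible(x)
}
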