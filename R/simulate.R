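# Seeded synthetic-data generators. Every generator is deterministic given
# its seed (seeding goes through withr::with_seed, so the caller's RNG state
# is never disturbed) and returns the ground truth needed to test the
# downstream estimator it feeds.

# fixed substream scheme: one top-level seed is split into per-stage seeds so
# pipeline stages can be re-run independently yet reproducibly
sub_seed <- function(seed, index) {
  ((as.numeric(seed) %% 1000003) * 2011 + index * 7919) %% 2147483629 + 1
}

with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Simulate a cuticle photograph
#'
#' Emulates a ventral photograph of the beetle metasternum as a base cuticle
#' colour plus independent Gaussian pixel noise, with a stated fraction of
#' specular-highlight and shadow pixels assigned per-pixel Bernoulli (the
#' brightness mask is rank-based, so spatial clustering of highlights is
#' irrelevant to the statistic). Channels are clipped and rounded to
#' \[0, 255\].
#'
#' @param width,height image size in pixels.
#' @param base_rgb integer RGB triple of the cuticle body colour.
#' @param noise_sd Gaussian noise standard deviation per channel, intensity
#'   units (default 8, a realistic sensor/texture noise level for close-up
#'   macro photography).
#' @param highlight_frac,shadow_frac fractions of highlight / shadow pixels
#'   in \[0, 1) with sum < 1 (defaults 0.05 each).
#' @param highlight_rgb,shadow_rgb colours of highlight and shadow pixels
#'   (defaults near white and near black).
#' @param seed integer seed.
#' @return List: `image` (an [rgb_image]), `truth` with the analytic redness
#'   of `base_rgb` (`redness = R - mean(R,G,B)`) and the realised
#'   `n_highlight`, `n_shadow`, `n_body` pixel counts
#'   (`n_highlight + n_shadow + n_body = width * height`).
#' @export
simulate_cuticle_image <- function(width, height, base_rgb,
                                   noise_sd = 8,
                                   highlight_frac = 0.05, shadow_frac = 0.05,
                                   highlight_rgb = c(250, 250, 250),
                                   shadow_rgb = c(5, 5, 5),
                                   seed = NULL) {
  if (width < 1 || height < 1) stop("width and height must be >= 1", call. = FALSE)
  for (v in list(base_rgb, highlight_rgb, shadow_rgb))
    if (length(v) != 3L || any(v < 0 | v > 255))
      stop("RGB triples must have 3 components in [0, 255]", call. = FALSE)
  if (highlight_frac < 0 || shadow_frac < 0 ||
      highlight_frac + shadow_frac >= 1)
    stop("need highlight_frac + shadow_frac < 1, both nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  npix <- width * height
  out <- with_seed_maybe(seed, {
    u <- stats::runif(npix)
    kind <- ifelse(u < highlight_frac, 1L,
                   ifelse(u < highlight_frac + shadow_frac, 2L, 0L))
    arr <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      v <- rep(base_rgb[ch], npix)
      if (noise_sd > 0) v <- v + stats::rnorm(npix, 0, noise_sd)
      v[kind == 1L] <- highlight_rgb[ch]
      v[kind == 2L] <- shadow_rgb[ch]
      arr[, , ch] <- matrix(pmin(pmax(round(v), 0), 255), height, width)
    }
    list(arr = arr, kind = kind)
  })
  list(
    image = rgb_image(out$arr),
    truth = list(redness = base_rgb[1] - mean(base_rgb),
                 n_highlight = sum(out$kind == 1L),
                 n_shadow = sum(out$kind == 2L),
                 n_body = sum(out$kind == 0L))
  )
}

# K2P transition-probability row for parent state k over a branch of d
# expected substitutions per site; kappa = 1 gives JC69
k2p_prob_rows <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * d / (kappa + 2)
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  rows <- matrix(p_tv, 4, 4)
  for (k in 1:4) {
    partner <- if (k <= 2) k + 2L else k - 2L
    rows[k, k] <- p_same
    rows[k, partner] <- p_ts
  }
  rows
}

mutate_states <- function(parent, d, rows) {
  if (d == 0) return(parent)
  child <- integer(length(parent))
  for (k in 1:4) {
    idx <- which(parent == k)
    if (length(idx))
      child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = rows[k, ])
  }
  child
}

#' Simulate a gapless alignment on a tree
#'
#' Sites evolve independently down a rooted tree from a uniform-composition
#' root (the JC69/K2P stationary distribution) using the exact closed-form
#' transition-probability matrices; branch lengths are expected substitutions
#' per site. Lineage-rate asymmetry is expressed simply through unequal
#' branch lengths. No indels, no across-site rate heterogeneity.
#'
#' @param tree a `phylo` object or Newick string with branch lengths, e.g.
#'   `"((L1:0.1,L2:0.05):0,O:0.2);"`.
#' @param model `"jc69"` or `"k2p"`.
#' @param kappa transition/transversion rate ratio (> 0), used under
#'   `"k2p"`; default 2.
#' @param length number of sites (>= 1).
#' @param seed integer seed.
#' @return An `nt_alignment` with one row per leaf.
#' @export
simulate_alignment <- function(tree, model = c("jc69", "k2p"), kappa = 2,
                               length = 1000, seed = NULL) {
  model <- match.arg(model)
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must carry a branch length on every edge", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree", call. = FALSE)
  if (length < 1) stop("alignment length must be >= 1", call. = FALSE)
  if (model == "k2p" && kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  kap <- if (model == "jc69") 1 else kappa
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- with_seed_maybe(seed, {
    st <- vector("list", ntip + tree$Nnode)
    st[[root]] <- sample.int(4L, length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      st[[chi]] <- mutate_states(st[[par]], tree$edge.length[e],
                                 k2p_prob_rows(tree$edge.length[e], kap))
    }
    st
  })
  bases <- c("A", "C", "G", "T")
  m <- do.call(rbind, lapply(states[seq_len(ntip)], function(s) bases[s]))
  rownames(m) <- tree$tip.label
  as_alignment(m)
}

#' Simulate composition-biased i.i.d. sequences
#'
#' Each site is drawn independently from the given base frequencies, for
#' testing AT-content estimation against a known truth (realised AT content
#' converges to `100 * (fA + fT)` as length grows).
#'
#' @param base_freqs probabilities for A, C, G, T; nonnegative, summing to 1
#'   (tolerance 1e-9).
#' @param length sites per sequence.
#' @param n_sequences number of sequences.
#' @param seed integer seed.
#' @return Named character vector of sequences (`seq1`, `seq2`, ...).
#' @export
simulate_composition_sequences <- function(base_freqs, length, n_sequences = 1,
                                           seed = NULL) {
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must be 4 nonnegative probabilities summing to 1",
         call. = FALSE)
  if (length < 1 || n_sequences < 1)
    stop("length and n_sequences must be >= 1", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  seqs <- with_seed_maybe(seed, {
    vapply(seq_len(n_sequences), function(i) {
      paste(sample(bases, length, replace = TRUE, prob = base_freqs),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("seq", seq_len(n_sequences))
  seqs
}

#' Simulate a two-group body-weight sample
#'
#' Gaussian draws truncated at zero (negative draws are rejected and
#' redrawn), emulating dry-body-weight measurements in milligrams.
#'
#' @param n sample size (>= 1).
#' @param mean mean weight, mg.
#' @param sd standard deviation, mg (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of `n` nonnegative weights.
#' @export
simulate_weights <- function(n, mean, sd, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  with_seed_maybe(seed, {
    x <- stats::rnorm(n, mean, sd)
    while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mean, sd)
    x
  })
}
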