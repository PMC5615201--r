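# Neighbor joining with the Studier-Keppler criterion, built on top of the
# package's model-corrected distances. Trees are returned as ape "phylo"
# objects so the whole ape toolkit (plotting, rerooting, comparison) applies.

check_dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix must be labelled", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)))
    stop("distance matrix entries must be finite", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  bad <- grepl("[,;:()\\[\\]]|\\s", rownames(d))
  if (any(bad))
    stop("taxon labels may not contain Newick metacharacters: ",
         paste(rownames(d)[bad], collapse = ", "), call. = FALSE)
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion:
#' `Q[i,j] = (r - 2) d[i,j] - R[i] - R[j]` with `R` the row sums over the
#' `r` active nodes. Ties in Q are broken deterministically by the lowest
#' (row, column) index pair. On an additive distance matrix the generating
#' topology is recovered with exact branch lengths. Negative branch lengths
#' (possible on non-additive input) are clamped to zero in the returned tree;
#' the number of clamped branches is attached as attribute `clamped`.
#'
#' @param d symmetric labelled distance matrix (e.g. from [dist_matrix()]),
#'   at least 3 taxa.
#' @return Unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  check_dist_matrix(d)
  dm <- unname(d)
  frag <- rownames(d)
  clamped <- 0L
  fmt <- function(x) {
    if (x < 0) clamped <<- clamped + 1L
    sprintf("%.10g", max(x, 0))
  }
  while (nrow(dm) > 3L) {
    r <- nrow(dm)
    R <- rowSums(dm)
    Q <- (r - 2) * dm - outer(R, R, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    # row-major first minimum = lowest (row, column) pair
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    vi <- dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- dm[i, j] - vi
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":", fmt(vj), ")")
    keep <- setdiff(seq_len(r), c(i, j))
    du <- (dm[i, keep] + dm[j, keep] - dm[i, j]) / 2
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], du), c(du, 0))
    frag <- c(frag[keep], new_frag)
  }
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                ",", frag[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# per-pattern site-class indicator matrices for a set of taxon pairs;
# shared with the rate test's bootstrap machinery
pair_class_matrices <- function(patterns, pairs_idx) {
  npat <- ncol(patterns)
  np <- nrow(pairs_idx)
  S <- TS <- TV <- matrix(0, npat, np)
  for (k in seq_len(np)) {
    x <- patterns[pairs_idx[k, 1], ]
    y <- patterns[pairs_idx[k, 2], ]
    sh <- !is.na(x) & !is.na(y)
    df <- sh & x != y
    ts <- df & ((x %% 2L) == (y %% 2L))
    S[, k] <- as.numeric(sh)
    TS[, k] <- as.numeric(ts)
    TV[, k] <- as.numeric(df & !ts)
  }
  list(S = S, TS = TS, TV = TV)
}

#' Neighbor-joining tree with column-bootstrap support values
#'
#' Builds the NJ tree from the model-corrected distances of the full
#' alignment, then resamples alignment columns with replacement `n_reps`
#' times, rebuilds the NJ tree for each replicate, and annotates every
#' internal edge of the full-data tree with the percentage of (successful)
#' replicates whose tree contains the same bipartition. Replicates in which a
#' pairwise distance saturates are skipped and counted; a warning is issued
#' when more than 1% are skipped.
#'
#' @param aln an `nt_alignment` (or coercible input).
#' @param model `"k2p"` (default) or `"jc69"`.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @param site_filter passed to [filter_sites()].
#' @return Unrooted `phylo` tree whose `node.label` holds bootstrap
#'   percentages (root label empty); attributes `n_reps`, `n_skipped`.
#' @export
bootstrap_nj <- function(aln, model = c("k2p", "jc69"), n_reps = 1000,
                         seed = NULL, site_filter = "complete_deletion") {
  model <- match.arg(model)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  filtered <- filter_sites(as_alignment(aln), mode = site_filter)
  code <- nt_codes(filtered)
  n <- nrow(code)
  if (n < 3L) stop("bootstrap NJ needs at least 3 taxa", call. = FALSE)
  labels <- rownames(code)
  pat <- site_patterns(code)
  n_sites <- sum(pat$counts)
  pairs_idx <- t(utils::combn(n, 2))
  cls <- pair_class_matrices(pat$patterns, pairs_idx)

  dist_mat_from_counts <- function(cnt) {
    dvec <- dist_from_class_counts(
      crossprod(cls$S, cnt), crossprod(cls$TS, cnt), crossprod(cls$TV, cnt),
      model)
    if (anyNA(dvec)) return(NULL)
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    d[pairs_idx] <- dvec
    d[pairs_idx[, c(2, 1)]] <- dvec
    d
  }

  d_full <- dist_mat_from_counts(matrix(pat$counts, ncol = 1))
  if (is.null(d_full))
    stop("saturated distances in the full alignment", call. = FALSE)
  if (all(d_full == 0))
    stop("all sequences identical: no phylogenetic signal to bootstrap",
         call. = FALSE)
  main <- neighbor_joining(d_full)

  draw <- function() stats::rmultinom(n_reps, n_sites, pat$counts / n_sites)
  boot_counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  boot_trees <- list()
  n_skipped <- 0L
  for (b in seq_len(n_reps)) {
    db <- dist_mat_from_counts(boot_counts[, b, drop = FALSE])
    if (is.null(db)) { n_skipped <- n_skipped + 1L; next }
    boot_trees[[length(boot_trees) + 1L]] <- neighbor_joining(db)
  }
  if (n_skipped > 0.01 * n_reps)
    warning(n_skipped, " of ", n_reps,
            " bootstrap replicates skipped (saturated distances)")
  n_used <- length(boot_trees)
  if (n_used == 0L) stop("every bootstrap replicate saturated", call. = FALSE)
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(main, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_used
  lab <- sprintf("%.10g", support)
  lab[1] <- ""  # root of the unrooted representation: trivial bipartition
  main$node.label <- lab
  attr(main, "support") <- support
  attr(main, "n_reps") <- n_reps
  attr(main, "n_used") <- n_used
  attr(main, "n_skipped") <- n_skipped
  main
}

#' Serialize a tree to Newick text
#'
#' Bootstrap supports, when present, travel as internal-node labels.
#'
#' @param tree a `phylo` object.
#' @param path optional file path; when given the text is written there.
#' @return Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse Newick text into a tree
#'
#' @param text Newick string, or a path to a file holding one.
#' @return A `phylo` object.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("\\(", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  if (!nzchar(trimws(paste(text, collapse = ""))))
    stop("empty Newick input", call. = FALSE)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick input", call. = FALSE)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in Newick input: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  tree
}
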