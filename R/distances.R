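# Model-corrected pairwise distances. Transitions are the purine-purine and
# pyrimidine-pyrimidine changes (A<->G, C<->T); everything else is a
# transversion. rRNA data are strongly transition-biased, hence the K2P
# default throughout the package.

#' Transition and transversion fractions between two aligned sequences
#'
#' @param seq_a,seq_b aligned residue strings of equal length, or integer
#'   code vectors (1..4 = A,C,G,T, NA = missing).
#' @return List with `P` (transition fraction), `Q` (transversion fraction)
#'   and `n_sites` (shared unambiguous sites), such that `P + Q <= 1`.
#' @export
p_q_counts <- function(seq_a, seq_b) {
  a <- if (is.character(seq_a) && length(seq_a) == 1L)
         nt_codes(as_alignment(c(x = seq_a, y = seq_b)))[1, ] else seq_a
  b <- if (is.character(seq_b) && length(seq_b) == 1L)
         nt_codes(as_alignment(c(x = seq_a, y = seq_b)))[2, ] else seq_b
  if (length(a) != length(b))
    stop("sequences differ in aligned length", call. = FALSE)
  shared <- !is.na(a) & !is.na(b)
  n <- sum(shared)
  if (n == 0L) stop("no shared unambiguous sites", call. = FALSE)
  a <- a[shared]; b <- b[shared]
  diff <- a != b
  # purines code 1,3; pyrimidines 2,4: a transition keeps code parity
  ts <- diff & ((a %% 2L) == (b %% 2L))
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n_sites = n)
}

#' Jukes-Cantor (1969) distance
#'
#' `d = -(3/4) * log(1 - 4p/3)` for mismatch fraction `p`.
#'
#' @param p observed mismatch fraction, `0 <= p < 0.75`.
#' @return Corrected distance in substitutions per site.
#' @export
jc69_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("JC69 saturation: mismatch fraction must satisfy 0 <= p < 0.75",
         call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura 2-parameter distance
#'
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)` for transition fraction
#' `P` and transversion fraction `Q`.
#'
#' @param P transition fraction.
#' @param Q transversion fraction.
#' @return Corrected distance in substitutions per site.
#' @export
k2p_distance <- function(P, Q) {
  if (any(P < 0) || any(Q < 0) || any(P + Q > 1))
    stop("P and Q must be nonnegative fractions with P + Q <= 1", call. = FALSE)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0))
    stop("K2P saturation: log argument <= 0 (P = ", paste(P, collapse = ","),
         ", Q = ", paste(Q, collapse = ","), ")", call. = FALSE)
  -0.5 * log(w1) - 0.25 * log(w2)
}

pair_distance <- function(a, b, model) {
  pq <- p_q_counts(a, b)
  if (model == "jc69") jc69_distance(pq$P + pq$Q) else k2p_distance(pq$P, pq$Q)
}

#' Model-corrected pairwise distance matrix
#'
#' @param aln an `nt_alignment` (or coercible input).
#' @param model `"k2p"` (default) or `"jc69"`.
#' @param site_filter `"complete_deletion"` (default) or
#'   `"pairwise_deletion"`; see [filter_sites()].
#' @return Symmetric numeric matrix of substitutions per site with zero
#'   diagonal, labelled by taxon ids; attribute `n_sites` gives the filtered
#'   site count (complete deletion) or the full column count.
#' @export
dist_matrix <- function(aln, model = c("k2p", "jc69"),
                        site_filter = "complete_deletion") {
  model <- match.arg(model)
  aln <- filter_sites(as_alignment(aln), mode = site_filter)
  code <- nt_codes(aln)
  n <- nrow(code)
  labels <- rownames(code)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pair_distance(code[i, ], code[j, ], model)
    }
  }
  attr(d, "n_sites") <- ncol(aln)
  attr(d, "model") <- model
  d
}

#' Split a pairwise distance into lineage-specific branch distances
#'
#' Given distances among two ingroup lineages A, B and an outgroup O, the
#' distance from each lineage to their last common ancestor is
#' `K1 = (dAB + dAO - dBO) / 2` and `K2 = (dAB + dBO - dAO) / 2`, so that
#' `K1 + K2 = dAB` exactly. Negative values (possible by sampling noise on
#' near-zero branches) are reported as-is with a warning flag.
#'
#' @param d_ab,d_ao,d_bo pairwise distances.
#' @return List with `K1`, `K2`, and logical `negative` flag.
#' @export
triplet_decompose <- function(d_ab, d_ao, d_bo) {
  stopifnot(is.finite(d_ab), is.finite(d_ao), is.finite(d_bo),
            d_ab >= 0, d_ao >= 0, d_bo >= 0)
  k1 <- (d_ab + d_ao - d_bo) / 2
  k2 <- (d_ab + d_bo - d_ao) / 2
  list(K1 = k1, K2 = k2, negative = (k1 < 0) || (k2 < 0))
}
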