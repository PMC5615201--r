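#' Build a nucleotide alignment matrix
#'
#' The alignment container is a character matrix with one row per taxon
#' (rownames are taxon ids) and one column per aligned site, residues
#' uppercase. Accepts a named character vector of equal-length aligned
#' strings (e.g. from [read_fasta()]) or an existing character matrix.
#'
#' @param x named character vector of aligned sequences, or character matrix.
#' @return Character matrix of class `nt_alignment`.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "nt_alignment")) return(x)
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("aligned sequences must be named", call. = FALSE)
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("aligned sequences differ in length (",
           paste(range(lens), collapse = "-"), ")", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(unname(x)), "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  if (nrow(m) < 2L) stop("an alignment needs at least 2 sequences", call. = FALSE)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment rows must carry unique taxon ids", call. = FALSE)
  bad <- setdiff(unique(as.vector(m)), NT_ALPHABET)
  if (length(bad))
    stop("illegal residue(s) in alignment: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  class(m) <- c("nt_alignment", class(m))
  m
}

#' @export
print.nt_alignment <- function(x, ...) {
  cat(sprintf("<nt_alignment> %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path path to aligned FASTA (all records the same length).
#' @return An `nt_alignment` matrix.
#' @export
read_alignment <- function(path) as_alignment(read_fasta(path))

# Integer coding of a residue: 1..4 = A,C,G,T (U folded into T), NA = gap or
# ambiguity code (treated as missing when `treat_ambiguous_as_missing`).
nt_codes <- function(aln, treat_ambiguous_as_missing = TRUE) {
  m <- unclass(aln)
  code <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  code[m == "A"] <- 1L
  code[m == "C"] <- 2L
  code[m == "G"] <- 3L
  code[m == "T" | m == "U"] <- 4L
  if (!treat_ambiguous_as_missing) {
    amb <- m %in% setdiff(NT_AMBIG, "U")
    if (any(amb))
      stop("alignment contains ambiguity codes; set treat_ambiguous_as_missing",
           call. = FALSE)
  }
  code
}

#' Drop alignment columns with missing data
#'
#' Site filtering ahead of distance estimation. Under complete deletion every
#' column containing a gap — and, by default, any ambiguity code — in any row
#' is removed, so all pairwise comparisons use one common site set (the way a
#' single aligned-site count can be quoted for a whole table of rate tests).
#' Under pairwise deletion the alignment is returned unchanged (minus all-gap
#' columns) and dropping is deferred to each pair at distance time.
#'
#' @param aln an `nt_alignment`.
#' @param mode `"complete_deletion"` or `"pairwise_deletion"`.
#' @param treat_ambiguous_as_missing logical; treat IUPAC ambiguity codes as
#'   missing (default `TRUE`).
#' @return Filtered `nt_alignment`; the retained original column indices are
#'   attached as attribute `kept_sites`.
#' @export
filter_sites <- function(aln,
                         mode = c("complete_deletion", "pairwise_deletion"),
                         treat_ambiguous_as_missing = TRUE) {
  mode <- match.arg(mode)
  aln <- as_alignment(aln)
  code <- nt_codes(aln, treat_ambiguous_as_missing = TRUE)
  missing <- is.na(code)
  if (!treat_ambiguous_as_missing) {
    # only true gaps count as missing; ambiguity codes stay (still unusable
    # for distances, but not grounds for dropping the whole column)
    missing <- matrix(unclass(aln) %in% NT_GAP, nrow(aln), ncol(aln))
  }
  keep <- if (mode == "complete_deletion") colSums(missing) == 0L
          else colSums(!missing) > 0L   # all-gap columns always go
  if (!any(keep))
    stop("no alignment columns survive ", mode, call. = FALSE)
  out <- aln[, keep, drop = FALSE]
  class(out) <- c("nt_alignment", "matrix", "array")
  attr(out, "kept_sites") <- which(keep)
  out
}

# Collapse an integer-coded alignment to unique site patterns with counts.
# A column bootstrap (resampling columns i.i.d. with replacement) is then a
# multinomial draw over pattern frequencies, which is what makes large
# bootstrap x replicate grids affordable.
site_patterns <- function(code) {
  key <- apply(code, 2, paste0, collapse = "\r")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = code[, first, drop = FALSE], counts = as.integer(tab))
}
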