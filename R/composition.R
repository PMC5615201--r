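# Nucleotide alphabet policy: IUPAC codes plus gaps; U is accepted and
# treated as T so rRNA-style input behaves like DNA. Everything is
# normalised to uppercase at parse time.
NT_UNAMBIG <- c("A", "C", "G", "T")
NT_AMBIG <- c("U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
NT_GAP <- c("-", ".")
NT_ALPHABET <- c(NT_UNAMBIG, NT_AMBIG, NT_GAP)

#' Read nucleotide sequences from FASTA
#'
#' Sequences are uppercased and validated against the IUPAC nucleotide
#' alphabet (plus `-` and `.` gap characters); any other residue is rejected
#' with an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of residue strings (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty id", call. = FALSE)
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, NT_ALPHABET)
    if (length(bad))
      stop("illegal residue(s) ", paste(sQuote(bad), collapse = ", "),
           " in record '", ids[i], "' of ", path, call. = FALSE)
  }
  seqs
}

#' Write nucleotide sequences to FASTA
#'
#' Output is wrapped at 70 columns so repeated writes of the same records are
#' byte-identical.
#'
#' @param records named character vector of residue strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("every record needs a nonempty id", call. = FALSE)
  set <- Biostrings::BStringSet(toupper(records))
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

seq_chars <- function(record) strsplit(toupper(record[[1]]), "", fixed = TRUE)[[1]]

#' Ungapped sequence length
#'
#' Number of non-gap characters (`-` and `.` are gaps).
#'
#' @param record a residue string.
#' @return Integer count.
#' @export
ungapped_length <- function(record) {
  chars <- seq_chars(record)
  sum(!(chars %in% NT_GAP))
}

#' Base composition and AT content
#'
#' AT content is `100 * (A + T) / (A + C + G + T)` where U counts as T; gaps
#' and IUPAC ambiguity codes (including N) are excluded from both numerator
#' and denominator. Elevated AT content is a classic signature of reductive
#' endosymbiont genome evolution, which is why it is reported per sequence.
#'
#' @param record a residue string.
#' @return A list of class `composition_summary`: `length_ungapped`, counts
#'   `A`, `C`, `G`, `T`, `ambiguous_count`, `at_content` (percent), and
#'   `gc_content` (percent, computed the same way).
#' @export
at_content <- function(record) {
  chars <- seq_chars(record)
  chars <- chars[!(chars %in% NT_GAP)]
  chars[chars == "U"] <- "T"
  cnt <- c(A = sum(chars == "A"), C = sum(chars == "C"),
           G = sum(chars == "G"), T = sum(chars == "T"))
  n_unambig <- sum(cnt)
  if (n_unambig == 0L)
    stop("sequence contains no unambiguous bases: AT content undefined",
         call. = FALSE)
  structure(
    list(length_ungapped = length(chars),
         A = unname(cnt["A"]), C = unname(cnt["C"]),
         G = unname(cnt["G"]), T = unname(cnt["T"]),
         ambiguous_count = length(chars) - n_unambig,
         at_content = 100 * (cnt[["A"]] + cnt[["T"]]) / n_unambig,
         gc_content = 100 * (cnt[["C"]] + cnt[["G"]]) / n_unambig),
    class = "composition_summary"
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf(
    "%d bp ungapped (A %d, C %d, G %d, T %d, ambiguous %d); AT %.1f%%\n",
    x$length_ungapped, x$A, x$C, x$G, x$T, x$ambiguous_count, x$at_content))
  invisible(x)
}

#' Composition table for a set of sequences
#'
#' @param records named character vector (e.g. from [read_fasta()]).
#' @return A data.frame with one row per record: id, length, base counts,
#'   ambiguous count and AT percent.
#' @export
composition_table <- function(records) {
  rows <- lapply(seq_along(records), function(i) {
    s <- at_content(records[[i]])
    data.frame(id = names(records)[i], length = s$length_ungapped,
               A = s$A, C = s$C, G = s$G, T = s$T,
               ambiguous = s$ambiguous_count, at_percent = s$at_content)
  })
  do.call(rbind, rows)
}
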